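split_codes <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ";",
                                    fixed = TRUE)

category_members <- function(annotation, category,
                             scheme = c("auto", "funcat", "kog",
                                        "cazy_family")) {
  scheme <- match.arg(scheme)
  if (scheme == "auto") {
    scheme <- if (grepl("^[A-Z]$", category)) "kog"
      else if (grepl("^(GH|CE|CBM|AA|GT|PL)[0-9]+$", category)) "cazy_family"
      else "funcat"
  }
  col <- switch(scheme, funcat = "funcat_codes", cazy_family = "cazy_families",
                kog = "kog_class")
  if (scheme == "kog") {
    annotation$gene_id[annotation$kog_class == category]
  } else {
    hits <- vapply(split_codes(annotation[[col]]),
                   function(v) category %in% v, logical(1))
    annotation$gene_id[hits]
  }
}

chi2_from_table <- function(a, b, c_, d, correct = FALSE) {
  # 2x2 Pearson chi-square, 1 df; optional Yates continuity correction.
  # doubles throughout: integer cell products overflow 32-bit range
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) return(list(chi2 = 0, p = 1))
  chi2 <- n * num^2 / denom
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square test of category enrichment within a gene group
#'
#' Tests whether a functional category is over- or under-represented in a
#' gene group relative to the genome-wide annotation background, using a
#' 2x2 Pearson chi-square test (in group / not in group x in category /
#' not in category), 1 df, no continuity correction by default. When any
#' expected cell falls below 1 the result is flagged `low_expected` and a
#' Fisher exact p-value is reported alongside.
#'
#' @param group_genes Character vector of gene ids forming the group.
#' @param annotation Annotation data.frame covering the universe.
#' @param category Category code (functional-catalogue dotted code, single
#'   KOG letter, or CAZyme family such as `GH18`).
#' @param universe Character vector of background gene ids; default: all
#'   annotated genes.
#' @param scheme Annotation scheme; `"auto"` infers it from the code shape.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row data.frame with the table margins, `expected`,
#'   `chi2`, `p_value`, `percent_of_category`, `low_expected` and
#'   `p_fisher` (NA unless flagged).
#' @export
chi_square_enrichment <- function(group_genes, annotation, category,
                                  universe = NULL, scheme = "auto",
                                  correct = FALSE) {
  if (is.null(universe)) universe <- annotation$gene_id
  if (!all(group_genes %in% universe))
    stop("group contains genes outside the universe")
  cat_genes <- intersect(category_members(annotation, category, scheme),
                         universe)
  n_genome <- length(universe)
  n_group <- length(group_genes)
  n_cat <- length(cat_genes)
  obs <- sum(group_genes %in% cat_genes)

  a <- obs                      # in group, in category
  b <- n_group - obs            # in group, not in category
  c_ <- n_cat - obs             # not in group, in category
  d <- n_genome - n_group - c_  # neither
  expected <- n_group * n_cat / n_genome
  exp_cells <- outer(c(n_group, n_genome - n_group),
                     c(n_cat, n_genome - n_cat)) / n_genome
  low <- any(exp_cells < 1)
  res <- chi2_from_table(a, b, c_, d, correct)
  p_fisher <- NA_real_
  if (low)
    p_fisher <- stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                          byrow = TRUE))$p.value
  data.frame(category = category, observed = obs, group_size = n_group,
             genome_category_count = n_cat, genome_size = n_genome,
             expected = expected, chi2 = res$chi2, p_value = res$p,
             percent_of_category = if (n_cat > 0) 100 * obs / n_cat else 0,
             low_expected = low, p_fisher = p_fisher,
             stringsAsFactors = FALSE)
}

#' Enrichment screen over all categories and transcript groups
#'
#' Runs [chi_square_enrichment()] for every category of a scheme with at
#' least one genome member, crossed with transcript groups A-E and the
#' constitutive set. P-values are unadjusted by default; a
#' Benjamini-Hochberg column can be added.
#'
#' @param assignments Output of [classify_transcript_groups()].
#' @param annotation Annotation data.frame.
#' @param scheme One of `"funcat"`, `"kog"`, `"cazy_family"`.
#' @param groups Which transcript groups to screen.
#' @param universe Background gene ids; default all annotated genes.
#' @param bh Add a `p_bh` Benjamini-Hochberg column (default `FALSE`).
#' @return A data.frame, one row per (category, group).
#' @export
enrichment_screen <- function(assignments, annotation,
                              scheme = c("funcat", "kog", "cazy_family"),
                              groups = c("A", "B", "C", "D", "E",
                                         "CONSTITUTIVE"),
                              universe = NULL, bh = FALSE) {
  scheme <- match.arg(scheme)
  if (is.null(universe)) universe <- annotation$gene_id
  cats <- switch(scheme,
    funcat = sort(unique(unlist(split_codes(annotation$funcat_codes)))),
    cazy_family = sort(unique(unlist(split_codes(annotation$cazy_families)))),
    kog = sort(setdiff(unique(annotation$kog_class), "")))
  out <- list()
  for (g in groups) {
    members <- intersect(assignments$gene_id[assignments$group == g],
                         universe)
    for (cat in cats) {
      row <- chi_square_enrichment(members, annotation, cat,
                                   universe = universe, scheme = scheme)
      out[[length(out) + 1L]] <- cbind(data.frame(group = g), row)
    }
  }
  res <- do.call(rbind, out)
  if (bh) res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res
}
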