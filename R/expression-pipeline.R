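#' Classification thresholds for transcript grouping
#'
#' Bundles the cutoffs used to call a gene "upregulated" relative to the
#' glucose reference and to delimit the constitutive set.
#'
#' @param fold_change_min Minimal linear fold change (default 2: a gene
#'   must be >2-fold more abundant than on glucose).
#' @param p_max Significance cutoff for the per-gene test (default 0.05,
#'   unadjusted).
#' @param constitutive_band Linear fold band for the constitutive set: all
#'   pairwise ratios of condition means must lie within
#'   `[1/band, band]` (default 1.4, boundary inclusive).
#' @param expression_floor Minimal log2 condition mean for a gene to count
#'   as expressed (default 1.0).
#' @param wl_fold_min Fold-change cutoff on the direct wheat-straw vs
#'   lactose contrast used to split jointly upregulated genes into the
#'   "stronger on one substrate" groups (default 2).
#' @return A list of class `transcript_thresholds`.
#' @export
transcript_thresholds <- function(fold_change_min = 2, p_max = 0.05,
                                  constitutive_band = 1.4,
                                  expression_floor = 1,
                                  wl_fold_min = 2) {
  if (fold_change_min <= 1) stop("fold_change_min must exceed 1")
  if (constitutive_band <= 1 || constitutive_band >= fold_change_min)
    stop("constitutive_band must satisfy 1 < constitutive_band < fold_change_min")
  if (p_max <= 0 || p_max > 1) stop("p_max must be in (0, 1]")
  structure(list(fold_change_min = fold_change_min, p_max = p_max,
                 constitutive_band = constitutive_band,
                 expression_floor = expression_floor,
                 wl_fold_min = wl_fold_min),
            class = "transcript_thresholds")
}

row_means_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- if (n > 1) rowSums((m - mu)^2) / (n - 1) else rep(0, nrow(m))
  list(mean = mu, var = v, n = n)
}

#' Per-gene differential expression between two conditions
#'
#' Computes, for every gene, the difference of log2 condition means (a log2
#' fold change of geometric means) and a per-gene p-value. The default test
#' is the two-sample equal-variance t-test on the log2 replicate values; no
#' multiple-testing correction is applied (matching the raw p < 0.05
#' convention of low-replicate array studies). Welch and label-permutation
#' tests are available as alternatives.
#'
#' When both groups have zero within-group variance the t statistic is
#' undefined; by convention p = 1 if the means are equal and p = 0 if they
#' differ (the noiseless case is then called at any fold change).
#'
#' @param x An [expr_matrix()].
#' @param cond_a,cond_b Condition labels; the fold change is a over b.
#' @param method One of `"t"` (pooled-variance t, default), `"welch"`,
#'   `"permutation"`.
#' @param n_perm Number of label permutations for `method = "permutation"`.
#' @param seed Seed used only by the permutation method.
#' @return A data.frame with columns `gene_id`, `log2_fc`, `p_value`,
#'   `mean_a`, `mean_b`.
#' @export
differential_expression <- function(x, cond_a, cond_b,
                                    method = c("t", "welch", "permutation"),
                                    n_perm = 1000, seed = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  method <- match.arg(method)
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% x$samples$condition) stop("condition not present: ", cond)
    if (replicate_count(x, cond) < 2L)
      stop("condition '", cond, "' needs >=2 replicates for DE")
  }
  a <- x$values[, x$samples$condition == cond_a, drop = FALSE]
  b <- x$values[, x$samples$condition == cond_b, drop = FALSE]
  sa <- row_means_vars(a); sb <- row_means_vars(b)
  lfc <- sa$mean - sb$mean

  degenerate <- sa$var == 0 & sb$var == 0
  p <- rep(NA_real_, nrow(a))
  if (method == "t") {
    df <- sa$n + sb$n - 2L
    sp2 <- ((sa$n - 1) * sa$var + (sb$n - 1) * sb$var) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    tt <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pt(-abs(tt), df)
  } else if (method == "welch") {
    for (i in seq_len(nrow(a))) {
      if (!degenerate[i]) {
        p[i] <- welch_t_test(a[i, ], b[i, ])$p_value
      }
    }
  } else {
    set.seed(seed)
    pooled <- cbind(a, b)
    na <- ncol(a)
    obs <- abs(lfc)
    cnt <- integer(nrow(a))
    for (k in seq_len(n_perm)) {
      idx <- sample.int(ncol(pooled))
      d <- abs(rowMeans(pooled[, idx[seq_len(na)], drop = FALSE]) -
                 rowMeans(pooled[, idx[-seq_len(na)], drop = FALSE]))
      cnt <- cnt + (d >= obs - 1e-12)
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  p[degenerate] <- ifelse(abs(lfc[degenerate]) < 1e-12, 1, 0)
  data.frame(gene_id = rownames(a), log2_fc = lfc, p_value = p,
             mean_a = sa$mean, mean_b = sb$mean,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify constitutively expressed genes
#'
#' A gene is constitutive when its log2 condition means are all above the
#' expression floor and every pairwise linear ratio of condition means lies
#' within the symmetric band `[1/band, band]` (default 1.4-fold, boundary
#' inclusive).
#'
#' @param x An [expr_matrix()] with at least 3 conditions.
#' @param thresholds A [transcript_thresholds()].
#' @return Character vector of constitutive gene ids.
#' @export
find_constitutive <- function(x, thresholds = transcript_thresholds()) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(conditions(x)) < 3L) stop("need >=3 conditions")
  cm <- condition_means(x)
  band <- log2(thresholds$constitutive_band)
  above <- rowSums(cm <= thresholds$expression_floor) == 0
  spread <- apply(cm, 1L, function(v) max(v) - min(v))
  # max pairwise log-ratio == max - min; tiny epsilon keeps the stated
  # closed interval closed under floating-point construction of the edge
  ok <- above & (spread <= band + 1e-9)
  rownames(cm)[ok]
}

#' Classify genes into substrate-response transcript groups
#'
#' Assigns every gene exactly one label out of A-E, CONSTITUTIVE or NONE
#' from three differential-expression contrasts:
#' \describe{
#'   \item{A}{upregulated (>= fold cutoff at p < p_max) on wheat straw
#'     only,}
#'   \item{B}{upregulated on lactose only,}
#'   \item{C}{up on both, significantly stronger (by the direct
#'     wheat-straw vs lactose contrast) on wheat straw,}
#'   \item{D}{up on both, stronger on lactose,}
#'   \item{E}{up on both to a comparable degree,}
#'   \item{CONSTITUTIVE}{supplied via `constitutive` (see
#'     [find_constitutive()]); takes precedence over A-E,}
#'   \item{NONE}{everything else.}
#' }
#'
#' @param de_ws_glc DE table wheat straw vs glucose
#'   (from [differential_expression()], `a` = wheat straw).
#' @param de_lac_glc DE table lactose vs glucose.
#' @param de_ws_lac DE table wheat straw vs lactose.
#' @param thresholds A [transcript_thresholds()].
#' @param constitutive Character vector of constitutive gene ids.
#' @return A data.frame with columns `gene_id`, `group` (factor with
#'   levels A, B, C, D, E, CONSTITUTIVE, NONE), `up_ws`, `up_lac`, and the
#'   supporting fold changes and p-values.
#' @export
classify_transcript_groups <- function(de_ws_glc, de_lac_glc, de_ws_lac,
                                       thresholds = transcript_thresholds(),
                                       constitutive = character()) {
  ids <- de_ws_glc$gene_id
  for (de in list(de_lac_glc, de_ws_lac)) {
    if (!setequal(ids, de$gene_id)) {
      diffs <- union(setdiff(ids, de$gene_id), setdiff(de$gene_id, ids))
      stop("gene universes disagree; symmetric difference: ",
           paste(utils::head(diffs, 20L), collapse = ", "))
    }
  }
  de_lac_glc <- de_lac_glc[match(ids, de_lac_glc$gene_id), ]
  de_ws_lac <- de_ws_lac[match(ids, de_ws_lac$gene_id), ]

  lfc_min <- log2(thresholds$fold_change_min)
  wl_min <- log2(thresholds$wl_fold_min)
  p_max <- thresholds$p_max

  up_ws <- de_ws_glc$log2_fc >= lfc_min & de_ws_glc$p_value < p_max
  up_lac <- de_lac_glc$log2_fc >= lfc_min & de_lac_glc$p_value < p_max
  ws_gt_lac <- de_ws_lac$log2_fc >= wl_min & de_ws_lac$p_value < p_max
  lac_gt_ws <- -de_ws_lac$log2_fc >= wl_min & de_ws_lac$p_value < p_max

  group <- rep("NONE", length(ids))
  group[up_ws & !up_lac] <- "A"
  group[!up_ws & up_lac] <- "B"
  both <- up_ws & up_lac
  group[both] <- "E"
  group[both & ws_gt_lac] <- "C"
  group[both & lac_gt_ws] <- "D"
  group[ids %in% constitutive] <- "CONSTITUTIVE"

  data.frame(gene_id = ids,
             group = factor(group, levels = c("A", "B", "C", "D", "E",
                                              "CONSTITUTIVE", "NONE")),
             up_ws = up_ws, up_lac = up_lac,
             log2_fc_ws_glc = de_ws_glc$log2_fc, p_ws_glc = de_ws_glc$p_value,
             log2_fc_lac_glc = de_lac_glc$log2_fc, p_lac_glc = de_lac_glc$p_value,
             log2_fc_ws_lac = de_ws_lac$log2_fc, p_ws_lac = de_ws_lac$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full transcript-group pipeline on an expression matrix
#'
#' Convenience wrapper: computes the three glucose-referenced contrasts,
#' the constitutive set, and the classification in one call.
#'
#' @param x An [expr_matrix()] containing the three standard conditions.
#' @param thresholds A [transcript_thresholds()].
#' @param glucose,lactose,wheat_straw Condition labels.
#' @param method DE method, see [differential_expression()].
#' @return The classification data.frame of
#'   [classify_transcript_groups()].
#' @export
transcript_group_pipeline <- function(x,
                                      thresholds = transcript_thresholds(),
                                      glucose = "glucose",
                                      lactose = "lactose",
                                      wheat_straw = "wheat_straw",
                                      method = "t") {
  de_wg <- differential_expression(x, wheat_straw, glucose, method = method)
  de_lg <- differential_expression(x, lactose, glucose, method = method)
  de_wl <- differential_expression(x, wheat_straw, lactose, method = method)
  const <- find_constitutive(x, thresholds)
  classify_transcript_groups(de_wg, de_lg, de_wl, thresholds, const)
}

facet_membership <- function(annotation, facet) {
  switch(facet,
    funcat = {
      codes <- split_codes(annotation$funcat_codes)
      lv <- sort(unique(unlist(codes)))
      lapply(stats::setNames(lv, lv), function(code)
        annotation$gene_id[vapply(codes, function(v) code %in% v, logical(1))])
    },
    cazy_family = {
      fams <- split_codes(annotation$cazy_families)
      lv <- sort(unique(unlist(fams)))
      lapply(stats::setNames(lv, lv), function(fam)
        annotation$gene_id[vapply(fams, function(v) fam %in% v, logical(1))])
    },
    secreted_class = {
      sec <- annotation[annotation$secreted, , drop = FALSE]
      has_cazy <- nzchar(sec$cazy_families)
      list(CAZy = sec$gene_id[has_cazy],
           SSCP = sec$gene_id[!has_cazy & sec$sscp],
           unknown = sec$gene_id[!has_cazy & !sec$sscp & sec$unknown],
           other = sec$gene_id[!has_cazy & !sec$sscp & !sec$unknown])
    },
    stop("unknown facet: ", facet))
}

#' Cross-tabulate transcript groups by an annotation facet
#'
#' Produces the group-by-category count tables used to summarize the
#' classification: functional categories, CAZyme families, or secreted
#' protein classes, each against transcript groups A-E. Genes without any
#' annotation row are counted as `unannotated`; for the functional-category
#' facet, `unknown` and `orphan` rows are added from the corresponding
#' annotation flags.
#'
#' @param assignments Output of [classify_transcript_groups()].
#' @param annotation A gene annotation data.frame (see
#'   [generate_annotation()] for the column contract).
#' @param facet One of `"funcat"`, `"cazy_family"`, `"secreted_class"`.
#' @return A data.frame: one row per facet level plus an `all_genes` total
#'   row, columns A-E and `total`.
#' @export
crosstab_groups <- function(assignments, annotation,
                            facet = c("funcat", "cazy_family",
                                      "secreted_class")) {
  facet <- match.arg(facet)
  groups <- c("A", "B", "C", "D", "E")
  by_group <- lapply(stats::setNames(groups, groups), function(g)
    assignments$gene_id[assignments$group == g])

  count_row <- function(members) vapply(by_group, function(g)
    sum(g %in% members), integer(1))

  rows <- list(all_genes = vapply(by_group, length, integer(1)))
  if (nrow(annotation) == 0L) {
    rows$unannotated <- rows$all_genes
  } else {
    members <- facet_membership(annotation, facet)
    if (facet == "funcat") {
      rows$unknown_genes <- count_row(annotation$gene_id[annotation$unknown])
      rows$orphans <- count_row(annotation$gene_id[annotation$orphan])
    }
    for (lv in names(members)) rows[[lv]] <- count_row(members[[lv]])
    unann <- setdiff(assignments$gene_id, annotation$gene_id)
    if (length(unann)) rows$unannotated <- count_row(unann)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$total <- rowSums(out)
  cbind(data.frame(level = rownames(out), stringsAsFactors = FALSE),
        `rownames<-`(out, NULL))
}

#' Per-gene expression ratios for a panel of genes
#'
#' Reports, for each panel gene and each non-baseline condition, the linear
#' ratio of condition means (2^difference of log2 means) with the per-gene
#' DE p-value, and flags the genes passing the upregulation criterion.
#' Panel genes absent from the matrix are collected in a `missing`
#' attribute and reported with a warning rather than an error.
#'
#' @param x An [expr_matrix()].
#' @param panel Character vector of gene ids.
#' @param baseline Baseline condition label (default `"glucose"`).
#' @param thresholds A [transcript_thresholds()].
#' @param method DE method, see [differential_expression()].
#' @return A data.frame with columns `gene_id`, `condition`, `ratio`,
#'   `p_value`, `flagged`; attribute `missing` lists absent panel genes.
#' @export
panel_report <- function(x, panel, baseline = "glucose",
                         thresholds = transcript_thresholds(),
                         method = "t") {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(panel, gene_ids(x))
  if (length(missing))
    warning("panel genes absent from matrix: ",
            paste(missing, collapse = ", "))
  panel <- intersect(panel, gene_ids(x))
  others <- setdiff(conditions(x), baseline)
  out <- do.call(rbind, lapply(others, function(cond) {
    de <- differential_expression(x, cond, baseline, method = method)
    de <- de[match(panel, de$gene_id), ]
    data.frame(gene_id = panel, condition = cond,
               ratio = 2^de$log2_fc, p_value = de$p_value,
               flagged = de$log2_fc >= log2(thresholds$fold_change_min) &
                 de$p_value < thresholds$p_max,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "missing") <- missing
  out
}
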