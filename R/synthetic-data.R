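TRANSCRIPT_GROUPS <- c("A", "B", "C", "D", "E", "CONSTITUTIVE", "NONE")

DEFAULT_FUNCAT_VOCAB <- c(
  "01.01", "01.03", "01.06.01", "01.06.03", "01.20", "01.25.01",
  "02.01", "02.07", "02.10", "10.01", "10.03", "11.02.03.04", "12.04",
  "14.07.02", "20.01.01.01", "20.01.03", "20.09.16", "30.01.05", "32.07")

DEFAULT_CAZY_VOCAB <- c("GH3", "GH5", "GH7", "GH10", "GH11", "GH16",
                        "GH18", "GH27", "GH28", "GH55", "GH61", "CE5",
                        "CBM1")

DEFAULT_KOG_VOCAB <- c("J", "K", "O", "G", "E", "C", "T", "Z", "R", "S")

#' Design of a synthetic three-condition expression study
#'
#' Collects every parameter of the synthetic-data generators: a
#' three-condition (glucose reference, lactose, wheat straw) replicated
#' expression design with planted transcript groups, annotation labels
#' with controlled category enrichment, promoters with planted motif
#' sites, and qPCR Ct tables with known true ratios. The defaults emulate
#' the study conditions the pipeline targets: two replicate arrays per
#' condition, a 4-fold (2 log2 units) planted induction comfortably above
#' the 2-fold calling threshold, constitutive genes jittered well inside
#' the 1.4-fold band, and Gaussian log2 noise of 0.25.
#'
#' @param n_genes Number of genes.
#' @param conditions Three condition labels, reference first.
#' @param replicates_per_condition Replicates per condition (>= 2;
#'   default 2).
#' @param group_proportions Named fractions over
#'   A, B, C, D, E, CONSTITUTIVE, NONE; must sum to 1.
#' @param baseline_mean,baseline_sd Log2 baseline expression level and
#'   between-gene spread.
#' @param effect_size Planted log2 induction (default 2.0 = 4-fold).
#' @param within_band_jitter Half-width of the uniform log2 jitter applied
#'   per condition to constitutive genes; must stay below log2(1.4).
#' @param noise_sd Per-replicate Gaussian log2 noise sd.
#' @param expression_floor Log2 floor below which a gene counts as not
#'   expressed; NONE genes are planted at half the floor.
#' @param category_vocab,category_base_rate Functional-category codes and
#'   their baseline membership rate(s).
#' @param enriched_pairs List of `list(group =, category =,
#'   odds_multiplier =)` entries; the named group's membership odds for
#'   that category are multiplied accordingly.
#' @param annotation_rates Named rates for `secreted`, `sscp`, `cazy`,
#'   `orphan`, `unknown` flags.
#' @param cazy_vocab,kog_vocab Family / class vocabularies.
#' @param kog_rate Fraction of genes receiving a KOG letter.
#' @param promoter_length Promoter window length in bp.
#' @param planted_sites_per_promoter Named integer vector gene -> planted
#'   motif-site count; default draws Poisson counts at the genome density
#'   of one site per 1500 bp.
#' @param motif IUPAC motif to plant and purge (default `"GGCWWWW"`).
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param qpcr_true_ratios Named true expression ratios per target gene.
#' @param qpcr_samples Non-calibrator sample ids.
#' @param efficiencies Named amplification efficiencies in (1, 2];
#'   default 2 for every gene.
#' @param normalizer,calibrator Reference gene and reference sample.
#' @param ct_noise_sd Gaussian Ct noise sd in cycles (default 0.15).
#' @param qpcr_experiments,qpcr_replicates Independent runs and replicate
#'   reactions per run (defaults 2 and 3).
#' @param seed Integer seed governing all generators.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 1000,
                             conditions = c("glucose", "lactose",
                                            "wheat_straw"),
                             replicates_per_condition = 2,
                             group_proportions = c(A = 0.20, B = 0.10,
                                                   C = 0.10, D = 0.05,
                                                   E = 0.15,
                                                   CONSTITUTIVE = 0.15,
                                                   NONE = 0.25),
                             baseline_mean = 6, baseline_sd = 1,
                             effect_size = 2, within_band_jitter = 0.2,
                             noise_sd = 0.25, expression_floor = 1,
                             category_vocab = DEFAULT_FUNCAT_VOCAB,
                             category_base_rate = 0.02,
                             enriched_pairs = list(),
                             annotation_rates = c(secreted = 0.08,
                                                  sscp = 0.4,
                                                  cazy = 0.06,
                                                  orphan = 0.05,
                                                  unknown = 0.30),
                             cazy_vocab = DEFAULT_CAZY_VOCAB,
                             kog_vocab = DEFAULT_KOG_VOCAB,
                             kog_rate = 0.6,
                             promoter_length = 1000,
                             planted_sites_per_promoter = NULL,
                             motif = "GGCWWWW",
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             qpcr_true_ratios = c(target1 = 8, target2 = 4,
                                                  target3 = 0.5,
                                                  target4 = 1),
                             qpcr_samples = c("lac_24h", "ws_24h"),
                             efficiencies = NULL,
                             normalizer = "tef1", calibrator = "glc_8h",
                             ct_noise_sd = 0.15,
                             qpcr_experiments = 2, qpcr_replicates = 3,
                             seed = 1) {
  if (length(conditions) != 3L)
    stop("conditions must name exactly three conditions (reference first)")
  if (replicates_per_condition < 2L)
    stop("replicates_per_condition must be >= 2 (the DE stage needs >= 2)")
  if (!setequal(names(group_proportions), TRANSCRIPT_GROUPS) ||
      abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must cover A-E, CONSTITUTIVE, NONE and sum to 1")
  if (any(group_proportions < 0)) stop("group_proportions must be >= 0")
  if (effect_size <= log2(2))
    stop("effect_size must exceed log2(2) so planted groups are recoverable")
  if (within_band_jitter >= log2(1.4))
    stop("within_band_jitter must stay below log2(1.4)")
  if (abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1")
  if (is.null(efficiencies)) {
    efficiencies <- stats::setNames(
      rep(2, length(qpcr_true_ratios) + 1L),
      c(names(qpcr_true_ratios), normalizer))
  }
  if (any(efficiencies <= 1 | efficiencies > 2))
    stop("efficiencies must lie in (1, 2]")
  if (!normalizer %in% names(efficiencies))
    stop("missing normalizer gene '", normalizer, "' in efficiencies")
  motif <- check_motif(motif)
  if (promoter_length < nchar(motif))
    stop("promoter_length must be >= motif length")
  structure(
    list(n_genes = n_genes, conditions = conditions,
         replicates_per_condition = replicates_per_condition,
         group_proportions = group_proportions[TRANSCRIPT_GROUPS],
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         effect_size = effect_size, within_band_jitter = within_band_jitter,
         noise_sd = noise_sd, expression_floor = expression_floor,
         category_vocab = category_vocab,
         category_base_rate = category_base_rate,
         enriched_pairs = enriched_pairs,
         annotation_rates = annotation_rates,
         cazy_vocab = cazy_vocab, kog_vocab = kog_vocab,
         kog_rate = kog_rate,
         promoter_length = promoter_length,
         planted_sites_per_promoter = planted_sites_per_promoter,
         motif = motif, base_composition = base_composition,
         qpcr_true_ratios = qpcr_true_ratios, qpcr_samples = qpcr_samples,
         efficiencies = efficiencies, normalizer = normalizer,
         calibrator = calibrator, ct_noise_sd = ct_noise_sd,
         qpcr_experiments = qpcr_experiments,
         qpcr_replicates = qpcr_replicates, seed = seed),
    class = "synthetic_design")
}

exact_allocation <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base
}

#' Generate a synthetic expression matrix with planted transcript groups
#'
#' Draws per-gene true condition means according to the planted group
#' (see [synthetic_design()]): group A genes are induced on wheat straw
#' only, B on lactose only, C on both with wheat straw one effect size
#' higher, D the mirror image, E on both equally, constitutive genes sit
#' at baseline with a small per-condition jitter inside the 1.4-fold band,
#' and NONE genes lie below the expression floor everywhere. Replicate
#' values are true mean plus i.i.d. Gaussian log2 noise. Deterministic for
#' a fixed design seed.
#'
#' @param design A [synthetic_design()].
#' @return List with `matrix` (an [expr_matrix()]) and `truth` (list with
#'   `group`, a named factor of planted labels, and `true_means`).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n <- design$n_genes
  counts <- exact_allocation(n, design$group_proportions)
  groups <- sample(rep(names(counts), counts))
  ids <- sprintf("g%05d", seq_len(n))

  b <- stats::rnorm(n, design$baseline_mean, design$baseline_sd)
  e <- design$effect_size
  ref <- b; lac <- b; ws <- b
  ws[groups == "A"] <- b[groups == "A"] + e
  lac[groups == "B"] <- b[groups == "B"] + e
  lac[groups == "C"] <- b[groups == "C"] + e
  ws[groups == "C"] <- b[groups == "C"] + 2 * e
  lac[groups == "D"] <- b[groups == "D"] + 2 * e
  ws[groups == "D"] <- b[groups == "D"] + e
  lac[groups == "E"] <- b[groups == "E"] + e
  ws[groups == "E"] <- b[groups == "E"] + e
  is_const <- groups == "CONSTITUTIVE"
  j <- design$within_band_jitter
  if (any(is_const)) {
    nc <- sum(is_const)
    jit <- function() stats::runif(nc, -j, j)
    ref[is_const] <- b[is_const] + jit()
    lac[is_const] <- b[is_const] + jit()
    ws[is_const] <- b[is_const] + jit()
  }
  off <- groups == "NONE"
  floor_val <- design$expression_floor / 2
  ref[off] <- floor_val; lac[off] <- floor_val; ws[off] <- floor_val

  true_means <- cbind(ref, lac, ws)
  dimnames(true_means) <- list(ids, design$conditions)

  k <- design$replicates_per_condition
  cond_vec <- rep(design$conditions, each = k)
  rep_vec <- rep(seq_len(k), times = 3L)
  vals <- matrix(NA_real_, n, 3L * k)
  for (jcol in seq_along(cond_vec)) {
    vals[, jcol] <- true_means[, cond_vec[jcol]] +
      stats::rnorm(n, 0, design$noise_sd)
  }
  rownames(vals) <- ids
  list(matrix = expr_matrix(vals, cond_vec, rep_vec),
       truth = list(group = stats::setNames(groups, ids),
                    true_means = true_means))
}

enrichment_odds_multiplier <- function(design, group, category) {
  m <- 1
  for (pair in design$enriched_pairs) {
    if (pair$group == group && pair$category == category)
      m <- m * pair$odds_multiplier
  }
  m
}

#' Generate a synthetic gene annotation table
#'
#' Baseline category membership is independent of transcript group; for
#' every enriched pair in the design the membership odds of that group's
#' genes are multiplied by the pair's odds multiplier (base probability p
#' becomes `o*m/(1 + o*m)` with `o = p/(1-p)`). Secreted/SSCP/CAZy/orphan/
#' unknown flags are drawn at the design's rates (SSCP only among secreted
#' genes). Deterministic for a fixed design seed.
#'
#' @param design A [synthetic_design()].
#' @param truth Ground truth from [generate_expression()] (the planted
#'   group of every gene).
#' @return data.frame with columns `gene_id`, `funcat_codes`
#'   (semicolon-separated), `kog_class`, `cazy_families`, `secreted`,
#'   `sscp`, `orphan`, `unknown`, `display_name`.
#' @export
generate_annotation <- function(design, truth) {
  stopifnot(inherits(design, "synthetic_design"))
  known <- c(design$category_vocab, design$cazy_vocab, design$kog_vocab)
  for (pair in design$enriched_pairs) {
    if (!pair$category %in% known)
      stop("unknown category code in enriched_pairs: ", pair$category)
    if (!pair$group %in% TRANSCRIPT_GROUPS)
      stop("unknown group in enriched_pairs: ", pair$group)
  }
  set.seed(design$seed + 1L)
  genes <- names(truth$group)
  groups <- as.character(truth$group)
  n <- length(genes)

  member_prob <- function(base, category) {
    p <- rep(base, n)
    for (pair in design$enriched_pairs) {
      if (pair$category == category) {
        o <- base / (1 - base) * pair$odds_multiplier
        p[groups == pair$group] <- o / (1 + o)
      }
    }
    p
  }

  base_rates <- design$category_base_rate
  if (length(base_rates) == 1L)
    base_rates <- stats::setNames(rep(base_rates,
                                      length(design$category_vocab)),
                                  design$category_vocab)
  funcat <- rep("", n)
  for (cat in design$category_vocab) {
    hit <- stats::rbinom(n, 1L, member_prob(base_rates[[cat]], cat)) == 1L
    funcat[hit] <- ifelse(funcat[hit] == "", cat,
                          paste(funcat[hit], cat, sep = ";"))
  }

  kog <- rep("", n)
  has_kog <- stats::runif(n) < design$kog_rate
  kog[has_kog] <- sample(design$kog_vocab, sum(has_kog), replace = TRUE)
  kog_pairs <- Filter(function(p) p$category %in% design$kog_vocab,
                      design$enriched_pairs)
  for (pair in kog_pairs) {
    base <- design$kog_rate / length(design$kog_vocab)
    o <- base / (1 - base) * pair$odds_multiplier
    idx <- which(groups == pair$group)
    hit <- stats::rbinom(length(idx), 1L, o / (1 + o)) == 1L
    kog[idx[hit]] <- pair$category
  }

  rates <- design$annotation_rates
  is_cazy <- stats::runif(n) < rates[["cazy"]]
  cazy <- rep("", n)
  cazy[is_cazy] <- sample(design$cazy_vocab, sum(is_cazy), replace = TRUE)
  for (pair in Filter(function(p) p$category %in% design$cazy_vocab,
                      design$enriched_pairs)) {
    base <- rates[["cazy"]] / length(design$cazy_vocab)
    o <- base / (1 - base) * pair$odds_multiplier
    idx <- which(groups == pair$group)
    hit <- stats::rbinom(length(idx), 1L, o / (1 + o)) == 1L
    cazy[idx[hit]] <- pair$category
  }

  secreted <- stats::runif(n) < rates[["secreted"]] | is_cazy
  sscp <- secreted & !is_cazy & stats::runif(n) < rates[["sscp"]]
  orphan <- stats::runif(n) < rates[["orphan"]]
  unknown <- !orphan & funcat == "" & stats::runif(n) < rates[["unknown"]]

  data.frame(gene_id = genes, funcat_codes = funcat, kog_class = kog,
             cazy_families = cazy, secreted = secreted, sscp = sscp,
             orphan = orphan, unknown = unknown, display_name = genes,
             row.names = NULL, stringsAsFactors = FALSE)
}

concretize_motif <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1L]], function(ch) {
    opts <- IUPAC_SETS[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

random_nonoverlapping_starts <- function(n_sites, L, k) {
  # uniform choice of n non-overlapping length-k intervals in 1..L
  t_ <- sort(sample.int(L - n_sites * k + n_sites, n_sites))
  t_ + (seq_len(n_sites) - 1L) * (k - 1L)
}

purge_motif <- function(seq, motif, bases, probs, max_iter = 50L) {
  k <- nchar(motif)
  for (i in seq_len(max_iter)) {
    hits <- scan_sequence(seq, motif, strands = "both",
                          prevent_overlap = FALSE)
    if (nrow(hits) == 0L) return(seq)
    chars <- strsplit(seq, "")[[1L]]
    for (s in unique(hits$start)) {
      chars[s:(s + k - 1L)] <- sample(bases, k, replace = TRUE, prob = probs)
    }
    seq <- paste(chars, collapse = "")
  }
  stop("could not purge motif matches from background sequence")
}

#' Generate promoters with planted motif sites
#'
#' For each gene, draws a background sequence from the design's base
#' composition with every motif-matching window (either strand) rejected
#' and resampled, then inserts exactly the requested number of
#' non-overlapping motif instances at uniformly chosen positions. The
#' construction is verified by re-scanning: [scan_promoters()] on the
#' output returns exactly the planted counts at the planted positions.
#'
#' @param design A [synthetic_design()]. `planted_sites_per_promoter` may
#'   name any subset of genes; the default draws Poisson counts at one
#'   site per 1500 bp for all `n_genes` genes.
#' @return List with `promoters` (named uppercase character vector) and
#'   `truth` (list with `counts` and `positions`, 1-based starts).
#' @export
generate_promoters <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed + 2L)
  L <- design$promoter_length
  motif <- design$motif
  k <- nchar(motif)
  planted <- design$planted_sites_per_promoter
  if (is.null(planted)) {
    ids <- sprintf("g%05d", seq_len(design$n_genes))
    planted <- stats::setNames(
      pmin(stats::rpois(length(ids), L / 1500), L %/% k), ids)
  }
  bases <- names(design$base_composition)
  probs <- unname(design$base_composition)
  proms <- character(length(planted))
  positions <- vector("list", length(planted))
  names(proms) <- names(positions) <- names(planted)
  for (g in names(planted)) {
    n_sites <- planted[[g]]
    if (n_sites * k > L)
      stop("requested sites cannot fit without overlap for gene ", g)
    ok <- FALSE
    for (attempt in 1:100) {
      seq <- paste(sample(bases, L, replace = TRUE, prob = probs),
                   collapse = "")
      seq <- purge_motif(seq, motif, bases, probs)
      starts <- integer()
      if (n_sites > 0L) {
        starts <- random_nonoverlapping_starts(n_sites, L, k)
        chars <- strsplit(seq, "")[[1L]]
        for (s in starts) {
          chars[s:(s + k - 1L)] <- strsplit(concretize_motif(motif),
                                            "")[[1L]]
        }
        seq <- paste(chars, collapse = "")
      }
      found <- scan_sequence(seq, motif, strands = "both",
                             prevent_overlap = TRUE)
      if (nrow(found) == n_sites &&
          identical(sort(found$start), sort(starts))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to construct promoter for gene ", g)
    proms[[g]] <- seq
    positions[[g]] <- starts
  }
  list(promoters = proms,
       truth = list(counts = planted, positions = positions))
}

#' Generate synthetic qPCR Ct tables with known true ratios
#'
#' Inverts the efficiency-corrected ratio model: normalizer Cts are flat
#' across samples, and each target's sample Ct is offset from its
#' calibrator Ct by `-log(ratio)/log(E)`, so that [pfaffl_ratio()] on
#' noiseless output recovers the planted ratios exactly. Gaussian noise of
#' `ct_noise_sd` cycles is added per replicate reaction, for
#' `qpcr_experiments` independent runs of `qpcr_replicates` reactions.
#'
#' @param design A [synthetic_design()].
#' @return List with `experiment` (a [qpcr_experiment()]) and `truth`
#'   (the planted ratios).
#' @export
generate_qpcr <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed + 3L)
  ratios <- design$qpcr_true_ratios
  eff <- design$efficiencies
  samples <- c(design$calibrator, design$qpcr_samples)
  cond_of <- function(s) {
    if (s == design$calibrator) "glucose"
    else if (startsWith(s, "lac")) "lactose"
    else if (startsWith(s, "ws")) "wheat_straw"
    else "unknown"
  }
  time_of <- function(s) {
    t <- suppressWarnings(as.numeric(sub("^.*_([0-9.]+)h$", "\\1", s)))
    if (is.na(t)) NA_real_ else t
  }
  rows <- list()
  base_ct <- c(stats::setNames(rep(22, length(ratios)), names(ratios)),
               stats::setNames(20, design$normalizer))
  for (s in samples) {
    for (g in c(names(ratios), design$normalizer)) {
      true_ct <- base_ct[[g]]
      if (g != design$normalizer && s != design$calibrator)
        true_ct <- true_ct - log(ratios[[g]]) / log(eff[[g]])
      for (ex in seq_len(design$qpcr_experiments)) {
        reps <- true_ct + stats::rnorm(design$qpcr_replicates, 0,
                                       design$ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, condition = cond_of(s), time_h = time_of(s),
          gene = g, ct = reps, experiment = ex,
          stringsAsFactors = FALSE)
      }
    }
  }
  meas <- do.call(rbind, rows)
  list(experiment = qpcr_experiment(meas, eff, design$normalizer,
                                    design$calibrator),
       truth = list(ratios = ratios))
}

#' Write / read annotation tables
#'
#' TSV round trip for the annotation contract of [generate_annotation()].
#'
#' @param annotation Annotation data.frame.
#' @param path File path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   funcat_codes = "character",
                                   kog_class = "character",
                                   cazy_families = "character",
                                   secreted = "logical",
                                   sscp = "logical",
                                   orphan = "logical",
                                   unknown = "logical",
                                   display_name = "character"),
                    na.strings = NULL)
}

#' Write / read promoter FASTA
#'
#' @param promoters Named character vector of promoter sequences.
#' @param path FASTA path.
#' @return `path` invisibly (write) or a named character vector (read).
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read qPCR measurement tables
#'
#' TSV with one row per replicate reaction plus per-row efficiency; the
#' reader reconstructs a [qpcr_experiment()].
#'
#' @param exp A `qpcr_experiment`.
#' @param path File path.
#' @param normalizer,calibrator Designations for the reader.
#' @return `path` invisibly (write) or a `qpcr_experiment` (read).
#' @export
write_qpcr <- function(exp, path) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  m <- exp$measurements
  m$efficiency <- unname(exp$efficiencies[m$gene])
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path, normalizer = "tef1", calibrator = "glc_8h") {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  eff <- tapply(m$efficiency, m$gene, function(v) v[1L])
  m$efficiency <- NULL
  qpcr_experiment(m, stats::setNames(as.numeric(eff), names(eff)),
                  normalizer, calibrator)
}

#' Write ground truth as JSON
#'
#' @param truth A ground-truth list from any generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
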