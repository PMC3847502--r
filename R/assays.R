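#' Construct a qPCR experiment object
#'
#' Container for Ct measurements with per-primer amplification
#' efficiencies, a normalizer (reference) gene and a calibrator sample.
#' The standard design is two independent experiments with three replicate
#' reactions each, every sample measured for the normalizer.
#'
#' @param measurements data.frame with columns `sample_id`, `condition`,
#'   `time_h`, `gene`, `ct`, `experiment` (one row per replicate
#'   reaction).
#' @param efficiencies Named numeric vector, gene -> amplification
#'   efficiency E in (1, 2.2].
#' @param normalizer Reference gene (default `"tef1"`).
#' @param calibrator Reference sample id (default `"glc_8h"`, a glucose
#'   8 h culture).
#' @return An object of class `qpcr_experiment`.
#' @export
qpcr_experiment <- function(measurements, efficiencies,
                            normalizer = "tef1", calibrator = "glc_8h") {
  need <- c("sample_id", "condition", "time_h", "gene", "ct", "experiment")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(measurements$ct <= 0 | measurements$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  if (!normalizer %in% measurements$gene)
    stop("normalizer gene '", normalizer, "' has no measurements")
  if (!normalizer %in% names(efficiencies))
    stop("no efficiency for normalizer gene")
  if (any(efficiencies <= 1 | efficiencies > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  for (s in unique(measurements$sample_id)) {
    if (!any(measurements$gene == normalizer & measurements$sample_id == s))
      stop("sample '", s, "' lacks normalizer Cts")
  }
  structure(list(measurements = measurements, efficiencies = efficiencies,
                 normalizer = normalizer, calibrator = calibrator),
            class = "qpcr_experiment")
}

#' @export
print.qpcr_experiment <- function(x, ...) {
  cat(sprintf(
    "qpcr_experiment: %d measurements, %d genes, normalizer %s, calibrator %s\n",
    nrow(x$measurements), length(unique(x$measurements$gene)),
    x$normalizer, x$calibrator))
  invisible(x)
}

cts_of <- function(exp, gene, sample) {
  m <- exp$measurements
  v <- m$ct[m$gene == gene & m$sample_id == sample]
  if (!length(v)) stop("no Ct values for gene '", gene, "', sample '",
                       sample, "'")
  v
}

pfaffl_from_means <- function(e_g, e_n, ct_g_cal, ct_g_smp,
                              ct_n_cal, ct_n_smp) {
  e_g^(ct_g_cal - ct_g_smp) / e_n^(ct_n_cal - ct_n_smp)
}

#' Efficiency-corrected relative expression ratio
#'
#' The efficiency-corrected relative-expression model: the ratio of a
#' target gene in a sample versus the calibrator, normalized to the
#' reference gene,
#' `R = E_gene^(Ct_cal - Ct_sample) / E_norm^(Ct_cal - Ct_sample)`,
#' computed from replicate-mean Cts. The standard error is obtained by
#' resampling replicate combinations (bootstrap over the four replicate
#' groups, sd of the log2 ratios back-transformed).
#'
#' @param exp A [qpcr_experiment()].
#' @param gene Target gene.
#' @param sample Sample id.
#' @param n_boot Bootstrap resamples for the standard error (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return List with `gene`, `sample`, `ratio`, `se` (standard error on
#'   the linear ratio scale), `log2_ratio`.
#' @export
pfaffl_ratio <- function(exp, gene, sample, n_boot = 500, seed = 1) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  e_g <- exp$efficiencies[[gene]]
  e_n <- exp$efficiencies[[exp$normalizer]]
  if (is.null(e_g)) stop("no efficiency for gene '", gene, "'")
  g_cal <- cts_of(exp, gene, exp$calibrator)
  g_smp <- cts_of(exp, gene, sample)
  n_cal <- cts_of(exp, exp$normalizer, exp$calibrator)
  n_smp <- cts_of(exp, exp$normalizer, sample)
  ratio <- pfaffl_from_means(e_g, e_n, mean(g_cal), mean(g_smp),
                             mean(n_cal), mean(n_smp))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    r <- pfaffl_from_means(
      e_g, e_n,
      mean(sample(g_cal, replace = TRUE)),
      mean(sample(g_smp, replace = TRUE)),
      mean(sample(n_cal, replace = TRUE)),
      mean(sample(n_smp, replace = TRUE)))
    log2(r)
  }, numeric(1))
  se <- ratio * log(2) * stats::sd(boots)  # delta method back-transform
  list(gene = gene, sample = sample, ratio = ratio, se = se,
       log2_ratio = log2(ratio))
}

#' Fixed-reallocation randomization test for a qPCR ratio
#'
#' Tests the null hypothesis ratio = 1 for a sample-vs-calibrator
#' comparison by randomly reallocating replicate observations between the
#' two groups. Target and normalizer Cts of the same replicate reaction
#' move together (they come from the same cDNA), which preserves the
#' within-replicate pairing under the null. The two-sided p-value is the
#' fraction of reallocations with an absolute log ratio at least as
#' extreme as observed, with the `(1 + c)/(n_iter + 1)` small-sample
#' correction.
#'
#' With m and c replicates there are only `choose(m + c, m)` distinct
#' allocations, so the attainable p-value floor is about
#' `2 / choose(m + c, m)`; with fewer than ~5 replicates per group the
#' test cannot reach p < 0.05.
#'
#' @param exp A [qpcr_experiment()].
#' @param gene Target gene.
#' @param sample Sample id (compared against the calibrator).
#' @param n_iter Number of random reallocations (default 2000).
#' @param seed RNG seed.
#' @return List with `p_value`, `ratio`, `n_iter`.
#' @export
rest_randomization_test <- function(exp, gene, sample, n_iter = 2000,
                                    seed = 1) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  e_g <- exp$efficiencies[[gene]]
  e_n <- exp$efficiencies[[exp$normalizer]]
  g_cal <- cts_of(exp, gene, exp$calibrator)
  g_smp <- cts_of(exp, gene, sample)
  n_cal <- cts_of(exp, exp$normalizer, exp$calibrator)
  n_smp <- cts_of(exp, exp$normalizer, sample)
  if (length(g_smp) < 3L || length(g_cal) < 3L)
    stop("need >=3 replicates per group")
  if (length(g_cal) != length(n_cal) || length(g_smp) != length(n_smp))
    stop("target and normalizer replicate counts must match within groups")

  r_obs <- pfaffl_from_means(e_g, e_n, mean(g_cal), mean(g_smp),
                             mean(n_cal), mean(n_smp))
  obs <- abs(log(r_obs))
  gg <- c(g_cal, g_smp)
  nn <- c(n_cal, n_smp)
  m_cal <- length(g_cal)
  total <- length(gg)
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_iter)) {
    idx <- sample.int(total)
    cal_i <- idx[seq_len(m_cal)]
    smp_i <- idx[-seq_len(m_cal)]
    r <- pfaffl_from_means(e_g, e_n, mean(gg[cal_i]), mean(gg[smp_i]),
                           mean(nn[cal_i]), mean(nn[smp_i]))
    if (abs(log(r)) >= obs - 1e-12) cnt <- cnt + 1L
  }
  list(p_value = (cnt + 1) / (n_iter + 1), ratio = r_obs, n_iter = n_iter)
}

#' Amplification efficiency from a dilution series
#'
#' Ordinary least-squares fit of Ct against log10 relative template input;
#' the amplification efficiency is `E = 10^(-1/slope)` (E = 2 is perfect
#' doubling, slope -3.32).
#'
#' @param ct Numeric vector of Ct values.
#' @param dilution Relative template amounts (e.g. 1, 0.1, 0.01), same
#'   length as `ct`; triplicate points at each level are the usual design.
#' @return List with `slope`, `efficiency`, `r_squared`.
#' @export
fit_efficiency <- function(ct, dilution) {
  if (length(unique(dilution)) < 3L)
    stop("need >=3 distinct dilution levels")
  fit <- stats::lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid assay: Ct does not decrease with template input (slope ",
         format(slope), ")")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  list(slope = slope, efficiency = 10^(-1 / slope),
       r_squared = 1 - ss_res / ss_tot)
}

#' Welch unequal-variance t-test
#'
#' The Welch two-sample statistic
#' `t = (m_a - m_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Degenerate conventions: both variances zero with equal means gives
#' p = 1; with different means p = 0 (flagged with a warning).
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >=2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (abs(ma - mb) < 1e-12) return(list(t = 0, df = na + nb - 2,
                                          p_value = 1))
    warning("both variances zero with different means; p = 0 by convention")
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p_value = 0))
  }
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}

#' Biomass dry weight from intracellular protein
#'
#' Converts a protein measurement, corrected by an uninoculated substrate
#' control, into biomass dry weight using a fixed intracellular protein
#' content (default 0.35 g protein per g dry cell mass). Negative
#' corrected values are floored at zero with a warning.
#'
#' @param protein Protein concentration, g/L (vectorized).
#' @param control Substrate-control protein concentration, g/L.
#' @param protein_per_dry_mass Conversion constant, g protein per g dry
#'   mass (default 0.35).
#' @return Dry weight, g/L.
#' @export
biomass_from_protein <- function(protein, control = 0,
                                 protein_per_dry_mass = 0.35) {
  if (any(protein < 0) || any(control < 0)) stop("inputs must be non-negative")
  corrected <- protein - control
  if (any(corrected < 0)) {
    warning("control exceeds protein for some samples; dry weight set to 0")
    corrected <- pmax(0, corrected)
  }
  corrected / protein_per_dry_mass
}
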