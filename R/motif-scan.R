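IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

check_motif <- function(motif) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  letters_ <- strsplit(toupper(motif), "")[[1L]]
  bad <- setdiff(letters_, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ""))
  paste(letters_, collapse = "")
}

# All candidate match start positions (1-based) of an IUPAC motif on one
# strand of a plus-strand sequence. A subject 'N' matches only a motif 'N'.
iupac_match_starts <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer())
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                fixed = FALSE)
  starts <- Biostrings::start(m)
  if (!length(starts)) return(starts)
  mot <- strsplit(motif, "")[[1L]]
  non_n <- which(mot != "N")
  keep <- vapply(starts, function(s) {
    win <- strsplit(substr(seq, s, s + length(mot) - 1L), "")[[1L]]
    !any(win[non_n] == "N")
  }, logical(1))
  starts[keep]
}

scan_sequence <- function(seq, motif, strands = "both",
                          prevent_overlap = TRUE) {
  seq <- toupper(seq)
  k <- nchar(motif)
  plus <- iupac_match_starts(seq, motif)
  cand <- data.frame(start = plus,
                     strand = rep("+", length(plus)),
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rc_motif <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    minus <- iupac_match_starts(seq, rc_motif)
    cand <- rbind(cand, data.frame(start = minus,
                                   strand = rep("-", length(minus)),
                                   stringsAsFactors = FALSE))
  }
  # greedy left-to-right; '+' wins ties at the same coordinate
  cand <- cand[order(cand$start, cand$strand), , drop = FALSE]
  if (prevent_overlap && nrow(cand) > 1L) {
    keep <- logical(nrow(cand))
    last_end <- -1L
    for (i in seq_len(nrow(cand))) {
      if (cand$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- cand$start[i] + k - 1L
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Scan promoter windows for a degenerate motif
#'
#' Counts non-overlapping matches of an IUPAC motif (default the
#' XYR1-binding consensus `GGCWWWW`, i.e. GGC followed by four A/T) in
#' each promoter. Matching is greedy left to right: a new match may not
#' overlap a previously accepted one, and with `strands = "both"` the
#' non-overlap constraint is enforced across strands on shared
#' coordinates. A sequence `N` matches only a motif `N`.
#'
#' @param promoters Named character vector of uppercase promoter sequences
#'   (or a `Biostrings::DNAStringSet`), e.g. from [extract_promoters()] or
#'   [generate_promoters()].
#' @param motif IUPAC motif string (default `"GGCWWWW"`).
#' @param strands `"both"` (default) or `"given"` (plus strand only).
#' @param prevent_overlap Enforce non-overlapping matches (default `TRUE`).
#' @return A data.frame with one row per promoter: `gene_id`, `count`,
#'   `window_length`, `positions` (semicolon-separated `offset:strand`
#'   pairs, 0-based offsets from the window start), and
#'   `upstream_positions` (the same sites as negative offsets relative to
#'   the translation start, window-end anchored).
#' @export
scan_promoters <- function(promoters, motif = "GGCWWWW",
                           strands = c("both", "given"),
                           prevent_overlap = TRUE) {
  strands <- match.arg(strands)
  motif <- check_motif(motif)
  if (methods::is(promoters, "DNAStringSet"))
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop("promoters must be uniquely named by gene id")
  rows <- lapply(names(promoters), function(g) {
    seq <- promoters[[g]]
    hits <- scan_sequence(seq, motif, strands, prevent_overlap)
    L <- nchar(seq)
    data.frame(
      gene_id = g, count = nrow(hits), window_length = L,
      positions = paste(sprintf("%d:%s", hits$start - 1L, hits$strand),
                        collapse = ";"),
      upstream_positions = paste(sprintf("%d:%s", hits$start - 1L - L,
                                         hits$strand), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean motif-site count per gene
#'
#' @param results Output of [scan_promoters()].
#' @return Arithmetic mean of the per-promoter counts.
#' @export
average_sites_per_gene <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    stop("no scan results to average")
  mean(results$count)
}

#' Extract fixed-length promoter windows from a genome
#'
#' Returns, for each gene, the `window` bases immediately 5' of the
#' translation start (positions -window..-1, excluding the ATG itself).
#' For minus-strand genes this is the reverse complement of the bases
#' immediately 3' (in genome coordinates) of the start position. Windows
#' truncated at a contig edge are returned shorter and flagged.
#'
#' @param genome Named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param coords data.frame with columns `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`) and `start_codon_pos`: the 1-based genomic coordinate of
#'   the first base of the start codon in transcript orientation (for
#'   minus-strand genes, the larger genomic coordinate of the codon).
#' @param window Window length in bp (default 1000).
#' @return Named character vector of promoter sequences with a
#'   `truncated` attribute (data.frame of `gene_id`, `length`,
#'   `truncated`).
#' @export
extract_promoters <- function(genome, coords, window = 1000) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  names(genome) <- sub("\\s.*$", "", names(genome))
  need <- c("gene_id", "contig", "strand", "start_codon_pos")
  if (!all(need %in% names(coords)))
    stop("coords must have columns: ", paste(need, collapse = ", "))
  out <- character(nrow(coords))
  trunc <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    g <- coords$gene_id[i]
    if (!coords$contig[i] %in% names(genome))
      stop("unknown contig for gene ", g, ": ", coords$contig[i])
    ctg <- genome[[coords$contig[i]]]
    len <- nchar(ctg)
    pos <- coords$start_codon_pos[i]
    if (pos < 1L || pos > len)
      stop("gene ", g, " start position off contig")
    if (coords$strand[i] == "+") {
      from <- max(1L, pos - window)
      if (pos == 1L) { out[i] <- ""; trunc[i] <- TRUE }
      else {
        out[i] <- substr(ctg, from, pos - 1L)
        trunc[i] <- from > pos - window
      }
    } else {
      to <- min(len, pos + window)
      if (pos == len) { out[i] <- ""; trunc[i] <- TRUE }
      else {
        fwd <- substr(ctg, pos + 1L, to)
        out[i] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(fwd)))
        trunc[i] <- to < pos + window
      }
    }
  }
  names(out) <- coords$gene_id
  attr(out, "truncated") <- data.frame(gene_id = coords$gene_id,
                                       length = nchar(out),
                                       truncated = trunc,
                                       stringsAsFactors = FALSE)
  out
}

#' Expected genome spacing between motif sites
#'
#' Given a genome-wide site census, the mean distance between consecutive
#' sites under a uniform-density model: `genome_length / total_sites`.
#' Reported raw and rounded to the nearest 500 bp (the precision at which
#' such densities are usually quoted).
#'
#' @param genome_length Genome length in bp.
#' @param total_sites Genome-wide number of motif sites.
#' @return List with `raw_bp` and `rounded_bp`.
#' @export
expected_spacing <- function(genome_length, total_sites) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (total_sites <= 0) stop("total_sites must be positive")
  raw <- genome_length / total_sites
  list(raw_bp = raw, rounded_bp = round(raw / 500) * 500)
}

#' Genome-density null model for per-window site counts
#'
#' Converts a genome-wide motif census into the Poisson rate expected for
#' a promoter window of the given length: windows are treated as random
#' genome intervals, so counts are Poisson with mean
#' `window_length / (genome_length / total_sites)`.
#'
#' @param genome_length Genome length in bp.
#' @param total_sites Genome-wide number of motif sites.
#' @param window_length Promoter window length in bp (default 1000).
#' @return List of class `spacing_null` with `expected_spacing_bp` and
#'   `lambda_per_window`.
#' @export
spacing_null <- function(genome_length, total_sites, window_length = 1000) {
  sp <- expected_spacing(genome_length, total_sites)
  structure(list(genome_length = genome_length, total_sites = total_sites,
                 window_length = window_length,
                 expected_spacing_bp = sp$raw_bp,
                 lambda_per_window = window_length / sp$raw_bp),
            class = "spacing_null")
}

# Tie-adjusted two-sample Anderson-Darling machinery. For sets of equal
# size g (observed + n_sim simulated), the statistic of each set against
# the pool of all others is computed in one vectorized pass: the combined
# sample of any such comparison is always the grand total, so the combined
# midranks are shared.
ad2_from_tabs <- function(tabs, total) {
  N <- sum(total)
  n1 <- rowSums(tabs)
  n2 <- N - n1
  l <- total
  B <- cumsum(l) - l / 2
  denom <- B * (N - B) - N * l / 4
  use <- l > 0 & denom > 0
  if (!any(use)) return(rep(0, nrow(tabs)))
  M1 <- t(apply(tabs, 1L, cumsum)) - tabs / 2
  M2 <- matrix(B, nrow(tabs), length(B), byrow = TRUE) - M1
  w <- l / N
  Bm <- matrix(B, nrow(tabs), length(B), byrow = TRUE)
  wm <- matrix(w, nrow(tabs), length(w), byrow = TRUE)
  dm <- matrix(denom, nrow(tabs), length(denom), byrow = TRUE)
  inner1 <- wm * (N * M1 - n1 * Bm)^2 / dm
  inner2 <- wm * (N * M2 - n2 * Bm)^2 / dm
  s1 <- rowSums(inner1[, use, drop = FALSE])
  s2 <- rowSums(inner2[, use, drop = FALSE])
  (N - 1) / N * (s1 / n1 + s2 / n2)
}

#' Two-sample Anderson-Darling statistic with tie adjustment
#'
#' The rank-based two-sample Anderson-Darling statistic in its
#' tie-adjusted (midrank) form, suitable for discrete data such as
#' per-window motif counts. Returns the raw statistic (expectation k-1 = 1
#' under the null).
#'
#' @param x,y Numeric vectors (the two samples).
#' @return The statistic (a single number; 0 when the pooled sample is
#'   constant).
#' @export
ad_2sample <- function(x, y) {
  vals <- sort(unique(c(x, y)))
  if (length(vals) < 2L) return(0)
  tx <- vapply(vals, function(v) sum(x == v), numeric(1))
  ty <- vapply(vals, function(v) sum(y == v), numeric(1))
  ad2_from_tabs(matrix(tx, nrow = 1L), tx + ty)[1L]
}

#' Test motif-site counts against the genome-density null
#'
#' Compares observed per-promoter site counts with the Poisson count
#' distribution implied by the genome-wide site density. `n_sim` replicate
#' count sets of the same size are drawn from
#' Poisson(`lambda_per_window`); the tie-adjusted two-sample
#' Anderson-Darling statistic of the observed set against the pooled
#' simulated sets is referred to the exchangeable null distribution of the
#' same statistic computed for each simulated set against the pool of the
#' others, giving an exact Monte-Carlo p-value
#' `(1 + #(T_sim >= T_obs)) / (n_sim + 1)`.
#'
#' @param observed Integer vector of observed per-promoter counts.
#' @param null A [spacing_null()].
#' @param n_sim Number of simulated replicate sets (>= 999 for useful p
#'   resolution; default 999).
#' @param seed RNG seed.
#' @param alpha Decision level (default 0.05).
#' @return List with `statistic`, `p_value`, `lambda_per_window`,
#'   `observed_mean`, `expected_mean`, `reject`.
#' @export
density_significance <- function(observed, null, n_sim = 999, seed = 1,
                                 alpha = 0.05) {
  stopifnot(inherits(null, "spacing_null"))
  if (n_sim < 999) stop("n_sim must be >= 999 for p-value resolution")
  lambda <- null$lambda_per_window
  if (lambda <= 0) stop("lambda_per_window must be positive")
  g <- length(observed)
  if (g < 1L) stop("no observed counts")
  set.seed(seed)
  sims <- matrix(stats::rpois(n_sim * g, lambda), nrow = n_sim)
  maxv <- max(observed, sims)
  vals <- 0:maxv
  tab_of <- function(v) vapply(vals, function(z) sum(v == z), numeric(1))
  tabs <- rbind(tab_of(observed),
                t(apply(sims, 1L, tab_of)))
  total <- colSums(tabs)
  stats_all <- ad2_from_tabs(tabs, total)
  t_obs <- stats_all[1L]
  t_null <- stats_all[-1L]
  p <- (1 + sum(t_null >= t_obs)) / (n_sim + 1)
  list(statistic = t_obs, p_value = p, lambda_per_window = lambda,
       observed_mean = mean(observed), expected_mean = lambda,
       reject = p < alpha)
}
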