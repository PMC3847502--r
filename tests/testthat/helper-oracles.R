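# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles rather than calling package
# internals.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")

bf_revcomp <- function(s) {
  paste(rev(RC_MAP[strsplit(s, "")[[1L]]]), collapse = "")
}

bf_window_matches <- function(win, motif) {
  wc <- strsplit(win, "")[[1L]]
  mc <- strsplit(motif, "")[[1L]]
  for (i in seq_along(mc)) {
    if (wc[i] == "N") {
      if (mc[i] != "N") return(FALSE)
    } else if (!wc[i] %in% IUPAC_ORACLE[[mc[i]]]) return(FALSE)
  }
  TRUE
}

# Greedy left-to-right non-overlapping count; '+' wins ties at a position.
bf_scan_count <- function(seq, motif, strands = "both") {
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) return(0L)
  rc <- bf_revcomp(motif)
  count <- 0L
  last_end <- 0L
  for (s in seq_len(L - k + 1L)) {
    if (s <= last_end) next
    win <- substr(seq, s, s + k - 1L)
    hit <- bf_window_matches(win, motif) ||
      (strands == "both" && bf_window_matches(win, rc))
    if (hit) {
      count <- count + 1L
      last_end <- s + k - 1L
    }
  }
  count
}

# Pearson chi-square on a 2x2 table from Sum (O-E)^2 / E over the 4 cells.
bf_chi2 <- function(a, b, c_, d) {
  obs <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
  n <- sum(obs)
  e <- outer(rowSums(obs), colSums(obs)) / n
  if (any(e == 0)) return(0)
  sum((obs - e)^2 / e)
}

# O(n^3) agglomerative clustering; returns sorted merge heights.
bf_linkage_heights <- function(points, linkage = "average") {
  clusters <- lapply(seq_len(nrow(points)), identity)
  heights <- numeric()
  cdist <- function(ci, cj) {
    dd <- as.matrix(stats::dist(points))[ci, cj, drop = FALSE]
    switch(linkage, average = mean(dd), complete = max(dd),
           single = min(dd))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        d <- cdist(clusters[[i]], clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

recovery_rate <- function(truth, assignments) {
  called <- as.character(assignments$group[match(names(truth$group),
                                                 assignments$gene_id)])
  mean(called == as.character(truth$group))
}
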