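test_that("motif validation and basic matching work", {
  expect_error(scan_promoters(c(g = "ACGT"), motif = "GGCXWWW"),
               "invalid IUPAC")
  sc <- scan_promoters(c(g = "GGCATAT"), strands = "given")
  expect_equal(sc$count, 1L)
  expect_equal(sc$positions, "0:+")
  # two tandem sites: greedy non-overlapping matching finds both
  sc2 <- scan_promoters(c(g = "GGCATATGGCATAT"), strands = "given")
  expect_equal(sc2$count, 2L)
  expect_equal(sc2$positions, "0:+;7:+")
  # overlap prevention across strands: a plus-strand site at 0 and an
  # overlapping minus-strand site at 3 yield one accepted match
  sc3 <- scan_promoters(c(g = "GGCAAAAGCC"), strands = "both",
                        prevent_overlap = TRUE)
  expect_equal(sc3$count, 1L)
  expect_equal(sc3$positions, "0:+")
  sc3b <- scan_promoters(c(g = "GGCAAAAGCC"), strands = "both",
                         prevent_overlap = FALSE)
  expect_equal(sc3b$count, 2L)
  # N in the sequence never matches a non-N motif letter
  expect_equal(scan_promoters(c(g = "GGCNTAT"), strands = "given")$count, 0L)
  # upstream offsets are window-end anchored
  sc4 <- scan_promoters(c(g = "GGCATATAAA"), strands = "given")
  expect_equal(sc4$upstream_positions, "-10:+")
})

test_that("scan counts equal the brute-force oracle on random sequences", {
  set.seed(7)
  seqs <- random_dna(500, 60)
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  res <- scan_promoters(seqs, "GGCWWWW", strands = "both")
  oracle <- vapply(seqs, bf_scan_count, integer(1), motif = "GGCWWWW",
                   strands = "both")
  expect_equal(res$count, unname(oracle))
  # one-strand policy agrees too
  res1 <- scan_promoters(seqs, "GGCWWWW", strands = "given")
  oracle1 <- vapply(seqs, bf_scan_count, integer(1), motif = "GGCWWWW",
                    strands = "given")
  expect_equal(res1$count, unname(oracle1))
  # non-overlap bound: count <= floor(window / motif length)
  expect_true(all(res$count <= 60 %/% 7))
})

test_that("reverse-complement scanning is strand symmetric", {
  set.seed(9)
  seqs <- random_dna(100, 50)
  rc <- vapply(seqs, bf_revcomp, character(1))
  a <- scan_promoters(stats::setNames(seqs, sprintf("s%03d", 1:100)),
                      "GGCWWWW", strands = "both")
  b <- scan_promoters(stats::setNames(rc, sprintf("s%03d", 1:100)),
                      "GGCWWWW", strands = "both")
  expect_equal(a$count, b$count)
})

test_that("promoter extraction uses -L..-1 coordinates on both strands", {
  # hand-worked 20 bp contig; start codon ATG at positions 11-13 (+)
  ctg <- c(chr1 = "ACGTACGTACATGGGGCCCC")
  plus <- extract_promoters(ctg, data.frame(
    gene_id = "gp", contig = "chr1", strand = "+", start_codon_pos = 11),
    window = 5)
  expect_equal(unname(plus["gp"]), "CGTAC")
  # minus-strand gene whose transcript-orientation first base is position
  # 10: upstream is genomic 11..15 ("ATGGG"), reverse-complemented
  minus <- extract_promoters(ctg, data.frame(
    gene_id = "gm", contig = "chr1", strand = "-", start_codon_pos = 10),
    window = 5)
  expect_equal(unname(minus["gm"]), bf_revcomp("ATGGG"))
  # truncation at the contig edge is recorded
  tr <- extract_promoters(ctg, data.frame(
    gene_id = "gt", contig = "chr1", strand = "+", start_codon_pos = 4),
    window = 10)
  expect_equal(unname(tr["gt"]), "ACG")
  expect_true(attr(tr, "truncated")$truncated)
  expect_error(extract_promoters(ctg, data.frame(
    gene_id = "gz", contig = "chrX", strand = "+", start_codon_pos = 5)),
    "unknown contig")
  # FASTA round trip into the scanner
  tdir <- withr::local_tempdir()
  fa <- file.path(tdir, "genome.fa")
  write_promoters(ctg, fa)
  plus2 <- extract_promoters(fa, data.frame(
    gene_id = "gp", contig = "chr1", strand = "+", start_codon_pos = 11),
    window = 5)
  expect_equal(unname(plus2["gp"]), "CGTAC")
})

test_that("average sites per gene is the plain mean", {
  res <- data.frame(gene_id = c("a", "b"), count = c(3L, 1L))
  expect_equal(average_sites_per_gene(res), 2)
  expect_equal(average_sites_per_gene(
    data.frame(gene_id = "a", count = 0L)), 0)
  expect_error(average_sites_per_gene(res[0, ]), "no scan results")
})

test_that("expected spacing is the census quotient and scale invariant", {
  sp <- expected_spacing(33e6, 20692)
  expect_equal(round(sp$raw_bp), 1595)
  expect_equal(sp$rounded_bp, 1500)
  expect_equal(expected_spacing(1000, 1)$raw_bp, 1000)
  expect_equal(expected_spacing(10000, 20)$raw_bp, 500)
  # scale invariance
  expect_equal(expected_spacing(7 * 33e6, 7 * 20692)$raw_bp, sp$raw_bp)
  expect_error(expected_spacing(1000, 0), "positive")
})

test_that("two-sample AD statistic matches a reference implementation", {
  # standardized (mean 1, Scholz-Stephens variance) values frozen from an
  # independent reference implementation of the tie-adjusted k-sample
  # statistic
  standardize <- function(a2, n1, n2) {
    k <- 2; N <- n1 + n2
    H <- 1 / n1 + 1 / n2
    h <- sum(1 / (1:(N - 1)))
    g <- sum(vapply(1:(N - 2), function(i)
      sum(1 / ((N - i) * ((i + 1):(N - 1)))), numeric(1)))
    a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
    b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H -
      8 * h + 4 * g - 6
    cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
      (2 * h - 6) * H + 4 * h
    d <- (2 * h + 6) * k^2 - 4 * h * k
    v <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
    (a2 - (k - 1)) / sqrt(v)
  }
  x1 <- c(0, 1, 1, 2, 3, 0, 0, 5, 2, 1)
  y1 <- c(1, 1, 0, 0, 2, 2, 3, 1, 0, 0, 1, 4)
  expect_equal(standardize(ad_2sample(x1, y1), 10, 12), -1.2519568788,
               tolerance = 1e-9)
  x2 <- c(6, 6, 6, 6, 6, 5, 6)
  y2 <- c(0, 1, 0, 2, 1, 0, 0, 0, 1, 3)
  expect_equal(standardize(ad_2sample(x2, y2), 7, 10), 12.7656614289,
               tolerance = 1e-9)
  x3 <- c(1.2, 3.4, 2.2, 0.1, 5.5)
  y3 <- c(2.0, 2.0, 3.1, 0.5, 4.4, 6.6)
  expect_equal(standardize(ad_2sample(x3, y3), 5, 6), -1.1264048015,
               tolerance = 1e-9)
  # symmetry in the two samples; constant pooled sample gives 0
  expect_equal(ad_2sample(x1, y1), ad_2sample(y1, x1))
  expect_equal(ad_2sample(c(2, 2, 2), c(2, 2)), 0)
})

test_that("density significance detects an extreme shift and is deterministic", {
  nullm <- spacing_null(33e6, 20692, 1000)
  expect_equal(nullm$lambda_per_window, 1000 / (33e6 / 20692))
  # sixteen promoters all carrying 6 sites vs lambda ~0.63: clear rejection
  res <- density_significance(rep(6, 16), nullm, n_sim = 999, seed = 2)
  expect_lt(res$p_value, 0.01)
  expect_true(res$reject)
  # identical seeds give identical p; different seeds may not
  res2 <- density_significance(rep(6, 16), nullm, n_sim = 999, seed = 2)
  expect_identical(res$p_value, res2$p_value)
  # the vectorized internal statistic agrees with ad_2sample on the
  # observed-vs-pooled comparison
  set.seed(2)
  sims <- matrix(rpois(999 * 16, nullm$lambda_per_window), nrow = 999)
  expect_equal(res$statistic, ad_2sample(rep(6, 16), as.vector(sims)))
  expect_error(density_significance(rep(1, 5), nullm, n_sim = 99), ">= 999")
})
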