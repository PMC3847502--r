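toy_matrix <- function() {
  vals <- rbind(
    gA = c(6.0, 6.2, 6.1, 6.0, 8.1, 8.0),
    gB = c(5.0, 5.1, 5.0, 5.1, 5.0, 5.1))
  expr_matrix(vals, rep(c("glucose", "lactose", "wheat_straw"), each = 2))
}

test_that("expression tables read and write with validation", {
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "toy.tsv")
  write_expression(toy_matrix(), p)
  m <- read_expression(p)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(conditions(m), c("glucose", "lactose", "wheat_straw"))
  expect_equal(m$values, toy_matrix()$values)

  # --raw applies log2(x + 1): a raw 0 becomes 0
  writeLines(c("gene_id\tglucose.1\tglucose.2",
               "g1\t0\t3"), p)
  raw <- read_expression(p, raw = TRUE)
  expect_equal(unname(raw$values[1, ]), c(0, 2))

  writeLines(c("gene_id\tglucose.1\tglucose.2",
               "g1\t1\t2", "g1\t3\t4"), p)
  expect_error(read_expression(p), "duplicate gene_id")

  writeLines(c("gene_id\tglucose.1\tglucose.2",
               "g1\t1\toops"), p)
  expect_error(read_expression(p), "non-numeric")
})

test_that("differential expression matches the pooled-variance t formula", {
  vals <- rbind(g1 = c(7.1, 7.3, 7.2, 6.0, 6.2, 6.1))
  m <- expr_matrix(vals, rep(c("a", "b"), each = 3))
  de <- differential_expression(m, "a", "b")
  # textbook oracle, recomputed from scratch
  a <- c(7.1, 7.3, 7.2); b <- c(6.0, 6.2, 6.1)
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / 4
  t_exp <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(de$log2_fc, mean(a) - mean(b))
  expect_equal(de$p_value, 2 * pt(-abs(t_exp), 4))

  # identical replicate vectors: fc 0, p 1
  m0 <- expr_matrix(rbind(g1 = c(5, 6, 5, 6)), rep(c("a", "b"), each = 2))
  de0 <- differential_expression(m0, "a", "b")
  expect_equal(de0$log2_fc, 0)
  expect_equal(de0$p_value, 1)

  # near-noiseless 4-fold difference
  m4 <- expr_matrix(rbind(g1 = c(8, 8 + 1e-6, 6, 6 - 1e-6)),
                    rep(c("a", "b"), each = 2))
  de4 <- differential_expression(m4, "a", "b")
  expect_equal(de4$log2_fc, 2, tolerance = 1e-5)
  expect_lt(de4$p_value, 0.05)

  expect_error(differential_expression(
    expr_matrix(rbind(g1 = c(1, 2)), c("a", "b")), "a", "b"),
    ">=2 replicates")
})

test_that("welch and permutation DE agree with the default on clear cases", {
  set.seed(9)
  vals <- matrix(rnorm(40 * 6, 6, 0.3), 40)
  vals[1:10, 5:6] <- vals[1:10, 5:6] + 3
  rownames(vals) <- sprintf("g%02d", 1:40)
  m <- expr_matrix(vals, rep(c("glucose", "lactose", "wheat_straw"),
                             each = 2))
  for (meth in c("welch", "permutation")) {
    de <- differential_expression(m, "wheat_straw", "glucose", method = meth)
    expect_true(all(de$p_value >= 0 & de$p_value <= 1))
    expect_equal(de$log2_fc,
                 differential_expression(m, "wheat_straw", "glucose")$log2_fc)
  }
})

test_that("constitutive band is applied to all pairwise ratios, inclusive", {
  th <- transcript_thresholds()
  mk <- function(means) {
    vals <- matrix(rep(means, each = 2), nrow = 1)
    rownames(vals) <- "g1"
    expr_matrix(vals, rep(c("glucose", "lactose", "wheat_straw"), each = 2))
  }
  expect_equal(find_constitutive(mk(c(6, 6, 6)), th), "g1")
  # 1.5-fold spread exceeds the band
  expect_equal(find_constitutive(mk(c(6, 6, 6 + log2(1.5))), th),
               character(0))
  # exactly 1.4-fold at the band edge is inside (closed interval)
  expect_equal(find_constitutive(mk(c(6, 6 + log2(1.4), 6)), th), "g1")
  # below the expression floor: excluded regardless of flatness
  expect_equal(find_constitutive(mk(c(0.5, 0.5, 0.5)), th), character(0))
})

test_that("classification implements the group definitions", {
  mk_de <- function(fc, p) data.frame(gene_id = "g1", log2_fc = log2(fc),
                                      p_value = p, mean_a = 8, mean_b = 6)
  th <- transcript_thresholds()
  # up on wheat straw only -> A
  asn <- classify_transcript_groups(mk_de(4, 0.01), mk_de(1.2, 0.3),
                                    mk_de(3.3, 0.01), th)
  expect_equal(as.character(asn$group), "A")
  # up on both, no wheat-straw-vs-lactose difference -> E
  asn <- classify_transcript_groups(mk_de(4, 0.01), mk_de(4, 0.01),
                                    mk_de(1.0, 0.9), th)
  expect_equal(as.character(asn$group), "E")
  # up on both, >2-fold stronger on wheat straw -> C
  asn <- classify_transcript_groups(mk_de(8, 0.01), mk_de(4, 0.01),
                                    mk_de(2.5, 0.01), th)
  expect_equal(as.character(asn$group), "C")
  # lactose mirror -> D
  asn <- classify_transcript_groups(mk_de(4, 0.01), mk_de(8, 0.01),
                                    mk_de(1 / 2.5, 0.01), th)
  expect_equal(as.character(asn$group), "D")
  # disagreeing universes are rejected
  de2 <- data.frame(gene_id = "g2", log2_fc = 0, p_value = 1,
                    mean_a = 6, mean_b = 6)
  expect_error(classify_transcript_groups(mk_de(4, 0.01), de2,
                                          mk_de(1, 1), th),
               "symmetric difference")
})

test_that("classification partitions the universe and is order invariant", {
  d <- synthetic_design(n_genes = 300, replicates_per_condition = 3,
                        seed = 7)
  ge <- generate_expression(d)
  asn <- transcript_group_pipeline(ge$matrix)
  # partition: one label per gene, counts sum to the universe
  expect_equal(sort(asn$gene_id), sort(gene_ids(ge$matrix)))
  expect_equal(sum(table(asn$group)), 300)
  # |C| + |D| + |E| equals the number of genes up on both
  expect_equal(sum(asn$group %in% c("C", "D", "E")),
               sum(asn$up_ws & asn$up_lac))
  # permuting rows and columns leaves the assignment unchanged
  set.seed(1)
  perm_rows <- sample(nrow(ge$matrix$values))
  perm_cols <- sample(ncol(ge$matrix$values))
  m2 <- expr_matrix(ge$matrix$values[perm_rows, perm_cols],
                    ge$matrix$samples$condition[perm_cols],
                    ge$matrix$samples$replicate[perm_cols])
  asn2 <- transcript_group_pipeline(m2)
  asn2 <- asn2[match(asn$gene_id, asn2$gene_id), ]
  expect_equal(as.character(asn$group), as.character(asn2$group))
})

test_that("tightening thresholds never enlarges the regulated set", {
  d <- synthetic_design(n_genes = 400, replicates_per_condition = 3,
                        seed = 13)
  ge <- generate_expression(d)
  n_reg <- function(th) {
    asn <- transcript_group_pipeline(ge$matrix, th)
    sum(asn$group %in% c("A", "B", "C", "D", "E"))
  }
  base <- n_reg(transcript_thresholds())
  expect_lte(n_reg(transcript_thresholds(fold_change_min = 3)), base)
  expect_lte(n_reg(transcript_thresholds(p_max = 0.01)), base)
})

test_that("cross-tabulations match brute-force tallies of the truth", {
  d <- synthetic_design(
    n_genes = 600, replicates_per_condition = 3, seed = 17,
    enriched_pairs = list(list(group = "A", category = "GH18",
                               odds_multiplier = 8)))
  ge <- generate_expression(d)
  ann <- generate_annotation(d, ge$truth)
  asn <- transcript_group_pipeline(ge$matrix)

  tab <- crosstab_groups(asn, ann, facet = "cazy_family")
  for (g in c("A", "B")) {
    in_group <- asn$gene_id[asn$group == g]
    for (fam in c("GH18", "GH7")) {
      expected <- sum(ann$gene_id[ann$cazy_families == fam] %in% in_group)
      row <- tab[tab$level == fam, ]
      if (nrow(row)) expect_equal(row[[g]], expected)
    }
  }
  # row sums are consistent with group sizes
  expect_equal(unname(unlist(tab[tab$level == "all_genes",
                                 c("A", "B", "C", "D", "E")])),
               unname(as.vector(table(asn$group)[c("A", "B", "C", "D",
                                                   "E")])))
  # empty annotation: all counts fall into the unannotated row
  tab0 <- crosstab_groups(asn, ann[0, ], facet = "funcat")
  expect_equal(unlist(tab0[tab0$level == "unannotated", c("A", "E")]),
               unlist(tab0[tab0$level == "all_genes", c("A", "E")]))
})

test_that("panel report flags exactly the planted panel", {
  d <- synthetic_design(n_genes = 200, replicates_per_condition = 3,
                        seed = 19)
  ge <- generate_expression(d)
  panel <- names(ge$truth$group[ge$truth$group == "A"])[1:7]
  rep_ <- panel_report(ge$matrix, panel)
  ws <- rep_[rep_$condition == "wheat_straw", ]
  lac <- rep_[rep_$condition == "lactose", ]
  expect_true(all(ws$flagged))
  expect_false(any(lac$flagged))
  # equal means give ratio 1; a 2 log2 difference gives ratio 4
  flat <- expr_matrix(rbind(g1 = c(6, 6, 6, 6, 8, 8)),
                      rep(c("glucose", "lactose", "wheat_straw"), each = 2))
  pr <- panel_report(flat, "g1")
  expect_equal(pr$ratio[pr$condition == "lactose"], 1)
  expect_equal(pr$ratio[pr$condition == "wheat_straw"], 4)
  # missing panel genes warn and are listed, not fatal
  expect_warning(pm <- panel_report(ge$matrix, c(panel[1], "nope")),
                 "nope")
  expect_equal(attr(pm, "missing"), "nope")
})
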