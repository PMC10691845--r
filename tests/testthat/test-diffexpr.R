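test_that("exact Wilcoxon reproduces hand-enumerated examples", {
  got <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$W, 6)
  expect_equal(got$p, 2 / 20)  # both tails of C(6,3) = 20 assignments
  expect_equal(wilcoxon_rank_sum(c(5, 1, 3), c(3, 1, 5))$p, 1)  # x == y
})

test_that("exact path equals the permutation oracle on all splits of 8", {
  vals <- c(2.1, 3.7, 5.0, 5.9, 7.3, 8.8, 10.1, 12.4)
  for (nx in 1:4) {
    splits <- utils::combn(8, nx)
    for (k in seq_len(ncol(splits))) {
      x <- vals[splits[, k]]
      y <- vals[-splits[, k]]
      expect_equal(wilcoxon_rank_sum(x, y)$p, perm_oracle(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("normal approximation tracks the exact p at n = m = 10", {
  set.seed(31)
  for (i in 1:10) {
    x <- round(rnorm(10), 4)
    y <- round(rnorm(10, 0.3), 4)
    exact <- wilcoxon_rank_sum(x, y)$p
    approx <- wilcoxon_rank_sum(x, y, exact_max = 0)$p
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("degenerate all-identical input warns and returns p = 1", {
  expect_warning(got <- wilcoxon_rank_sum(rep(2, 15), rep(2, 15)),
                 "identical")
  expect_equal(got$p, 1)
})

test_that("tie-corrected approximation agrees with stats::wilcox.test", {
  set.seed(7)
  for (i in 1:8) {
    x <- rpois(40, 2)
    y <- rpois(60, 2.6)
    got <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bh_adjust matches closed forms and the step-up property", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, stats::p.adjust(p, "BH"))  # independent reference
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= 0 & q <= 1))
  # NAs are excluded from the effective number of tests (stricter than
  # p.adjust, whose default n counts NA positions)
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
})

test_that("stars uses the conventional four-step ladder", {
  expect_equal(stars(c(0.2, 0.04, 0.007, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(stars(0.05), "ns")
})

test_that("de_by_cluster recovers planted upregulation and skips small clusters", {
  cfg <- small_config(seed = 55, n_nuclei_per_group = 500)
  ds <- cached_dataset(cfg)
  pp <- prep_pipeline(ds)
  de <- suppressWarnings(de_by_cluster(pp$norm, pp$major, pp$groups))
  noncanon <- ds$config$panels$imprint_noncanonical[[1]]
  tb <- de[de$cluster == "trophoblast" & de$gene %in% noncanon, ]
  expect_gte(mean(tb$q < 0.05 & tb$log2fc > 0), 0.95)
  # log2FC antisymmetry and p preservation under group swap
  flipped <- ifelse(pp$groups == "IVF", "SCNT", "IVF")
  de2 <- suppressWarnings(de_by_cluster(pp$norm, pp$major, flipped))
  tb2 <- de2[de2$cluster == "trophoblast" & de2$gene %in% noncanon, ]
  expect_equal(tb2$log2fc, -tb$log2fc)
  expect_equal(tb2$p, tb$p, tolerance = 1e-12)
  # a cluster below min_cells is skipped with a warning
  few <- pp$major
  few[pp$major == "erythrocyte" & pp$groups == "SCNT"][-(1:5)] <- "ambiguous"
  expect_warning(de3 <- de_by_cluster(pp$norm, few, pp$groups,
                                      min_cells = 20),
                 "erythrocyte skipped")
  expect_false("erythrocyte" %in% de3$cluster)
  expect_error(suppressWarnings(
    de_by_cluster(pp$norm, few, pp$groups, min_cells = 1e6)), "no cluster")
})

test_that("hypergeometric over-representation matches closed forms", {
  universe <- paste0("g", 1:20)
  gene_set <- universe[1:5]
  hits <- universe[1:5]
  got <- set_overrepresentation(hits, gene_set, universe)
  expect_equal(got$overlap, 5)
  expect_equal(got$p, 1 / choose(20, 5), tolerance = 1e-12)
  none <- set_overrepresentation(universe[6:10], gene_set, universe)
  expect_equal(none$overlap, 0)
  expect_equal(none$p, 1)
})

test_that("chromatin panel is enriched in fetal clusters but not decidua", {
  cfg <- small_config(seed = 55, n_nuclei_per_group = 500)
  ds <- cached_dataset(cfg)
  pp <- prep_pipeline(ds)
  de <- suppressWarnings(de_by_cluster(pp$norm, pp$major, pp$groups))
  chromatin <- ds$config$panels$chromatin[[1]]
  # at this reduced n only the larger clusters are well powered; the
  # full-scale every-fetal-cluster claim is exercised in the acceptance
  # suite on the default configuration
  for (cl in intersect(c("trophoblast", "decidual_stroma"),
                       unique(de$cluster))) {
    d <- de[de$cluster == cl, ]
    hits <- d$gene[d$q < 0.05 & d$log2fc > 0]
    ora <- set_overrepresentation(hits, chromatin, rownames(pp$norm))
    if (cl == "decidual_stroma") {
      expect_gt(ora$p, 0.01)
    } else {
      expect_lt(ora$p, 0.01)
    }
  }
})
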