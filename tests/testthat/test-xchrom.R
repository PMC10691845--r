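toy_annotation <- function() {
  data.frame(gene = c("x1", "x2", "a1", "a2", "Xist"),
             chrom = c("X", "X", "1", "2", "X"),
             start = c(1e6, 2e6, 1e6, 2e6, 3e6),
             stringsAsFactors = FALSE)
}

toy_counts <- function() {
  m <- matrix(c(4, 6, 50, 50, 0,
                8, 12, 100, 100, 0), ncol = 2,
              dimnames = list(c("x1", "x2", "a1", "a2", "Xist"),
                              c("b1", "b2")))
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("xa_ratio computes X over autosome sums on raw counts", {
  xa <- xa_ratio(toy_counts(), toy_annotation())
  expect_equal(xa$ratio, c(0.1, 0.1))  # 10/100 and 20/200
  # doubling a nucleus leaves its ratio unchanged (computed above: b2 = 2*b1)
  # gene reordering is irrelevant
  shuf <- toy_counts()[c(3, 1, 5, 2, 4), ]
  expect_equal(xa_ratio(shuf, toy_annotation())$ratio, xa$ratio)
  # zero autosomal sum flags NA
  zero <- toy_counts()
  zero[c("a1", "a2"), 1] <- 0
  expect_true(is.na(xa_ratio(zero, toy_annotation())$ratio[1]))
  expect_error(xa_ratio(toy_counts()[1:2, ], toy_annotation()[3:4, ]),
               "cover")
})

test_that("excluding Xist strictly lowers SCNT trophoblast X sums", {
  ds <- cached_dataset(small_config())
  tr <- truth_map(ds)
  counts <- ds$counts$SCNT
  tb <- tr$barcode[tr$group == "SCNT" & tr$major_type == "trophoblast"]
  with_x <- xa_ratio(counts, ds$genes)
  no_x <- xa_ratio(counts, ds$genes, exclude = "Xist")
  w <- stats::setNames(with_x$x_counts, with_x$barcode)[tb]
  n <- stats::setNames(no_x$x_counts, no_x$barcode)[tb]
  expect_true(all(n <= w))
  expect_lt(sum(n), sum(w))
})

test_that("compare_xa: identical groups give p = 1", {
  ratios <- data.frame(barcode = paste0("b", 1:40),
                       x_counts = 1, autosome_counts = 10,
                       ratio = rep(c(0.1, 0.2), 20))
  labels <- stats::setNames(rep("t", 40), ratios$barcode)
  groups <- rep(c("IVF", "SCNT"), each = 20)
  # identical multisets per group
  out <- compare_xa(ratios, labels, groups)
  expect_equal(out$p, 1)
})

test_that("x_de_summary applies q, effect size and direction jointly", {
  de <- expand.grid(cluster = c("c1", "c2"), gene = c("gx", "ga"),
                    stringsAsFactors = FALSE)
  de$q <- c(0.01, 0.01, 0.01, 0.01)
  de$log2fc <- c(-1, -1, -1, -1)
  de$direction <- "down"
  ann <- data.frame(gene = c("gx", "ga"), chrom = c("X", "3"),
                    start = c(1e6, 1e6))
  out <- x_de_summary(de, ann, clusters = c("c1", "c2"))
  expect_equal(out$gene, "gx")  # autosomal gene never qualifies
  # effect below threshold disqualifies
  de$log2fc[1] <- -0.3
  expect_equal(nrow(x_de_summary(de, ann, clusters = c("c1", "c2"))), 0)
  # inconsistent direction disqualifies
  de$log2fc[1] <- 1; de$direction[1] <- "up"
  expect_equal(nrow(x_de_summary(de, ann, clusters = c("c1", "c2"))), 0)
})

test_that("x_position_spread separates uniform from clustered layouts", {
  len <- snPlacenta:::chrom_lengths()[["X"]]
  even <- data.frame(gene = paste0("g", 1:30), chrom = "X",
                     start = round(seq(len / 60, len, length.out = 30)))
  got <- x_position_spread(even$gene, even)
  expect_gt(got$p, 0.9)
  tight <- even
  tight$start <- round(seq(1, 0.01 * len, length.out = 30))
  expect_lt(x_position_spread(tight$gene, tight)$p, 0.001)
  expect_warning(out <- x_position_spread("g1", even), "skipped")
  expect_null(out)
})

test_that("X dosage is repressed in fetal clusters and stable in decidua", {
  ds <- cached_dataset(small_config())
  pp <- prep_pipeline(ds)
  xa <- xa_ratio(pp$counts, ds$genes)
  cmp <- compare_xa(xa, pp$major, pp$groups)
  fet <- cmp[cmp$cluster %in% fetal_types(), ]
  expect_true(all(fet$median_ratio < 1))
  expect_true(all(fet$p < 0.05))
  dec <- cmp[cmp$cluster == "decidual_stroma", ]
  # ~80 decidual nuclei/group here; the 5% bound is asserted at full
  # scale in the acceptance suite
  expect_lt(abs(dec$median_ratio - 1), 0.15)
  expect_gt(dec$p, 0.01)
})

test_that("imprinted_panel_summary separates the two imprint classes", {
  ds <- cached_dataset(small_config())
  pp <- prep_pipeline(ds)
  panels <- list(
    noncanonical = ds$config$panels$imprint_noncanonical[[1]],
    canonical = ds$config$panels$imprint_canonical[[1]])
  imp <- imprinted_panel_summary(pp$norm, pp$major, pp$groups, panels)
  tb <- imp[imp$cluster == "trophoblast", ]
  nc <- tb[tb$panel == "noncanonical", ]
  expect_true(all(nc$log2fc > 0 & nc$q < 0.05))  # stable upregulation
  affected <- ds$genes$gene[ds$genes$canonical_affected]
  ca <- tb[tb$panel == "canonical", ]
  # the 1.5x canonical fold is deliberately mild; at this reduced n
  # expect most (not all) affected genes to reach significance, and at
  # most one chance hit among the unaffected ones.  The full-scale
  # claim runs in the acceptance suite.
  expect_gte(sum(ca$q[ca$gene %in% affected] < 0.05), 2)
  expect_lte(sum(ca$q[!ca$gene %in% affected] < 0.05), 1)
  # validation
  expect_error(imprinted_panel_summary(pp$norm, pp$major, pp$groups,
                                       list(a = character(0))),
               "non-empty")
  expect_error(imprinted_panel_summary(pp$norm, pp$major, pp$groups,
                                       list(a = "H19", b = "H19")),
               "disjoint")
})

test_that("classify_icr thresholds beta values", {
  expect_equal(classify_icr(c(0.5, 0.9, 0.1)), c("normal", "hyper", "hypo"))
  expect_equal(classify_icr(c(0.25, 0.75)), c("normal", "normal"))
  expect_error(classify_icr(1.2), "beta")
  expect_error(classify_icr(0.5, hypo = 0.8, hyper = 0.2), "hypo < hyper")
})
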