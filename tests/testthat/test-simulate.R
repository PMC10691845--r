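test_that("gene annotation places the named genes and partitions genes", {
  cfg <- small_config()
  ann <- build_gene_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_genes)
  # genes with a fixed chromosome in the mouse genome
  for (g in c("Xist", "Dusp9", "Mid1")) {
    expect_equal(ann$chrom[ann$gene == g], "X")
  }
  for (g in c("Nos1ap", "Prl3d1", "Ehmt1", "Ezh2", "Setd5", "Ino80",
              "Dnmt3b")) {
    expect_true(g %in% ann$gene)
    expect_true(ann$chrom[ann$gene == g] %in% as.character(1:19))
  }
  expect_true(all(ann$chrom %in% c(as.character(1:19), "X")))
  expect_true(all(ann$start >= 1))
  # per-chromosome counts partition n_genes
  expect_equal(sum(table(ann$chrom)), cfg$n_genes)
  expect_false(anyDuplicated(ann$gene) > 0)
  expect_equal(sum(ann$planted_x), cfg$n_planted_x_degs)
  expect_true(all(ann$chrom[ann$planted_x] == "X"))
  expect_false("Xist" %in% ann$gene[ann$planted_x])
})

test_that("n_genes equal to the panel size leaves no filler genes", {
  cfg <- small_config(n_planted_x_degs = 2)  # Mid1 + Dusp9, no X fillers
  named <- sum(build_gene_annotation(cfg)$role != "")
  cfg2 <- small_config(n_genes = named, n_planted_x_degs = 2)
  ann <- build_gene_annotation(cfg2)
  expect_equal(nrow(ann), named)
  expect_true(all(ann$role != ""))
  # too small is an error
  expect_error(build_gene_annotation(small_config(n_genes = named - 1,
                                                  n_planted_x_degs = 2)),
               "smaller than")
})

test_that("a symbol shared across exclusive panels is rejected", {
  panels <- read_panels()
  panels$chromatin$chromatin <- c(panels$chromatin$chromatin, "Nos1ap")
  cfg <- small_config(panels = panels)
  expect_error(build_gene_annotation(cfg), "mutually exclusive")
})

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(allele_error = 0.5), "allele_error")
  expect_error(sim_config(fetal_immune_fraction = 1.2), "fetal_immune")
  expect_error(sim_config(marker_fold = 0), "marker_fold")
  bad_frac <- list(IVF = stats::setNames(rep(1, 7), major_types()),
                   SCNT = stats::setNames(rep(1 / 7, 7), major_types()))
  expect_error(sim_config(major_type_fractions = bad_frac), "summing to 1")
})

test_that("the same config and seed reproduce the dataset exactly", {
  cfg <- small_config(seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$counts$IVF), as.matrix(d2$counts$IVF))
  expect_identical(as.matrix(d1$counts$SCNT), as.matrix(d2$counts$SCNT))
  expect_identical(as.matrix(d1$allele$SCNT$maternal),
                   as.matrix(d2$allele$SCNT$maternal))
  expect_identical(d1$truth, d2$truth)
})

test_that("zero nuclei per group yields empty, valid matrices", {
  cfg <- small_config(n_nuclei_per_group = 0)
  ds <- simulate_dataset(cfg)
  expect_equal(ncol(ds$counts$IVF), 0L)
  expect_equal(nrow(ds$counts$IVF), cfg$n_genes)
  expect_equal(nrow(ds$truth), 0L)
})

test_that("truth labels respect lineage origin rules", {
  ds <- cached_dataset(small_config())
  tr <- ds$truth
  expect_true(all(tr$origin[tr$major_type == "decidual_stroma"] == "maternal"))
  expect_true(all(tr$origin[tr$major_type %in% fetal_types()] == "fetal"))
  expect_true(all(is.na(tr$subtype) != (tr$major_type == "trophoblast")))
  # immune origin is a ~50/50 mix
  imm <- tr$origin[tr$major_type == "immune"]
  expect_gt(length(imm), 20)
  ci <- stats::binom.test(sum(imm == "fetal"), length(imm))$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("empirical gene means match configured means at low noise", {
  # dispersion -> 0 (Poisson) and a tight library factor; unaffected
  # baseline genes in the IVF group should recover the baseline mean
  cfg <- small_config(n_nuclei_per_group = 2000, nb_dispersion = 0,
                      libsize_lognorm = c(0, 0), seed = 5)
  ds <- simulate_dataset(cfg)
  ann <- ds$genes
  plain <- ann$role == "" & !ann$planted_x
  emp <- Matrix::rowSums(ds$counts$IVF[plain, ]) / ncol(ds$counts$IVF)
  expected <- snPlacenta:::with_seed(cfg$seed, {
    ann2 <- snPlacenta:::build_annotation_impl(cfg)
    base <- stats::rlnorm(nrow(ann2), meanlog = 0.5, sdlog = 1)
    base[plain]
  })
  # aggregate relative error of the mean across ~300 genes
  expect_lt(abs(sum(emp) - sum(expected)) / sum(expected), 0.05)
  expect_lt(stats::median(abs(emp - expected) / pmax(expected, 0.1)), 0.25)
})

test_that("null config carries no group information", {
  cfg <- null_config(n_nuclei_per_group = 250, n_genes = 400,
                     n_planted_x_degs = 2, seed = 9)
  expect_equal(cfg$x_repression_factor, 1)
  expect_equal(cfg$major_type_fractions$IVF, cfg$major_type_fractions$SCNT)
  ds <- simulate_dataset(cfg)
  j <- join_groups(ds)
  norm <- normalize_counts(j$counts)
  # per-gene Wilcoxon p across groups should be roughly uniform;
  # a full KS calibration at 2000 genes runs in the acceptance suite
  mat <- as.matrix(norm[snPlacenta:::with_seed(1, sample(nrow(norm), 150)), ])
  p <- snPlacenta:::wilcoxon_rows(mat, j$groups == "SCNT")$p
  expect_gt(mean(p < 0.05), 0.0)
  expect_lt(mean(p < 0.05), 0.12)
})
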