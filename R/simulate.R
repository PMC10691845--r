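#' Simulation configuration for synthetic IVF/SCNT placenta datasets
#'
#' Builds a validated configuration describing the study design the
#' generator emulates: two groups (IVF, SCNT), seven major placental cell
#' types, twelve trophoblast subtypes with the two giant-cell subtypes
#' together near 50% of trophoblasts, mixed maternal/fetal origin (decidua
#' maternal, immune roughly half fetal, remaining lineages fetal), and
#' SCNT-specific planted effects: global X-linked repression in fetal
#' nuclei sparing Xist, Xist upregulation in trophoblast, stable
#' upregulation of non-canonical imprinted genes, upregulation of a random
#' subset of canonical imprinted genes, chromatin-modifier upregulation in
#' fetal-lineage clusters, an immune/erythrocyte composition shift, an
#' elevated S-TGC share, and enhanced decidua-to-pericyte/endothelial
#' ligand signalling.
#'
#' @param n_nuclei_per_group Nuclei per group (default 3000).
#' @param n_genes Total genes including panel genes (default 2000).
#' @param major_type_fractions Named list with elements `IVF` and `SCNT`,
#'   each a probability vector over [major_types()].
#' @param trophoblast_subtype_fractions Same structure over
#'   [trophoblast_subtypes()].
#' @param marker_fold Multiplicative fold applied to a type's marker
#'   genes in nuclei of that type (default 8).
#' @param lr_marker_fold Fold applied to a ligand/receptor gene in its
#'   home cell type (default 8).
#' @param nb_dispersion Negative-binomial dispersion; `size = 1/dispersion`
#'   (default 0.3).  Zero selects Poisson sampling.
#' @param libsize_lognorm Length-2 numeric `(meanlog, sdlog)` of the
#'   per-nucleus library-size factor (default `c(0, 0.3)`).
#' @param x_repression_factor Multiplier on X-linked gene means (Xist
#'   excepted) in SCNT fetal-origin nuclei (default 0.7).
#' @param xist_scnt_fold Xist fold in SCNT trophoblast nuclei, all
#'   subtypes (default 4).
#' @param noncanonical_imprint_fold SCNT fold for the non-canonical
#'   imprinted panel in fetal-lineage clusters (default 2).
#' @param canonical_imprint_fold SCNT fold applied to a random subset of
#'   the canonical imprinted panel (default 1.5).
#' @param canonical_imprint_subset Fraction of canonical imprinted genes
#'   affected (default 0.3).
#' @param chromatin_fold SCNT fold for the chromatin-modifier panel in
#'   fetal-lineage clusters (default 1.5).
#' @param fetal_immune_fraction Probability an immune nucleus is fetal
#'   (default 0.5).
#' @param n_snps Strain-informative SNP count (default 200).
#' @param snp_coverage_mean Poisson mean reads per SNP per nucleus
#'   (default 0.1, i.e. about 20 informative reads per nucleus).
#' @param allele_error Per-read probability of observing the wrong-strain
#'   allele (default 0.01).
#' @param n_planted_x_degs Number of X-linked genes given strong SCNT
#'   repression in all fetal nuclei (default 30).
#' @param planted_x_fold Repression fold for the planted X set (default
#'   0.4; stronger than the global factor so recovery is near-certain).
#' @param interaction_fold SCNT fold for the boosted decidual ligands
#'   (default 3).
#' @param boost_ligands Ligand symbols upregulated in SCNT decidual
#'   stroma (default `c("Igf1", "Angpt1")`, driving the planted
#'   decidua-to-pericyte and decidua-to-endothelial enhancement).
#' @param seed RNG seed (default 1).
#' @param panels Panel list as returned by [read_panels()].
#' @param lr_table LR pair table as returned by [read_lr_table()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_nuclei_per_group = 3000,
                       n_genes = 2000,
                       major_type_fractions = NULL,
                       trophoblast_subtype_fractions = NULL,
                       marker_fold = 8,
                       lr_marker_fold = 8,
                       nb_dispersion = 0.3,
                       libsize_lognorm = c(0, 0.3),
                       x_repression_factor = 0.7,
                       xist_scnt_fold = 4,
                       noncanonical_imprint_fold = 2,
                       canonical_imprint_fold = 1.5,
                       canonical_imprint_subset = 0.3,
                       chromatin_fold = 1.5,
                       fetal_immune_fraction = 0.5,
                       n_snps = 200,
                       snp_coverage_mean = 0.1,
                       allele_error = 0.01,
                       n_planted_x_degs = 30,
                       planted_x_fold = 0.4,
                       interaction_fold = 3,
                       boost_ligands = c("Igf1", "Angpt1"),
                       seed = 1,
                       panels = read_panels(),
                       lr_table = read_lr_table()) {
  if (is.null(major_type_fractions)) {
    major_type_fractions <- list(
      IVF  = stats::setNames(c(0.20, 0.45, 0.08, 0.07, 0.08, 0.05, 0.07),
                             major_types()),
      SCNT = stats::setNames(c(0.19, 0.45, 0.13, 0.03, 0.08, 0.05, 0.07),
                             major_types()))
  }
  if (is.null(trophoblast_subtype_fractions)) {
    base <- stats::setNames(c(0.22, 0.28, 0.12, 0.08, 0.08, 0.07, 0.05,
                              0.02, 0.02, 0.02, 0.02, 0.02),
                            trophoblast_subtypes())
    scnt <- base
    scnt["S-TGC"] <- 0.30
    scnt["P-TGC"] <- 0.20
    trophoblast_subtype_fractions <- list(IVF = base, SCNT = scnt)
  }
  cfg <- structure(list(
    n_nuclei_per_group = as.integer(n_nuclei_per_group),
    n_genes = as.integer(n_genes),
    major_type_fractions = major_type_fractions,
    trophoblast_subtype_fractions = trophoblast_subtype_fractions,
    marker_fold = marker_fold,
    lr_marker_fold = lr_marker_fold,
    nb_dispersion = nb_dispersion,
    libsize_lognorm = libsize_lognorm,
    x_repression_factor = x_repression_factor,
    xist_scnt_fold = xist_scnt_fold,
    noncanonical_imprint_fold = noncanonical_imprint_fold,
    canonical_imprint_fold = canonical_imprint_fold,
    canonical_imprint_subset = canonical_imprint_subset,
    chromatin_fold = chromatin_fold,
    fetal_immune_fraction = fetal_immune_fraction,
    n_snps = as.integer(n_snps),
    snp_coverage_mean = snp_coverage_mean,
    allele_error = allele_error,
    n_planted_x_degs = as.integer(n_planted_x_degs),
    planted_x_fold = planted_x_fold,
    interaction_fold = interaction_fold,
    boost_ligands = boost_ligands,
    seed = as.integer(seed),
    panels = panels,
    lr_table = lr_table), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (g in c("IVF", "SCNT")) {
    for (fld in c("major_type_fractions", "trophoblast_subtype_fractions")) {
      v <- cfg[[fld]][[g]]
      if (is.null(v)) stop(fld, " missing group ", g, call. = FALSE)
      if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
        stop(fld, "[", g, "] must be a probability vector summing to 1",
             call. = FALSE)
      }
    }
  }
  folds <- c("marker_fold", "lr_marker_fold", "x_repression_factor",
             "xist_scnt_fold",
             "noncanonical_imprint_fold", "canonical_imprint_fold",
             "chromatin_fold", "planted_x_fold", "interaction_fold")
  for (f in folds) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(f, " must be > 0", call. = FALSE)
    }
  }
  if (cfg$fetal_immune_fraction < 0 || cfg$fetal_immune_fraction > 1) {
    stop("fetal_immune_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$allele_error < 0 || cfg$allele_error >= 0.5) {
    stop("allele_error must lie in [0, 0.5)", call. = FALSE)
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$n_nuclei_per_group < 0 || cfg$n_genes < 1) {
    stop("n_nuclei_per_group must be >= 0 and n_genes >= 1", call. = FALSE)
  }
  cfg
}

#' A null configuration: no group effects, identical composition
#'
#' All planted folds set to 1 and the SCNT composition vectors copied from
#' IVF, so the group label carries no information.  Used for type-I-error
#' calibration of every downstream test.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  cfg <- sim_config(...)
  over <- names(list(...))
  for (f in c("x_repression_factor", "xist_scnt_fold",
              "noncanonical_imprint_fold", "canonical_imprint_fold",
              "chromatin_fold", "planted_x_fold", "interaction_fold")) {
    if (!f %in% over) cfg[[f]] <- 1
  }
  if (!"major_type_fractions" %in% over) {
    cfg$major_type_fractions$SCNT <- cfg$major_type_fractions$IVF
  }
  if (!"trophoblast_subtype_fractions" %in% over) {
    cfg$trophoblast_subtype_fractions$SCNT <-
      cfg$trophoblast_subtype_fractions$IVF
  }
  validate_sim_config(cfg)
}

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build the gene annotation for a simulation configuration
#'
#' Lays out all panel genes (markers of the 7 major types and 12
#' trophoblast subtypes, imprinted panels, chromatin modifiers,
#' ligand-receptor genes, Xist and Mid1) plus unnamed filler genes, and
#' assigns every gene a chromosome (autosomes 1-19 or X) and a 1-based
#' start position.  Genes with a fixed chromosome in the mouse genome and
#' named in the underlying study design (Xist, Dusp9, Mid1 on X) are
#' placed there; filler chromosomes are drawn with probability
#' proportional to chromosome length.  Also freezes, deterministically
#' under the config seed, the planted X-linked DEG set (Mid1 and Dusp9
#' plus filler X genes, `n_planted_x_degs` in total) and the affected
#' canonical-imprint subset.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `gene`, `chrom`, `start`, `panel`,
#'   `role`, `planted_x`, `canonical_affected`.
#' @export
build_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_annotation_impl(config))
}

build_annotation_impl <- function(config) {
  p <- config$panels
  lr <- config$lr_table
  rows <- list()
  add <- function(genes, panel, role) {
    data.frame(gene = genes, panel = panel, role = role,
               stringsAsFactors = FALSE)
  }
  for (nm in names(p$major)) rows[[length(rows) + 1L]] <- add(p$major[[nm]], nm, "major_marker")
  for (nm in names(p$subtype)) rows[[length(rows) + 1L]] <- add(p$subtype[[nm]], nm, "subtype_marker")
  for (nm in names(p$imprint_noncanonical)) {
    rows[[length(rows) + 1L]] <- add(p$imprint_noncanonical[[nm]], nm, "imprint_noncanonical")
  }
  for (nm in names(p$imprint_canonical)) {
    rows[[length(rows) + 1L]] <- add(p$imprint_canonical[[nm]], nm, "imprint_canonical")
  }
  for (nm in names(p$chromatin)) rows[[length(rows) + 1L]] <- add(p$chromatin[[nm]], nm, "chromatin")
  if (!is.null(lr)) {
    lig_home <- lr$ligand_type %||% rep("trophoblast", nrow(lr))
    rec_home <- lr$receptor_type %||% rep("trophoblast", nrow(lr))
    rows[[length(rows) + 1L]] <- add(lr$ligand, lig_home, "lr")
    rows[[length(rows) + 1L]] <- add(lr$receptor, rec_home, "lr")
  }
  rows[[length(rows) + 1L]] <- add("Xist", "xist", "xist")
  rows[[length(rows) + 1L]] <- add("Mid1", "", "x_named")
  named <- do.call(rbind, rows)
  dup <- duplicated(named$gene)
  if (any(dup)) {
    # the same symbol may appear in several LR pairs, but not across
    # mutually exclusive functional panels
    dup_genes <- unique(named$gene[dup])
    conflict <- vapply(dup_genes, function(g) {
      length(unique(named$role[named$gene == g])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("gene(s) assigned to mutually exclusive panels: ",
           paste(dup_genes[conflict], collapse = ", "), call. = FALSE)
    }
    named <- named[!dup, ]
  }
  n_named <- nrow(named)
  if (config$n_genes < n_named) {
    stop(sprintf("n_genes = %d is smaller than the %d panel genes",
                 config$n_genes, n_named), call. = FALSE)
  }
  n_fill <- config$n_genes - n_named
  filler <- if (n_fill > 0) {
    data.frame(gene = sprintf("Gene%04d", seq_len(n_fill)),
               panel = "", role = "", stringsAsFactors = FALSE)
  } else {
    named[0, c("gene", "panel", "role")]
  }
  ann <- rbind(named, filler)

  lens <- chrom_lengths()
  fixed_x <- c("Xist", "Dusp9", "Mid1")
  chrom <- character(nrow(ann))
  named_idx <- which(ann$role != "")
  # named autosomal genes cycle over the autosomes deterministically
  auto_pool <- setdiff(names(lens), "X")
  chrom[named_idx] <- rep_len(auto_pool, length(named_idx))
  fill_idx <- which(ann$role == "")
  if (length(fill_idx)) {
    chrom[fill_idx] <- sample(names(lens), length(fill_idx),
                              replace = TRUE, prob = lens / sum(lens))
  }
  chrom[ann$gene %in% fixed_x] <- "X"
  start <- 1L + floor(stats::runif(nrow(ann)) * (lens[chrom] - 1))
  ann$chrom <- chrom
  ann$start <- as.integer(start)

  # planted X DEG set: Mid1 and Dusp9 plus the first filler X genes
  x_fillers <- ann$gene[ann$chrom == "X" & ann$role == ""]
  planted <- intersect(fixed_x[fixed_x != "Xist"], ann$gene)
  extra_needed <- max(0L, config$n_planted_x_degs - length(planted))
  if (extra_needed > length(x_fillers)) {
    stop(sprintf(paste0("cannot plant %d X-linked DEGs: only %d X genes ",
                        "available beyond Mid1/Dusp9; increase n_genes"),
                 config$n_planted_x_degs, length(x_fillers)), call. = FALSE)
  }
  planted <- c(planted, x_fillers[seq_len(extra_needed)])
  planted <- planted[seq_len(min(length(planted), config$n_planted_x_degs))]
  ann$planted_x <- ann$gene %in% planted

  canon <- ann$gene[ann$role == "imprint_canonical"]
  n_aff <- round(config$canonical_imprint_subset * length(canon))
  affected <- if (n_aff > 0) sample(canon, n_aff) else character(0)
  ann$canonical_affected <- ann$gene %in% affected
  rownames(ann) <- NULL
  ann[c("gene", "chrom", "start", "panel", "role",
        "planted_x", "canonical_affected")]
}

#' Simulate a synthetic IVF/SCNT placenta snRNA-seq dataset
#'
#' Draws, for each group, per-nucleus major types (and trophoblast
#' subtypes), maternal/fetal origins, negative-binomial UMI counts with
#' log-normal gene baselines and library-size factors, and
#' strain-informative allele counts at SNPs (per-SNP Poisson coverage,
#' binomial allele assignment with error `allele_error`).  All SCNT
#' group effects from the configuration are applied multiplicatively to
#' the mean matrix before sampling.  The same configuration and seed
#' always reproduce the identical dataset.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset`: list with `counts`
#'   (per-group gene x nucleus `dgCMatrix`), `allele` (per-group
#'   [allele_counts()]), `genes` (annotation), `truth` (per-nucleus truth
#'   data.frame) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ann <- build_annotation_impl(config)
    base <- stats::rlnorm(nrow(ann), meanlog = 0.5, sdlog = 1)
    # ligand/receptor genes get a fixed low baseline: real signalling
    # genes are expression-specific, and a shared baseline keeps
    # communication scores comparable across pathways while the planted
    # SCNT ligand boost stays a negligible share of any library
    base[ann$role == "lr"] <- 0.1
    # the planted X DEG panel emulates reliably *detected* placental
    # DEGs, which are by construction expressed genes; floor their
    # baseline so detectability is a property of the planted fold, not
    # of a lottery over lognormal baselines
    base[ann$planted_x] <- pmax(base[ann$planted_x], 2.5)
    # imprinted genes (H19, Igf2, ...) are among the most abundant
    # placental transcripts; floor both panels so the planted folds are
    # detectable properties rather than baseline lotteries
    imp <- ann$role %in% c("imprint_noncanonical", "imprint_canonical")
    base[imp] <- pmax(base[imp], 2)
    snps <- simulate_snp_annotation(config)
    counts <- list()
    allele <- list()
    truth <- list()
    for (g in c("IVF", "SCNT")) {
      sim <- simulate_group(config, ann, base, snps, g)
      counts[[g]] <- sim$counts
      allele[[g]] <- sim$allele
      truth[[g]] <- sim$truth
    }
    structure(list(counts = counts, allele = allele, genes = ann,
                   truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                   config = config),
              class = "synthetic_dataset")
  })
}

simulate_snp_annotation <- function(config) {
  n <- config$n_snps
  lens <- chrom_lengths()
  auto <- setdiff(names(lens), "X")  # informative SNPs kept autosomal
  chrom <- sample(auto, n, replace = TRUE, prob = lens[auto] / sum(lens[auto]))
  bases <- c("A", "C", "G", "T")
  mat_allele <- sample(bases, n, replace = TRUE)
  fet_allele <- vapply(mat_allele, function(b) sample(setdiff(bases, b), 1),
                       character(1), USE.NAMES = FALSE)
  data.frame(snp_id = sprintf("snp%04d", seq_len(n)),
             chrom = chrom,
             pos = 1L + as.integer(floor(stats::runif(n) * (lens[chrom] - 1))),
             maternal_allele = mat_allele,
             fetal_allele = fet_allele,
             stringsAsFactors = FALSE)
}

simulate_group <- function(config, ann, base, snps, group) {
  n <- config$n_nuclei_per_group
  G <- nrow(ann)
  types <- if (n > 0) {
    sample(major_types(), n, replace = TRUE,
           prob = config$major_type_fractions[[group]][major_types()])
  } else character(0)
  subtypes <- rep(NA_character_, n)
  tb <- which(types == "trophoblast")
  if (length(tb)) {
    subtypes[tb] <- sample(
      trophoblast_subtypes(), length(tb), replace = TRUE,
      prob = config$trophoblast_subtype_fractions[[group]][trophoblast_subtypes()])
  }
  origin <- ifelse(types == "decidual_stroma", "maternal", "fetal")
  imm <- which(types == "immune")
  if (length(imm)) {
    fetal_imm <- stats::runif(length(imm)) < config$fetal_immune_fraction
    origin[imm] <- ifelse(fetal_imm, "fetal", "maternal")
  }
  lib <- if (n > 0) {
    stats::rlnorm(n, config$libsize_lognorm[1], config$libsize_lognorm[2])
  } else numeric(0)

  M <- base %o% lib  # genes x nuclei mean matrix
  # marker folds: major-type markers and LR genes homed at a type
  for (tt in major_types()) {
    cols <- which(types == tt)
    if (!length(cols)) next
    rows <- which(ann$role == "major_marker" & ann$panel == tt)
    if (length(rows)) M[rows, cols] <- M[rows, cols] * config$marker_fold
    lr_rows <- which(ann$role == "lr" & ann$panel == tt)
    if (length(lr_rows)) {
      M[lr_rows, cols] <- M[lr_rows, cols] * config$lr_marker_fold
    }
  }
  for (st in trophoblast_subtypes()) {
    cols <- which(!is.na(subtypes) & subtypes == st)
    if (!length(cols)) next
    rows <- which(ann$role == "subtype_marker" & ann$panel == st)
    if (length(rows)) M[rows, cols] <- M[rows, cols] * config$marker_fold
  }
  if (group == "SCNT" && n > 0) {
    fetal_cluster_cols <- which(types != "decidual_stroma")
    fetal_origin_cols <- which(origin == "fetal")
    rows_chromatin <- which(ann$role == "chromatin")
    rows_noncanon <- which(ann$role == "imprint_noncanonical")
    rows_canon_aff <- which(ann$canonical_affected)
    rows_x <- which(ann$chrom == "X" & ann$gene != "Xist")
    rows_planted <- which(ann$planted_x)
    row_xist <- which(ann$gene == "Xist")
    mul <- function(rows, cols, f) {
      if (length(rows) && length(cols) && f != 1) {
        M[rows, cols] <<- M[rows, cols] * f
      }
    }
    mul(rows_chromatin, fetal_cluster_cols, config$chromatin_fold)
    mul(rows_noncanon, fetal_cluster_cols, config$noncanonical_imprint_fold)
    mul(rows_canon_aff, fetal_cluster_cols, config$canonical_imprint_fold)
    mul(rows_x, fetal_origin_cols, config$x_repression_factor)
    # planted genes already carry the global factor; top up to planted fold
    mul(rows_planted, fetal_origin_cols,
        config$planted_x_fold / config$x_repression_factor)
    mul(row_xist, which(types == "trophoblast"), config$xist_scnt_fold)
    rows_boost <- which(ann$gene %in% config$boost_ligands)
    mul(rows_boost, which(types == "decidual_stroma"), config$interaction_fold)
  }

  vals <- if (n > 0) {
    if (config$nb_dispersion > 0) {
      stats::rnbinom(length(M), size = 1 / config$nb_dispersion,
                     mu = as.vector(M))
    } else {
      stats::rpois(length(M), as.vector(M))
    }
  } else numeric(0)
  barcodes <- if (n > 0) sprintf("%s_%05d", group, seq_len(n)) else character(0)
  cm <- Matrix::Matrix(matrix(as.double(vals), nrow = G, ncol = n),
                       sparse = TRUE)
  cm <- methods::as(cm, "generalMatrix")
  dimnames(cm) <- list(ann$gene, barcodes)

  ac <- simulate_allele_counts(config, snps, origin, barcodes)
  truth <- data.frame(barcode = barcodes, group = rep(group, n),
                      major_type = types, subtype = subtypes,
                      origin = origin, stringsAsFactors = FALSE)
  list(counts = cm, allele = ac, truth = truth)
}

simulate_allele_counts <- function(config, snps, origin, barcodes) {
  n <- length(barcodes)
  S <- config$n_snps
  cov <- matrix(stats::rpois(S * n, config$snp_coverage_mean), nrow = S)
  p_mat <- ifelse(origin == "maternal", 1 - config$allele_error,
                  config$allele_error)
  m_reads <- matrix(stats::rbinom(S * n, as.vector(cov),
                                  rep(p_mat, each = S)), nrow = S)
  f_reads <- cov - m_reads
  mk <- function(x) {
    sm <- Matrix::Matrix(matrix(as.double(x), nrow = S, ncol = n),
                         sparse = TRUE)
    sm <- methods::as(sm, "generalMatrix")
    dimnames(sm) <- list(snps$snp_id, barcodes)
    sm
  }
  allele_counts(mk(m_reads), mk(f_reads), snps)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:",
      paste(sprintf("%s (%d nuclei)", names(x$counts),
                    vapply(x$counts, ncol, integer(1))), collapse = ", "),
      "\n  genes:", nrow(x$genes),
      " SNPs:", nrow(x$allele[[1]]$snps), "\n")
  invisible(x)
}
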