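#' Read a CellRanger-style sparse count matrix directory
#'
#' Expects `matrix.mtx` (Matrix Market coordinate, 1-based indices,
#' genes x nuclei), `features.tsv` (gene ids, one per row, first column
#' used) and `barcodes.tsv` (one barcode per row).  Row and column counts
#' are validated against the MTX header; negative or non-integer values
#' are rejected.
#'
#' @param directory Path containing the three files.
#' @return A `dgCMatrix` with genes as rows (rownames = gene ids) and
#'   nuclei as columns (colnames = barcodes).
#' @export
read_count_matrix <- function(directory) {
  mtx_path <- file.path(directory, "matrix.mtx")
  feat_path <- file.path(directory, "features.tsv")
  bc_path <- file.path(directory, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  m <- read_mtx_file(mtx_path)
  if (any(m@x < 0)) {
    stop("matrix.mtx: negative entries are not valid counts", call. = FALSE)
  }
  if (any(m@x != round(m@x))) {
    stop("matrix.mtx: non-integer entries are not valid counts",
         call. = FALSE)
  }
  feats <- read_id_column(feat_path)
  bcs <- read_id_column(bc_path)
  if (length(feats) != nrow(m)) {
    stop(sprintf("features.tsv declares %d genes but matrix.mtx has %d rows",
                 length(feats), nrow(m)), call. = FALSE)
  }
  if (length(bcs) != ncol(m)) {
    stop(sprintf("barcodes.tsv declares %d nuclei but matrix.mtx has %d columns",
                 length(bcs), ncol(m)), call. = FALSE)
  }
  if (anyDuplicated(feats)) stop("features.tsv: duplicate gene ids", call. = FALSE)
  if (anyDuplicated(bcs)) stop("barcodes.tsv: duplicate barcodes", call. = FALSE)
  dimnames(m) <- list(feats, bcs)
  m
}

# read an MTX file and normalize to a numeric general CsparseMatrix
# (writeMM emits `symmetric` or `pattern` variants when they apply)
read_mtx_file <- function(path) {
  m <- Matrix::readMM(path)
  m <- methods::as(m, "dMatrix")        # pattern -> numeric
  m <- methods::as(m, "generalMatrix")  # symmetric -> general
  methods::as(m, "CsparseMatrix")
}

# first column of a headerless TSV id file
read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

write_id_column <- function(ids, path) {
  writeLines(as.character(ids), path)
}

# Matrix Market writer for integer-valued sparse matrices
write_mtx <- function(m, path) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' Read paired allele-count matrices for strain-informative SNPs
#'
#' Expects `allele_maternal.mtx` and `allele_fetal.mtx` (SNPs x nuclei,
#' same dimensions and index order), `snps.tsv` (columns `snp_id`,
#' `chrom`, `pos`, `maternal_allele`, `fetal_allele`) and `barcodes.tsv`.
#' SNPs whose two strain alleles are identical carry no information and
#' are rejected.
#'
#' @param directory Path containing the files.
#' @return An object of class `allele_counts`: a list with sparse
#'   matrices `maternal` and `fetal` plus the `snps` annotation
#'   data.frame.
#' @export
read_allele_counts <- function(directory) {
  mat <- read_mtx_file(file.path(directory, "allele_maternal.mtx"))
  fet <- read_mtx_file(file.path(directory, "allele_fetal.mtx"))
  snps <- utils::read.delim(file.path(directory, "snps.tsv"),
                            stringsAsFactors = FALSE)
  bcs <- read_id_column(file.path(directory, "barcodes.tsv"))
  if (!all(dim(mat) == dim(fet))) {
    stop("allele_maternal.mtx and allele_fetal.mtx dimensions differ",
         call. = FALSE)
  }
  if (nrow(snps) != nrow(mat)) {
    stop(sprintf("snps.tsv declares %d SNPs but matrices have %d rows",
                 nrow(snps), nrow(mat)), call. = FALSE)
  }
  if (length(bcs) != ncol(mat)) {
    stop("barcodes.tsv length does not match allele matrix columns",
         call. = FALSE)
  }
  if (any(mat@x < 0) || any(fet@x < 0)) {
    stop("allele matrices contain negative read counts", call. = FALSE)
  }
  if (nrow(snps) && any(snps$maternal_allele == snps$fetal_allele)) {
    bad <- which(snps$maternal_allele == snps$fetal_allele)[1]
    stop(sprintf("snps.tsv line %d: maternal and fetal alleles identical (uninformative SNP)",
                 bad + 1L), call. = FALSE)
  }
  if (nrow(snps) && any(snps$pos <= 0)) {
    stop("snps.tsv: positions must be positive (1-based)", call. = FALSE)
  }
  mk <- function(x) {
    dimnames(x) <- list(snps$snp_id, bcs)
    x
  }
  allele_counts(mk(mat), mk(fet), snps)
}

#' Construct an allele_counts object
#'
#' @param maternal,fetal Sparse SNP x nuclei matrices of reads carrying
#'   the maternal-strain and fetal-strain allele respectively.
#' @param snps SNP annotation data.frame.
#' @return `allele_counts` object.
#' @export
allele_counts <- function(maternal, fetal, snps) {
  stopifnot(all(dim(maternal) == dim(fetal)))
  structure(list(maternal = maternal, fetal = fetal, snps = snps),
            class = "allele_counts")
}

#' Read gene panels (markers, imprinted sets, chromatin modifiers)
#'
#' The panel file is a TSV with columns `panel`, `role`, `gene`.
#' Recognised roles: `major`, `subtype`, `imprint_noncanonical`,
#' `imprint_canonical`, `chromatin`.  A gene repeated within one panel is
#' deduplicated with a warning; an unknown role is an error.
#'
#' @param path Panel TSV path; defaults to the fixture shipped with the
#'   package.
#' @return Named list of panels split by role; each role holds a named
#'   list of character vectors (panel -> gene symbols).
#' @export
read_panels <- function(path = system.file("extdata", "panels.tsv",
                                           package = "snPlacenta")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("panel", "role", "gene")
  if (!all(need %in% names(tab))) {
    stop("panel file must have columns panel, role, gene", call. = FALSE)
  }
  known <- c("major", "subtype", "imprint_noncanonical",
             "imprint_canonical", "chromatin")
  bad <- setdiff(unique(tab$role), known)
  if (length(bad)) {
    stop("unknown panel role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(tab[c("panel", "gene")])
  if (any(dup)) {
    warning(sum(dup), " duplicated gene(s) within a panel were dropped")
    tab <- tab[!dup, ]
  }
  out <- lapply(split(tab, tab$role), function(d) {
    lapply(split(d$gene, d$panel), as.character)
  })
  out[intersect(known, names(out))]
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns `ligand`, `receptor`, `pathway`; optional
#' `ligand_type` / `receptor_type` columns are generator hints naming the
#' cell type in which the synthetic generator plants high expression of
#' each gene (ignored by the analysis functions).  Pairs with identical
#' ligand and receptor are rejected.
#'
#' @param path LR TSV path; defaults to the shipped 15-pathway fixture.
#' @return data.frame of LR pairs.
#' @export
read_lr_table <- function(path = system.file("extdata", "lr_pairs.tsv",
                                             package = "snPlacenta")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pathway")
  if (!all(need %in% names(tab))) {
    stop("LR table must have columns ligand, receptor, pathway",
         call. = FALSE)
  }
  if (any(tab$ligand == tab$receptor)) {
    stop("LR table: ligand and receptor must differ", call. = FALSE)
  }
  if (any(!nzchar(tab$pathway))) {
    stop("LR table: empty pathway name", call. = FALSE)
  }
  tab
}

#' Write a synthetic dataset to disk
#'
#' Emits, per group, a CellRanger-style triplet (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`) plus allele matrices
#' (`allele_maternal.mtx`, `allele_fetal.mtx`, `snps.tsv`), and at the top
#' level `genes.tsv` (annotation), `truth.tsv` (per-nucleus truth) and
#' `config.yaml`.  Reading back with [read_dataset()] reproduces the
#' dataset exactly.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return `directory`, invisibly.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (dir.exists(directory) && length(dir(directory)) && !overwrite) {
    stop("directory ", directory,
         " is non-empty; pass overwrite = TRUE to replace", call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (g in names(dataset$counts)) {
    gd <- file.path(directory, g)
    dir.create(gd, showWarnings = FALSE)
    m <- dataset$counts[[g]]
    write_mtx(m, file.path(gd, "matrix.mtx"))
    write_id_column(rownames(m), file.path(gd, "features.tsv"))
    write_id_column(colnames(m), file.path(gd, "barcodes.tsv"))
    ac <- dataset$allele[[g]]
    write_mtx(ac$maternal, file.path(gd, "allele_maternal.mtx"))
    write_mtx(ac$fetal, file.path(gd, "allele_fetal.mtx"))
    utils::write.table(ac$snps, file.path(gd, "snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$genes, file.path(directory, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(directory, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg$panels <- NULL  # panels are fixture files, not scalar config
  cfg$lr_table <- NULL
  yaml::write_yaml(cfg, file.path(directory, "config.yaml"))
  invisible(directory)
}

#' Read back a synthetic dataset written by [write_dataset()]
#'
#' @param directory Dataset directory.
#' @return A `synthetic_dataset` (the `config` element holds only the
#'   scalar configuration echoed to `config.yaml`).
#' @export
read_dataset <- function(directory) {
  groups <- intersect(c("IVF", "SCNT"), dir(directory))
  if (!length(groups)) stop("no group subdirectories under ", directory)
  counts <- lapply(groups, function(g) read_count_matrix(file.path(directory, g)))
  allele <- lapply(groups, function(g) read_allele_counts(file.path(directory, g)))
  names(counts) <- names(allele) <- groups
  genes <- utils::read.delim(file.path(directory, "genes.tsv"),
                             stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(directory, "truth.tsv"),
                             stringsAsFactors = FALSE)
  cfg_path <- file.path(directory, "config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(list(counts = counts, allele = allele, genes = genes,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}
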