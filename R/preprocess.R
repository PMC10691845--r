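#' Quality-control parameters
#'
#' Per-nucleus thresholds applied by [qc_filter()].  Defaults follow
#' common snRNA-seq practice (the thresholds behind published nucleus
#' counts are rarely stated): at least 200 detected genes and total
#' counts between 500 and 50000.
#'
#' @param min_genes_detected Minimum genes with nonzero counts.
#' @param min_total_counts Minimum total counts per nucleus.
#' @param max_total_counts Maximum total counts per nucleus.
#' @return `qc_params` object.
#' @export
qc_params <- function(min_genes_detected = 200,
                      min_total_counts = 500,
                      max_total_counts = 50000) {
  if (min_total_counts > max_total_counts) {
    stop("min_total_counts must be <= max_total_counts", call. = FALSE)
  }
  if (min_genes_detected < 0 || min_total_counts < 0) {
    stop("QC thresholds must be nonnegative", call. = FALSE)
  }
  structure(list(min_genes_detected = min_genes_detected,
                 min_total_counts = min_total_counts,
                 max_total_counts = max_total_counts),
            class = "qc_params")
}

#' Filter nuclei on detected genes and total counts
#'
#' Removes nuclei failing any criterion; the gene set is never altered.
#' The attached report records how many nuclei each criterion removed
#' (a nucleus can fail several).
#'
#' @param counts Raw gene x nucleus count matrix.
#' @param params [qc_params()].
#' @return List with `counts` (filtered matrix) and `report` (data.frame
#'   of per-criterion removal counts and totals).
#' @export
qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  fail_genes <- detected < params$min_genes_detected
  fail_low <- totals < params$min_total_counts
  fail_high <- totals > params$max_total_counts
  keep <- !(fail_genes | fail_low | fail_high)
  if (!any(keep)) {
    stop("QC removed every nucleus; review qc_params thresholds",
         call. = FALSE)
  }
  report <- data.frame(
    criterion = c("min_genes_detected", "min_total_counts",
                  "max_total_counts", "total_removed", "retained"),
    n = c(sum(fail_genes), sum(fail_low), sum(fail_high),
          sum(!keep), sum(keep)))
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Depth-normalize a count matrix (counts per 10k, log1p)
#'
#' Each nucleus is scaled to a total of 10000 counts and transformed with
#' `log1p`.  Zeros are preserved, so sparsity is unchanged.  Nuclei with
#' zero total counts are an error: they should have been removed by QC.
#'
#' @param counts Raw gene x nucleus count matrix.
#' @return Sparse normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0),
         " nucleus/nuclei have zero total counts; run qc_filter first",
         call. = FALSE)
  }
  scaled <- counts %*% Matrix::Diagonal(x = 1e4 / totals)
  dimnames(scaled) <- dimnames(counts)
  out <- scaled
  out@x <- log1p(out@x)
  out
}
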