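#' Score nuclei against marker panels
#'
#' For each panel, the score of a nucleus is the mean over panel genes of
#' that gene's z-scored normalized expression (z across all supplied
#' nuclei, groups pooled, so group effects shift scores without changing
#' within-type rankings).  Genes with zero variance contribute 0.  Panel
#' genes absent from the matrix are ignored; a panel with no genes
#' present at all is an error.
#'
#' @param norm Normalized gene x nucleus matrix (see
#'   [normalize_counts()]).
#' @param panels Named list of character vectors (type -> marker
#'   symbols).
#' @return Numeric matrix, nuclei x panels.
#' @export
marker_scores <- function(norm, panels) {
  stopifnot(is.list(panels), length(panels) > 0)
  all_genes <- unique(unlist(panels))
  present <- intersect(all_genes, rownames(norm))
  missing_panels <- names(panels)[vapply(panels, function(g) {
    !any(g %in% present)
  }, logical(1))]
  if (length(missing_panels)) {
    stop("no panel genes present in matrix for: ",
         paste(missing_panels, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(norm[present, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- sqrt(rowMeans((x - mu)^2))  # population sd; only zero-ness matters
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  scores <- vapply(panels, function(genes) {
    g <- intersect(genes, present)
    colMeans(z[g, , drop = FALSE])
  }, numeric(ncol(norm)))
  if (ncol(norm) == 1L) scores <- matrix(scores, nrow = 1L,
                                         dimnames = list(colnames(norm),
                                                         names(panels)))
  rownames(scores) <- colnames(norm)
  scores
}

#' Assign a type label from a score table
#'
#' Label = argmax panel score; when the top two scores differ by less
#' than `margin` the nucleus is labelled `"ambiguous"`.  Exact ties are
#' broken lexicographically by type name, so assignment is deterministic.
#'
#' @param scores Nuclei x types score matrix from [marker_scores()].
#' @param margin Minimum lead of the top score (default 0.1 z-units).
#' @return Character vector of labels named by barcode.
#' @export
assign_types <- function(scores, margin = 0.1) {
  stopifnot(is.matrix(scores), all(is.finite(scores)))
  types <- colnames(scores)[order(colnames(scores))]
  scores <- scores[, types, drop = FALSE]  # lexicographic tie-break
  labels <- apply(scores, 1L, function(s) {
    top <- which.max(s)  # first max = lexicographically smallest
    if (ncol(scores) > 1L) {
      second <- max(s[-top])
      if (s[top] - second < margin) return("ambiguous")
    }
    types[top]
  })
  stats::setNames(as.character(labels), rownames(scores))
}

#' Annotate major cell types
#'
#' Convenience wrapper: [marker_scores()] then [assign_types()].
#'
#' @inheritParams marker_scores
#' @inheritParams assign_types
#' @return Character label vector named by barcode.
#' @export
annotate_major <- function(norm, panels, margin = 0.1) {
  assign_types(marker_scores(norm, panels), margin = margin)
}

#' Annotate trophoblast subtypes
#'
#' Re-runs marker scoring restricted to the trophoblast nuclei and the
#' subtype panels (z-scores are recomputed within the trophoblast
#' compartment, where subtype contrasts live).  Non-trophoblast nuclei
#' are not relabelled.
#'
#' @param norm Normalized matrix over all nuclei.
#' @param major_labels Labels from [annotate_major()], aligned to
#'   `colnames(norm)`.
#' @param subtype_panels Named list of subtype marker vectors.
#' @param margin Ambiguity margin, as in [assign_types()].
#' @return Character vector of subtype labels named by barcode, for
#'   trophoblast nuclei only (empty, with a warning, when there are
#'   none).
#' @export
subcluster_trophoblast <- function(norm, major_labels, subtype_panels,
                                   margin = 0.1) {
  stopifnot(length(major_labels) == ncol(norm))
  tb <- colnames(norm)[major_labels == "trophoblast"]
  if (!length(tb)) {
    warning("no trophoblast nuclei to subcluster")
    return(stats::setNames(character(0), character(0)))
  }
  sub <- norm[, tb, drop = FALSE]
  assign_types(marker_scores(sub, subtype_panels), margin = margin)
}
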