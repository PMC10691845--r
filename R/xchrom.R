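#' Per-nucleus X-to-autosome read ratio
#'
#' Ratio of summed raw counts on chromosome X to summed raw counts on
#' the autosomes, the standard single-cell X-dosage statistic.  Computed
#' on raw counts (reads), so it is invariant to per-nucleus depth
#' scaling.  Genes listed in `exclude` (for example `"Xist"`, whose
#' upregulation in clones inflates the X sum against the repression
#' signal) are omitted from both sums.
#'
#' @param counts Raw gene x nucleus count matrix.
#' @param annotation Gene annotation data.frame with `gene` and `chrom`
#'   covering every matrix gene.
#' @param exclude Gene symbols to drop before summing (default none).
#' @return data.frame with `barcode`, `x_counts`, `autosome_counts`,
#'   `ratio` (`NA` when the autosomal sum is 0).
#' @export
xa_ratio <- function(counts, annotation, exclude = character(0)) {
  chrom <- stats::setNames(annotation$chrom, annotation$gene)
  if (any(!rownames(counts) %in% names(chrom))) {
    stop("annotation does not cover every matrix gene", call. = FALSE)
  }
  gene_chrom <- chrom[rownames(counts)]
  keep <- !(rownames(counts) %in% exclude)
  x_rows <- keep & gene_chrom == "X"
  a_rows <- keep & gene_chrom != "X"
  xs <- Matrix::colSums(counts[x_rows, , drop = FALSE])
  as_ <- Matrix::colSums(counts[a_rows, , drop = FALSE])
  data.frame(barcode = colnames(counts),
             x_counts = as.numeric(xs), autosome_counts = as.numeric(as_),
             ratio = ifelse(as_ > 0, xs / as_, NA_real_),
             stringsAsFactors = FALSE)
}

#' Compare X:A ratios between groups within each cluster
#'
#' Per-cluster Wilcoxon rank-sum test of the per-nucleus X:A ratio
#' between IVF and SCNT, with group medians and star labels.
#'
#' @param ratios Output of [xa_ratio()] over all nuclei.
#' @param labels Named cluster labels aligned by barcode.
#' @param groups Group vector aligned to `labels`.
#' @return data.frame per cluster: medians, median ratio
#'   (SCNT over IVF), `p`, `stars`.
#' @export
compare_xa <- function(ratios, labels, groups) {
  r <- stats::setNames(ratios$ratio, ratios$barcode)[names(labels)]
  clusters <- sort(setdiff(unique(labels), "ambiguous"))
  out <- do.call(rbind, lapply(clusters, function(cl) {
    iv <- r[labels == cl & groups == "IVF"]
    sc <- r[labels == cl & groups == "SCNT"]
    iv <- iv[!is.na(iv)]
    sc <- sc[!is.na(sc)]
    if (!length(iv) || !length(sc)) return(NULL)
    wt <- wilcoxon_rank_sum(sc, iv)
    data.frame(cluster = cl,
               median_ivf = stats::median(iv),
               median_scnt = stats::median(sc),
               median_ratio = stats::median(sc) / stats::median(iv),
               p = wt$p, stars = stars(wt$p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' X-linked genes consistently changed across fetal clusters
#'
#' Collects X-linked genes that qualify as differentially expressed
#' (`q < fdr` and `|log2FC| >= min_l2fc`) in every listed fetal cluster
#' of a [de_by_cluster()] table, with the same direction of change
#' throughout.  The effect-size requirement (default 1.4-fold, the
#' common single-cell DEG convention) distinguishes severe gene-level
#' repression from the mild chromosome-wide dosage shift that an X
#' inactivation defect imposes on every X-linked gene.  Decidual stroma
#' is maternal and the immune compartment is of mixed origin, so the
#' default cluster set is [fetal_types()].
#'
#' @param de DE table from [de_by_cluster()].
#' @param annotation Gene annotation with `gene`, `chrom`.
#' @param clusters Clusters that must all agree (default
#'   [fetal_types()], intersected with the clusters present).
#' @param fdr Significance threshold on `q` (default 0.05).
#' @param min_l2fc Minimum absolute log2 fold change (default 0.5).
#' @return data.frame with `gene`, `direction`, `max_q`, plus the number
#'   of clusters consulted as attribute `n_clusters`.
#' @export
x_de_summary <- function(de, annotation, clusters = fetal_types(),
                         fdr = 0.05, min_l2fc = 0.5) {
  clusters <- intersect(clusters, unique(de$cluster))
  if (!length(clusters)) stop("none of the requested clusters in DE table")
  x_genes <- annotation$gene[annotation$chrom == "X"]
  sub <- de[de$cluster %in% clusters & de$gene %in% x_genes, ]
  hit <- do.call(rbind, lapply(split(sub, sub$gene), function(d) {
    if (nrow(d) < length(clusters)) return(NULL)
    if (any(d$q >= fdr | abs(d$log2fc) < min_l2fc)) return(NULL)
    if (length(unique(d$direction)) != 1) return(NULL)
    data.frame(gene = d$gene[1], direction = d$direction[1],
               max_q = max(d$q), stringsAsFactors = FALSE)
  }))
  if (is.null(hit)) {
    hit <- data.frame(gene = character(0), direction = character(0),
                      max_q = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(hit) <- NULL
  attr(hit, "n_clusters") <- length(clusters)
  hit
}

#' Positional spread of a gene set along chromosome X
#'
#' Kolmogorov-Smirnov test of the gene start positions against a uniform
#' distribution over the X chromosome length, asking whether a
#' differential set is concentrated in local regions or spread along the
#' chromosome.
#'
#' @param gene_set Character vector of gene symbols.
#' @param annotation Gene annotation with `gene`, `chrom`, `start`.
#' @return List with `n`, `ks_statistic`, `p`; `NULL` (with a warning)
#'   when fewer than 2 genes are on X.
#' @export
x_position_spread <- function(gene_set, annotation) {
  pos <- annotation$start[annotation$gene %in% gene_set &
                            annotation$chrom == "X"]
  if (length(pos) < 2) {
    warning("fewer than 2 X-linked genes; spread test skipped")
    return(NULL)
  }
  len <- chrom_lengths()[["X"]]
  kt <- suppressWarnings(stats::ks.test(pos, "punif", 0, len))
  list(n = length(pos), ks_statistic = unname(kt$statistic),
       p = kt$p.value)
}

#' Imprinted-gene panel expression summaries per cluster
#'
#' For each (cluster, panel gene): per-group CP10K means, log2 fold
#' change, Wilcoxon p, BH q (within cluster x panel) and stars.  Used
#' for both the non-canonical (H3K27me3-dependent) and canonical
#' (DNA-methylation-dependent) imprinted panels.
#'
#' @param norm Normalized matrix, both groups.
#' @param labels Named cluster labels.
#' @param groups Group vector aligned to `labels`.
#' @param panels Named list of gene-symbol vectors (panels must be
#'   disjoint and non-empty).
#' @param min_cells Minimum nuclei per group per cluster (default 20).
#' @return data.frame: `panel`, `cluster`, `gene`, means, `log2fc`, `p`,
#'   `q`, `stars`.
#' @export
imprinted_panel_summary <- function(norm, labels, groups, panels,
                                    min_cells = 20) {
  if (!length(panels) || any(!lengths(panels))) {
    stop("panels must be non-empty", call. = FALSE)
  }
  if (length(panels) > 1) {
    all_genes <- unlist(panels)
    if (anyDuplicated(all_genes)) {
      stop("imprinted panels must be disjoint", call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(names(panels), function(pn) {
    genes <- intersect(panels[[pn]], rownames(norm))
    if (!length(genes)) stop("no genes of panel ", pn, " in matrix")
    de <- suppressWarnings(
      de_by_cluster(norm, labels, groups, min_cells = min_cells,
                    genes = genes))
    cbind(panel = pn, de, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify ICR methylation states from beta values
#'
#' Threshold classifier for imprinting-control-region methylation:
#' `hypo` below `hypo`, `hyper` above `hyper`, `normal` between.  An ICR
#' in a faithfully reprogrammed sample is expected near 0.5 (one
#' methylated parental allele).
#'
#' @param beta Numeric vector of methylation beta values in `[0, 1]`.
#' @param hypo Lower threshold (default 0.25).
#' @param hyper Upper threshold (default 0.75).
#' @return Character vector of states.
#' @export
classify_icr <- function(beta, hypo = 0.25, hyper = 0.75) {
  stopifnot(hypo < hyper)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(beta < hypo, "hypo", ifelse(beta > hyper, "hyper", "normal"))
}
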