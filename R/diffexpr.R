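#' Two-sample Wilcoxon rank-sum test
#'
#' Internally implemented rank-sum test with midranks for ties.  The
#' statistic `W` is the rank sum of the first sample.  When both samples
#' have at most 10 observations and there are no ties, the two-sided
#' p-value is exact, by enumeration of all rank assignments; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.  When every value is identical across both
#' samples the test is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_max Largest per-sample size for the exact path
#'   (default 10).
#' @return List with `W` (rank sum of `x`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  all_v <- c(x, y)
  r <- rank(all_v)  # midranks
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (!has_ties && nx <= exact_max && ny <= exact_max) {
    # exact two-sided p: enumerate every assignment of ranks to sample x
    splits <- utils::combn(N, nx)
    sums <- colSums(matrix(seq_len(N)[splits], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(W = W, p = p))
  }
  cnt <- rle(sort(all_v))$lengths
  tie_term <- sum(cnt^3 - cnt)
  v <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    warning("all values identical across both samples; degenerate test")
    return(list(W = W, p = 1))
  }
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  list(W = W, p = 2 * stats::pnorm(-abs(z)))
}

# vectorized normal-approximation Wilcoxon over the rows of a dense
# matrix; group1 is a logical column selector.  Returns W (rank sum of
# group1) and two-sided p per row.
wilcoxon_rows <- function(mat, group1) {
  nx <- sum(group1)
  ny <- sum(!group1)
  N <- nx + ny
  mu <- nx * (N + 1) / 2
  res <- apply(mat, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[group1])
    cnt <- rle(sort(v))$lengths
    tie_term <- sum(cnt^3 - cnt)
    vv <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (vv <= 0) return(c(W, 1))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(vv)
    c(W, 2 * stats::pnorm(-abs(z)))
  })
  list(W = res[1, ], p = res[2, ])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up procedure; input order is preserved and `NA`s are
#' propagated without counting toward the number of tests.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  q[ok[o]] <- adj
  q
}

#' Significance-star labels
#'
#' Conventional four-step ladder: `ns` for p >= 0.05, then `*` (< 0.05),
#' `**` (< 0.01), `***` (< 0.001), `****` (< 0.0001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |> as.character()
}

#' Per-cluster differential expression between groups
#'
#' For every cluster with at least `min_cells` nuclei in both groups,
#' tests every gene with the Wilcoxon rank-sum test on normalized
#' expression and adjusts with BH within the cluster.  The fold change is
#' `log2((mean2 + 1) / (mean1 + 1))` of the group means on the CP10K
#' scale (pseudocount 1 stabilises zero means), where group 2 is `SCNT`
#' and group 1 is `IVF`, so positive values mean higher in SCNT.
#'
#' @param norm Normalized gene x nucleus matrix, both groups
#'   concatenated.
#' @param labels Named cluster label vector aligned to `colnames(norm)`.
#' @param groups Group vector aligned to columns (`"IVF"` / `"SCNT"`).
#' @param min_cells Minimum nuclei per group per cluster (default 20);
#'   clusters below this are skipped with a warning.
#' @param genes Optional subset of genes to test (default all).
#' @return data.frame with `cluster`, `gene`, per-group means, `log2fc`,
#'   `W`, `p`, `q`, `direction`, `stars`.
#' @export
de_by_cluster <- function(norm, labels, groups, min_cells = 20,
                          genes = rownames(norm)) {
  stopifnot(length(labels) == ncol(norm), length(groups) == ncol(norm))
  genes <- intersect(genes, rownames(norm))
  clusters <- sort(setdiff(unique(labels), "ambiguous"))
  pieces <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    n_ivf <- sum(in_cl & groups == "IVF")
    n_scnt <- sum(in_cl & groups == "SCNT")
    if (n_ivf < min_cells || n_scnt < min_cells) {
      warning(sprintf("cluster %s skipped: %d IVF / %d SCNT nuclei (< %d)",
                      cl, n_ivf, n_scnt, min_cells))
      next
    }
    sub <- as.matrix(norm[genes, in_cl, drop = FALSE])
    is_scnt <- groups[in_cl] == "SCNT"
    wt <- wilcoxon_rows(sub, is_scnt)
    # means on the CP10K scale (undo log1p) for the fold change
    cp10k <- expm1(sub)
    mean_ivf <- rowMeans(cp10k[, !is_scnt, drop = FALSE])
    mean_scnt <- rowMeans(cp10k[, is_scnt, drop = FALSE])
    l2fc <- log2((mean_scnt + 1) / (mean_ivf + 1))
    q <- bh_adjust(wt$p)
    pieces[[cl]] <- data.frame(
      cluster = cl, gene = genes,
      mean_ivf = mean_ivf, mean_scnt = mean_scnt,
      log2fc = l2fc, W = wt$W, p = wt$p, q = q,
      direction = ifelse(l2fc > 0, "up", ifelse(l2fc < 0, "down", "none")),
      stars = stars(wt$p), stringsAsFactors = FALSE)
  }
  if (!length(pieces)) {
    stop("no cluster has at least ", min_cells,
         " nuclei in both groups", call. = FALSE)
  }
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation (hypergeometric upper tail)
#'
#' Probability of observing at least the seen overlap between a hit list
#' and a gene set when drawing `|hits|` genes from the universe without
#' replacement: `P(X >= k)`.
#'
#' @param hits Character vector of hit genes (e.g. significant DEGs).
#' @param gene_set Character vector, the panel being tested.
#' @param universe Character vector of all testable genes.
#' @return List with `overlap`, `expected`, `p`.
#' @export
set_overrepresentation <- function(hits, gene_set, universe) {
  hits <- intersect(unique(hits), universe)
  gene_set <- intersect(unique(gene_set), universe)
  k <- length(intersect(hits, gene_set))
  m <- length(gene_set)
  n <- length(universe) - m
  drawn <- length(hits)
  p <- stats::phyper(k - 1, m, n, drawn, lower.tail = FALSE)
  list(overlap = k, expected = drawn * m / length(universe), p = p)
}
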