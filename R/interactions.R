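# mean normalized expression of the given genes per cell type
type_means <- function(expr, labels, types) {
  sums <- vapply(types, function(tt) {
    cols <- which(labels == tt)
    rowSums(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  if (nrow(expr) == 1L) sums <- matrix(sums, nrow = 1L)
  counts <- vapply(types, function(tt) sum(labels == tt), numeric(1))
  sweep(sums, 2L, pmax(counts, 1), "/")
}

#' Ligand-receptor communication scores
#'
#' Simplified cell-cell communication scoring: for every ordered
#' (sender, receiver) pair of annotated cell types and every
#' ligand-receptor pair, the score is the mean normalized ligand
#' expression in the sender times the mean normalized receptor
#' expression in the receiver.  Types with fewer than `min_cells` nuclei
#' are not scored; LR pairs whose ligand or receptor is absent from the
#' matrix are skipped with a warning.
#'
#' @param norm Normalized gene x nucleus matrix (one group).
#' @param labels Named cell-type labels aligned to `colnames(norm)`.
#' @param lr_table data.frame from [read_lr_table()].
#' @param min_cells Minimum nuclei per type (default 10).
#' @return data.frame: `sender`, `receiver`, `ligand`, `receptor`,
#'   `pathway`, `score`.
#' @export
lr_scores <- function(norm, labels, lr_table, min_cells = 10) {
  stopifnot(length(labels) == ncol(norm))
  present <- lr_table$ligand %in% rownames(norm) &
    lr_table$receptor %in% rownames(norm)
  if (any(!present)) {
    warning(sum(!present), " LR pair(s) skipped: gene(s) absent from matrix")
  }
  lr <- lr_table[present, , drop = FALSE]
  if (!nrow(lr)) stop("no usable LR pairs", call. = FALSE)
  tab <- table(labels[labels != "ambiguous"])
  types <- sort(names(tab)[tab >= min_cells])
  if (!length(types)) stop("no cell type has >= ", min_cells, " nuclei")
  genes <- unique(c(lr$ligand, lr$receptor))
  expr <- as.matrix(norm[genes, , drop = FALSE])
  mu <- type_means(expr, labels, types)
  rownames(mu) <- genes
  grid <- expand.grid(sender = types, receiver = types,
                      pair = seq_len(nrow(lr)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    sender = grid$sender, receiver = grid$receiver,
    ligand = lr$ligand[grid$pair], receptor = lr$receptor[grid$pair],
    pathway = lr$pathway[grid$pair],
    score = mu[cbind(lr$ligand[grid$pair], grid$sender)] *
      mu[cbind(lr$receptor[grid$pair], grid$receiver)],
    stringsAsFactors = FALSE)
  out[order(out$pathway, out$ligand, out$receptor,
            out$sender, out$receiver), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Permutation test for LR communication scores
#'
#' Null distribution by permuting the cell-type labels across nuclei
#' (`n_perm` times, seeded): `p = (1 + #(permuted >= observed)) /
#' (1 + n_perm)`, so the smallest attainable p is `1 / (n_perm + 1)`.
#' A zero observed score always has `p = 1`.
#'
#' @param scores Score table from [lr_scores()].
#' @param norm,labels The matrix and labels the scores were computed
#'   from.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed (default 1).
#' @param alpha Significance threshold on `p` (default 0.05, no
#'   multiplicity correction, matching common practice in communication
#'   tools; apply [bh_adjust()] to the `p` column for a corrected
#'   variant).
#' @return `scores` with columns `p` and `significant` appended.
#' @export
lr_permutation_test <- function(scores, norm, labels, n_perm = 1000,
                                seed = 1, alpha = 0.05) {
  types <- sort(unique(c(scores$sender, scores$receiver)))
  genes <- unique(c(scores$ligand, scores$receptor))
  expr <- as.matrix(norm[genes, , drop = FALSE])
  rownames(expr) <- genes
  exceed <- numeric(nrow(scores))
  li <- match(scores$ligand, genes)
  ri <- match(scores$receptor, genes)
  si <- match(scores$sender, types)
  vi <- match(scores$receiver, types)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      mu <- type_means(expr, perm, types)
      perm_score <- mu[cbind(li, si)] * mu[cbind(ri, vi)]
      exceed <- exceed + (perm_score >= scores$score - 1e-12)
    }
  })
  scores$p <- (1 + exceed) / (1 + n_perm)
  scores$p[scores$score <= 0] <- 1
  scores$significant <- scores$p < alpha
  scores
}

#' Differential interaction network between two score tables
#'
#' Per (sender, receiver) cell-type pair: difference (second minus
#' first) in the number of significant LR pairs and in summed
#' significant score ("interaction strength").  Positive deltas mean
#' stronger communication in the second table.
#'
#' @param scores_1,scores_2 Score tables from [lr_permutation_test()]
#'   (e.g. IVF and SCNT).
#' @return data.frame: `sender`, `receiver`, `delta_n_significant`,
#'   `delta_strength`.
#' @export
differential_network <- function(scores_1, scores_2) {
  agg <- function(s) {
    s$strength <- ifelse(s$significant, s$score, 0)
    key <- interaction(s$sender, s$receiver, drop = FALSE, sep = "\r")
    data.frame(key = levels(key),
               n_sig = as.numeric(tapply(s$significant, key, sum)),
               strength = as.numeric(tapply(s$strength, key, sum)),
               stringsAsFactors = FALSE)
  }
  a1 <- agg(scores_1)
  a2 <- agg(scores_2)
  keys <- sort(union(a1$key, a2$key))
  g <- function(a, k, col) {
    v <- a[[col]][match(k, a$key)]
    ifelse(is.na(v), 0, v)
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    sender = vapply(parts, `[[`, character(1), 1L),
    receiver = vapply(parts, `[[`, character(1), 2L),
    delta_n_significant = g(a2, keys, "n_sig") - g(a1, keys, "n_sig"),
    delta_strength = g(a2, keys, "strength") - g(a1, keys, "strength"),
    stringsAsFactors = FALSE)
}

#' Per-pathway information flow
#'
#' Information flow of a pathway within a group = sum of its significant
#' communication scores; relative flow is normalized to sum to 1 within
#' the group (all-zero groups stay at 0).
#'
#' @param scores_by_group Named list of score tables from
#'   [lr_permutation_test()], one per group.
#' @return data.frame: `pathway`, then per group `flow_<group>` and
#'   `relflow_<group>`.
#' @export
pathway_information_flow <- function(scores_by_group) {
  pathways <- sort(unique(unlist(lapply(scores_by_group,
                                        function(s) s$pathway))))
  out <- data.frame(pathway = pathways, stringsAsFactors = FALSE)
  for (g in names(scores_by_group)) {
    s <- scores_by_group[[g]]
    s$strength <- ifelse(s$significant, s$score, 0)
    flow <- vapply(pathways, function(pw) {
      sum(s$strength[s$pathway == pw])
    }, numeric(1))
    rel <- if (sum(flow) > 0) flow / sum(flow) else flow
    out[[paste0("flow_", g)]] <- flow
    out[[paste0("relflow_", g)]] <- rel
  }
  out
}
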