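#' Join the per-group matrices of a dataset
#'
#' Binds the IVF and SCNT count matrices column-wise and returns the
#' aligned group vector and truth table.
#'
#' @param dataset A `synthetic_dataset`.
#' @return List with `counts`, `groups`, `truth`.
#' @export
join_groups <- function(dataset) {
  counts <- do.call(cbind, unname(dataset$counts))
  groups <- rep(names(dataset$counts),
                vapply(dataset$counts, ncol, integer(1)))
  list(counts = counts, groups = stats::setNames(groups, colnames(counts)),
       truth = dataset$truth)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$panels <- NULL
  cfg$lr_table <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes simulate (unless a dataset is supplied) -> QC -> normalize ->
#' annotate (major + trophoblast subtypes) -> origin -> composition ->
#' differential expression (+ chromatin-panel over-representation) ->
#' X:A / X DEG / imprinting summaries -> LR interaction network, writing
#' one TSV per analysis and a machine-readable `summary.json` of the
#' headline comparisons.  Every output directory is stamped with the
#' configuration hash and seed.
#'
#' @param out_dir Output directory for the stage TSVs.
#' @param config [sim_config()] used for simulation (and for panel /
#'   LR fixtures).
#' @param dataset Optional pre-built `synthetic_dataset` (skips
#'   simulation).
#' @param qc [qc_params()].
#' @param margin Annotation ambiguity margin.
#' @param error,tau,min_coverage Origin-classifier parameters.
#' @param min_cells Minimum nuclei per group per cluster for DE.
#' @param fdr DE significance threshold on q.
#' @param n_perm Interaction permutations.
#' @param overwrite Overwrite an existing non-empty `out_dir`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), dataset = NULL,
                         qc = qc_params(), margin = 0.1,
                         error = 0.01, tau = 0.99, min_coverage = 5,
                         min_cells = 20, fdr = 0.05, n_perm = 1000,
                         overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory ", out_dir, " is non-empty", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  ann <- dataset$genes
  joined <- join_groups(dataset)

  ## -- QC ------------------------------------------------------------
  qcres <- qc_filter(joined$counts, qc)
  counts <- qcres$counts
  groups <- joined$groups[colnames(counts)]
  write_tsv(qcres$report, file.path(out_dir, "qc_report.tsv"))
  norm <- normalize_counts(counts)

  ## -- annotation (fig 1D/1K analogs) ---------------------------------
  panels <- config$panels
  major <- annotate_major(norm, panels$major, margin = margin)
  subtypes <- subcluster_trophoblast(norm, major, panels$subtype,
                                     margin = margin)
  lab_tab <- data.frame(barcode = names(major), group = groups,
                        major_type = unname(major),
                        subtype = unname(subtypes[names(major)]),
                        stringsAsFactors = FALSE)
  write_tsv(lab_tab, file.path(out_dir, "labels.tsv"))

  ## -- origin (fig 1E analog) -----------------------------------------
  allele_joined <- allele_counts(
    do.call(cbind, lapply(unname(dataset$allele), `[[`, "maternal")),
    do.call(cbind, lapply(unname(dataset$allele), `[[`, "fetal")),
    dataset$allele[[1]]$snps)
  calls <- origin_calls(allele_joined, error = error, tau = tau,
                        min_coverage = min_coverage)
  calls <- calls[calls$barcode %in% names(major), ]
  write_tsv(calls, file.path(out_dir, "origin_calls.tsv"))
  origin_comp <- cluster_origin_composition(major, calls)
  write_tsv(origin_comp, file.path(out_dir, "origin_composition.tsv"))

  ## -- composition (fig 1F/1L analogs) --------------------------------
  prop <- type_proportions(major, groups)
  comp <- compare_type_proportions(prop)
  write_tsv(comp, file.path(out_dir, "composition.tsv"))
  tgc <- tgc_subtype_summary(subtypes, groups[names(subtypes)])
  write_tsv(tgc$shares, file.path(out_dir, "tgc_shares.tsv"))

  ## -- differential expression (fig 1G/1H analogs) --------------------
  de <- suppressWarnings(
    de_by_cluster(norm, major, groups, min_cells = min_cells))
  write_tsv(de, file.path(out_dir, "de.tsv"))
  universe <- rownames(norm)
  chromatin <- panels$chromatin[[1]]
  enr <- do.call(rbind, lapply(split(de, de$cluster), function(d) {
    hits <- d$gene[d$q < fdr & d$log2fc > 0]
    ora <- set_overrepresentation(hits, chromatin, universe)
    data.frame(cluster = d$cluster[1], n_up = length(hits),
               overlap = ora$overlap, expected = ora$expected,
               p = ora$p, stringsAsFactors = FALSE)
  }))
  rownames(enr) <- NULL
  write_tsv(enr, file.path(out_dir, "chromatin_enrichment.tsv"))

  ## -- X dosage and imprinting (fig 2 analogs) ------------------------
  xa <- xa_ratio(counts, ann)
  xa_cmp <- compare_xa(xa, major, groups)
  write_tsv(xa_cmp, file.path(out_dir, "xa_by_cluster.tsv"))
  xdeg <- x_de_summary(de, ann, fdr = fdr)
  write_tsv(xdeg, file.path(out_dir, "x_degs.tsv"))
  spread <- if (nrow(xdeg) >= 2) x_position_spread(xdeg$gene, ann) else NULL
  if (!is.null(spread)) {
    write_tsv(as.data.frame(spread), file.path(out_dir, "x_spread.tsv"))
  }
  imp <- imprinted_panel_summary(
    norm, major, groups,
    panels = c(panels$imprint_noncanonical, panels$imprint_canonical),
    min_cells = min_cells)
  write_tsv(imp, file.path(out_dir, "imprinting.tsv"))

  ## -- interactions (fig 1I/1J analogs) -------------------------------
  lr <- config$lr_table
  sc_by_group <- list()
  for (g in names(dataset$counts)) {
    sel <- groups == g
    sc <- lr_scores(norm[, sel, drop = FALSE], major[sel], lr)
    sc_by_group[[g]] <- lr_permutation_test(
      sc, norm[, sel, drop = FALSE], major[sel],
      n_perm = n_perm, seed = config$seed + match(g, names(dataset$counts)))
  }
  net <- differential_network(sc_by_group$IVF, sc_by_group$SCNT)
  write_tsv(net, file.path(out_dir, "network_delta.tsv"))
  flow <- pathway_information_flow(sc_by_group)
  write_tsv(flow, file.path(out_dir, "pathway_flow.tsv"))

  ## -- headline summary -----------------------------------------------
  imm <- origin_comp[origin_comp$cluster == "immune", ]
  imm_called <- imm$n_maternal + imm$n_fetal
  sig <- function(tt) {
    any(comp$type == tt) && comp$q[comp$type == tt] < 0.05
  }
  fetal_cl <- intersect(fetal_types(), xa_cmp$cluster)
  summary <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_nuclei = stats::setNames(as.list(as.integer(table(groups))),
                               names(table(groups))),
    n_major_types = length(setdiff(unique(major), "ambiguous")),
    n_subtypes = length(setdiff(unique(subtypes), "ambiguous")),
    immune_fetal_pct = if (nrow(imm) && imm_called > 0) {
      100 * imm$n_fetal / imm_called
    } else NA,
    composition = list(
      immune_significant = sig("immune"),
      erythrocyte_significant = sig("erythrocyte"),
      trophoblast_significant = sig("trophoblast")),
    tgc = list(
      share_tgc = stats::setNames(as.list(tgc$shares$share_tgc),
                                  tgc$shares$group),
      s_tgc_higher_in_scnt =
        tgc$shares$share_stgc[tgc$shares$group == "SCNT"] >
        tgc$shares$share_stgc[tgc$shares$group == "IVF"],
      s_tgc_p = tgc$s_tgc_test$p),
    x_dosage = list(
      fetal_clusters_reduced = all(
        xa_cmp$median_ratio[xa_cmp$cluster %in% fetal_cl] < 1 &
          xa_cmp$p[xa_cmp$cluster %in% fetal_cl] < 0.05),
      decidua_unchanged =
        xa_cmp$p[xa_cmp$cluster == "decidual_stroma"] >= 0.05,
      n_x_degs = nrow(xdeg)),
    pathways_nonzero_flow = sum(
      rowSums(as.matrix(flow[grep("^flow_", names(flow))])) > 0))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
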