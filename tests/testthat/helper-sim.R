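# small, fast configurations shared across test files; datasets are
# memoized per session so several test files can reuse one simulation
small_config <- function(seed = 101, n_nuclei_per_group = 400,
                         n_genes = 500, n_planted_x_degs = 10, ...) {
  sim_config(n_nuclei_per_group = n_nuclei_per_group, n_genes = n_genes,
             n_planted_x_degs = n_planted_x_degs, seed = seed, ...)
}

.sim_cache <- new.env(parent = emptyenv())

cached_dataset <- function(config) {
  key <- paste0("ds_", config_hash_for_tests(config))
  if (!exists(key, envir = .sim_cache)) {
    assign(key, simulate_dataset(config), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

config_hash_for_tests <- function(config) {
  snPlacenta:::config_hash(config)
}

truth_map <- function(dataset) {
  tr <- dataset$truth
  rownames(tr) <- tr$barcode
  tr
}

# normalized matrix, labels and groups for a dataset, computed once
prep_pipeline <- function(dataset, margin = 0.1) {
  j <- join_groups(dataset)
  norm <- normalize_counts(j$counts)
  major <- annotate_major(norm, dataset$config$panels$major, margin = margin)
  list(counts = j$counts, norm = norm, groups = j$groups, major = major)
}
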