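# shared world cache so expensive simulations are built once per run
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, simulate_world(config), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

default_world <- function(seed = 1) {
  cached_world(paste0("default_", seed), world_config(seed = seed))
}

tiny_world <- function(seed = 42, ...) {
  simulate_world(world_config(n_orthogroups = 120, n_factors = 8,
                              chrom_per_subgenome = 1, n_contrasts = 5,
                              n_accessions = 6, seed = seed, ...))
}

null_world <- function(seed = 7) {
  cached_world(paste0("null_", seed), world_config(
    planted_logodds_effect = 0, mutant_mark_drop_log2 = 0,
    mutant_expr_gain_log2 = 0, infection_mark_drop_log2 = 0,
    divergence_coupling = 0, seed = seed
  ))
}

# RRPM-normalized mark densities split by condition
mark_rrpm <- function(world, conditions = c("wt", "mut")) {
  sam <- world$mark_samples
  sp <- stats::setNames(sam$spikein_total, sam$sample_id)
  rr <- rrpm_normalize(world$mark_counts, sp[colnames(world$mark_counts)])
  lapply(stats::setNames(conditions, conditions), function(cond) {
    rr[, sam$sample_id[sam$condition == cond], drop = FALSE]
  })
}
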