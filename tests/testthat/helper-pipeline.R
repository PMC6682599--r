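## Shared in-memory pipeline runs used by several test files.

## Simulate and quantify up to the crown-wide percent matrix.
quantified_simulation <- function(seed = 1, n_proteins = 100, ...) {
  sim <- simulate_dataset(simulation_config(n_proteins = n_proteins,
                                            seed = seed, ...))
  flt <- filter_identifications(sim$peptides)
  pct <- percent_scale(log_transform(volume_normalize(
    top3_abundance(flt$records, sim$grid), sim$grid)))
  list(sim = sim, filtered = flt, percent = pct)
}

planted_group_labels <- function(grid) unname(stage_groups(grid$stage))
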