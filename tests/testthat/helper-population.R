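# Shared simulated populations for the heavier scenario tests. Populations
# are pure functions of their seed, so caching them across test files only
# saves time, never changes results.

.pop_cache <- new.env(parent = emptyenv())

# Default-scale study population: 2,000 animals over 5 generations on the
# 5 x 2,000-marker high-density map, with the nested panel ladder emulating
# the 800K : 35K : 50K : 10K : 7K : 3K density ratios of the commercial
# chips (10,000 markers -> 667 / 467 / 133 / 92 / 40 after scaling).
study_population <- function(seed, trait = FALSE) {
  key <- paste0("study_", seed)
  if (is.null(.pop_cache[[key]])) {
    pop <- simulate_population(n_animals = 2000, n_generations = 5,
                               seed = seed)
    g <- true_genotypes(pop)
    freq <- colMeans(g) / 2
    panels <- build_panels(pop$map, pmin(freq, 1 - freq),
                           c(md = 667, ld35 = 467, ld10 = 133,
                             ld7k = 92, ld3k = 40))
    .pop_cache[[key]] <- list(pop = pop, freq = freq, panels = panels)
  }
  out <- .pop_cache[[key]]
  if (trait && is.null(out$pop$phenotypes)) {
    out$pop$phenotypes <- list(trait_h25 = simulate_phenotypes(
      out$pop, trait_spec("trait_h25", h2 = 0.25, n_qtl = 300),
      seed = stage_seed(seed, "trait1")
    ))
    .pop_cache[[key]] <- out
  }
  out
}

# Smaller single-chromosome population for tier experiments at full
# high-density width.
tier_population <- function(seed) {
  key <- paste0("tier_", seed)
  if (!is.null(.pop_cache[[key]])) return(.pop_cache[[key]])
  map <- uniform_genome_map(n_chrom = 1, markers_per_chrom = 2000)
  pop <- simulate_population(n_animals = 600, n_generations = 5, map = map,
                             n_sires = 10, seed = seed)
  g <- true_genotypes(pop)
  freq <- colMeans(g) / 2
  panels <- build_panels(map, pmin(freq, 1 - freq), c(md = 133, ld7 = 18))
  out <- list(pop = pop, freq = freq, panels = panels)
  .pop_cache[[key]] <- out
  out
}

# Tiny population for fast unit tests.
toy_population <- function(seed = 1, n_animals = 120, n_markers = 300,
                           n_chrom = 1) {
  map <- uniform_genome_map(n_chrom = n_chrom, markers_per_chrom = n_markers)
  simulate_population(n_animals = n_animals, n_generations = 3, map = map,
                      n_sires = 6, seed = seed)
}
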