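#' Chip-assay view of simulated genotypes
#'
#' Converts simulation truth into what a genotyping array would report for a
#' marker panel: allele counts with random missingness and random genotyping
#' errors. An error replaces the true genotype by one of the two other codes
#' with equal probability; missingness and errors are independent across
#' entries. Truth is never modified -- retrieve it with [true_genotypes()].
#'
#' @param pop a `sim_population`.
#' @param panel a [snp_panel()] (or character vector of marker ids).
#' @param missing_rate per-entry probability of a missing call, in `[0, 1]`.
#' @param error_rate per-entry probability of a genotyping error, in `[0, 1]`.
#' @param animal_ids animals to assay (default all).
#' @param seed integer seed.
#' @return Integer matrix animals x panel markers with entries 0/1/2 and
#'   `NA` for missing calls.
#' @export
apply_genotyping <- function(pop, panel, missing_rate = 0, error_rate = 0,
                             animal_ids = NULL, seed = 1) {
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate > 1) {
    stop("missing_rate and error_rate must lie in [0, 1]", call. = FALSE)
  }
  markers <- panel_markers(panel)
  g <- true_genotypes(pop, markers = markers, animal_ids = animal_ids)
  set.seed(as.integer(seed))
  n <- length(g)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    if (length(err)) {
      # shift by 1 or 2 modulo 3: lands on one of the other two codes
      g[err] <- (g[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
  }
  if (missing_rate > 0) {
    g[stats::runif(n) < missing_rate] <- NA_integer_
  }
  g
}

#' Simulate a complete study population
#'
#' One-call wrapper wiring map, pedigree, founder haplotypes, gene drop and
#' phenotypes together at the package's default scale: 2,000 animals over 5
#' generations and 5 chromosomes x 2,000 markers of high-density truth, with
#' ancestral-mosaic founders (pool of 20, one switch per cM).
#'
#' @param n_animals approximate total number of animals; the founder
#'   generation holds `n_animals / n_generations` of them.
#' @param n_generations pedigree depth.
#' @param map a [genome_map()]; default [uniform_genome_map()].
#' @param n_sires designated sires per generation.
#' @param maf_spectrum,n_ancestral,mosaic_switch_rate see
#'   [simulate_founder_haplotypes()].
#' @param traits list of [trait_spec()]s to attach as phenotypes.
#' @param seed master seed; internal stages derive their own seeds from it
#'   via [stage_seed()].
#' @return A `sim_population` with an added `phenotypes` element (one
#'   data.frame per trait, named by trait).
#' @export
simulate_population <- function(n_animals = 2000, n_generations = 5,
                                map = uniform_genome_map(),
                                n_sires = 25,
                                maf_spectrum = c(0.05, 0.5),
                                n_ancestral = 20, mosaic_switch_rate = 1,
                                traits = list(), seed = 1) {
  per_gen <- max(2L, round(n_animals / n_generations))
  ped <- simulate_pedigree(
    n_founders = per_gen, n_generations = n_generations, n_sires = n_sires,
    n_offspring = per_gen, seed = stage_seed(seed, "pedigree")
  )
  fh <- simulate_founder_haplotypes(
    map, maf_spectrum = maf_spectrum, n_ancestral = n_ancestral,
    mosaic_switch_rate = mosaic_switch_rate, n_founders = sum(is_founder(ped)),
    seed = stage_seed(seed, "founders")
  )
  pop <- gene_drop(ped, fh$founder_haplotypes, map,
                   seed = stage_seed(seed, "genedrop"))
  if (length(traits)) {
    phen <- lapply(seq_along(traits), function(k) {
      simulate_phenotypes(pop, traits[[k]],
                          seed = stage_seed(seed, paste0("trait", k)))
    })
    names(phen) <- vapply(traits, function(t) t$name, character(1))
    pop$phenotypes <- phen
  }
  pop
}
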