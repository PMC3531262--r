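#' Default run configuration
#'
#' A scaled study mimicking the shape of a dairy imputation benchmark: a
#' 2,000-animal pedigree on a 5 x 2,000-marker genome, a nested panel ladder
#' whose densities keep the 800K : 50K : 7K : 3K ratios at roughly 1/75
#' scale, a 50%-bulls reference scenario imputing the medium panel from the
#' low-density panels, and a weighted SNP-BLUP comparison of true, imputed
#' and low-density genotypes for a heritability-0.25 trait.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("imputeBench_run_")) {
  structure(list(
    seed = seed,
    outdir = outdir,
    simulation = list(n_animals = 2000, n_generations = 5, n_chrom = 5,
                      markers_per_chrom = 2000, n_sires = 25),
    panels = list(md = 667, ld7k = 92, ld3k = 40),
    hmm = list(ne = 100, eps = 0.005, max_ref_haplotypes = 100),
    scenarios = list(
      list(name = "half_ref_ld3k", target_panel = "md", typed_panel = "ld3k",
           reference = list(sex = "M", fraction = 0.5), n_test = 50)
    ),
    prediction = list(trait = list(name = "trait_h25", h2 = 0.25, n_qtl = 300),
                      typed_panel = "ld3k", target_panel = "md",
                      validation_fraction = 0.25)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [default_run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  if (is.null(base$seed)) stop("config must contain a seed", call. = FALSE)
  structure(base, class = "run_config")
}

#' Run a complete scenario pipeline
#'
#' Executes simulate -> panels -> split/mask -> impute (2- or 3-tier) ->
#' evaluate -> predict from one configuration, writing every intermediate
#' artifact (TSV/VCF/CSV/JSON) plus a manifest with per-stage seeds and
#' file checksums to the output directory. The whole run is a pure function
#' of the configuration, including its master seed.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_scenario <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("config must be a run_config", call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_events <- list()
  say <- function(stage, msg) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ",
                   msg)
    log_lines <<- c(log_lines, line)
    log_events[[length(log_events) + 1L]] <<- list(stage = stage, message = msg)
    message(line)
  }
  seeds <- list()
  sseed <- function(stage) {
    s <- stage_seed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }

  if (length(config$scenarios) == 0L) {
    warning("configuration has an empty scenario list; writing manifest only",
            call. = FALSE)
  }

  # --- simulate -------------------------------------------------------------
  say("simulate", "generating population")
  sim <- config$simulation
  map <- uniform_genome_map(n_chrom = sim$n_chrom,
                            markers_per_chrom = sim$markers_per_chrom)
  traits <- if (!is.null(config$prediction)) {
    list(do.call(trait_spec, config$prediction$trait))
  } else list()
  pop <- simulate_population(
    n_animals = sim$n_animals, n_generations = sim$n_generations, map = map,
    n_sires = sim$n_sires %||% 25, traits = traits, seed = sseed("simulate")
  )
  write_map(map, file.path(outdir, "map.tsv"))
  write_pedigree(pop$pedigree, file.path(outdir, "pedigree.tsv"))
  if (length(traits)) {
    write_phenotypes(pop$phenotypes[[1]], file.path(outdir, "phenotypes.tsv"))
  }

  # --- panels ---------------------------------------------------------------
  say("panels", "building density ladder")
  g_all <- true_genotypes(pop)
  freq <- colMeans(g_all) / 2
  maf <- pmin(freq, 1 - freq)
  panels <- build_panels(map, maf, unlist(config$panels))
  for (p in panels) write_panel(p, map, file.path(outdir, paste0("panel_",
                                                                p$name, ".tsv")))

  hmm_cfg <- do.call(hmm_config, config$hmm %||% list())
  results <- list()

  # --- scenarios ------------------------------------------------------------
  for (sc in config$scenarios) {
    say("scenario", sc$name)
    target <- panels[[sc$target_panel]]
    typed <- panels[[sc$typed_panel]]
    scn <- scenario(sc$name, reference = sc$reference, typed_panel = typed)
    split <- split_reference_test(pop, scn, seed = sseed(paste0("split_", sc$name)))
    test_ids <- split$test
    if (!is.null(sc$n_test) && sc$n_test < length(test_ids)) {
      set.seed(sseed(paste0("testsub_", sc$name)))
      test_ids <- sample(test_ids, sc$n_test)
    }
    truth_full <- true_genotypes(pop, markers = target$markers,
                                 animal_ids = test_ids)
    mk <- mask_genotypes(truth_full, typed)
    reference <- population_reference(pop, target, split$reference)

    if (!is.null(sc$mid_panel)) {
      say("impute", paste0(sc$name, ": 3-tier"))
      mid_ids <- setdiff(pop$pedigree$animal_id,
                         c(split$reference, test_ids))
      mid_geno <- true_genotypes(pop, markers = panels[[sc$mid_panel]]$markers,
                                 animal_ids = mid_ids)
      imp <- impute_tiered(mk$masked_geno, mid_geno, reference, hmm_cfg)
    } else {
      say("impute", paste0(sc$name, ": 2-tier"))
      imp <- impute_diploid(mk$masked_geno, reference, hmm_cfg)
    }

    say("evaluate", sc$name)
    rep_ <- error_report(mk$truth, imp$best_guess, map)
    utils::write.csv(rep_$per_animal,
                     file.path(outdir, paste0("errors_", sc$name, "_per_animal.csv")),
                     row.names = FALSE)
    utils::write.csv(rep_$per_chromosome,
                     file.path(outdir, paste0("errors_", sc$name, "_per_chrom.csv")),
                     row.names = FALSE)
    kin <- pedigree_kinship(pop$pedigree)
    per_animal <- stats::setNames(rep_$per_animal$allelic_error,
                                  rep_$per_animal$animal_id)
    strat <- stratify_error_by_kinship(per_animal, kin, split$reference)
    sire_cmp <- sire_in_reference_comparison(per_animal, pop$pedigree,
                                             split$reference)
    write_vcf(file.path(outdir, paste0("imputed_", sc$name, ".vcf.gz")),
              geno = imp$best_guess, map = map[match(target$markers,
                                                     map$marker_id), ],
              animal_ids = test_ids, ds = imp$dosage, gp = imp$posterior)
    summary <- list(
      scenario = sc$name,
      allelic_error = rep_$overall$allelic_error,
      genotypic_error = rep_$overall$genotypic_error,
      n_genotypes = rep_$overall$n_genotypes,
      kinship_strata = strat, sire_comparison = sire_cmp
    )
    jsonlite::write_json(summary,
                         file.path(outdir, paste0("summary_", sc$name, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results[[sc$name]] <- summary
  }

  # --- prediction -----------------------------------------------------------
  if (!is.null(config$prediction) && length(traits)) {
    say("predict", "weighted SNP-BLUP comparison")
    pr <- config$prediction
    target <- panels[[pr$target_panel]]
    typed <- panels[[pr$typed_panel]]
    phen <- pop$phenotypes[[1]]
    set.seed(sseed("predict_split"))
    n <- nrow(pop$pedigree)
    # validation: the youngest animals
    gen <- pop$pedigree$generation
    ord <- order(gen, decreasing = TRUE)
    n_val <- round((pr$validation_fraction %||% 0.25) * n)
    val_ids <- pop$pedigree$animal_id[ord[seq_len(n_val)]]
    train_ids <- setdiff(pop$pedigree$animal_id, val_ids)

    Xtr <- true_genotypes(pop, markers = target$markers, animal_ids = train_ids)
    ytr <- 2 * phen$dtd[match(train_ids, phen$animal_id)]
    rtr <- phen$reliability[match(train_ids, phen$animal_id)]
    cv <- cross_validate_lambda(ytr, Xtr, rtr,
                                grid = default_lambda_grid(ncol(Xtr),
                                                           traits[[1]]$h2),
                                seed = sseed("predict_cv"))
    fit <- solve_mme(ytr, Xtr, rtr, cv$lambda)
    dtd_val <- phen$dtd[match(val_ids, phen$animal_id)]

    Xval_true <- true_genotypes(pop, markers = target$markers,
                                animal_ids = val_ids)
    mk <- mask_genotypes(Xval_true, typed)
    imp <- impute_diploid(mk$masked_geno,
                          population_reference(pop, target, train_ids),
                          hmm_cfg)
    acc <- list(
      lambda = cv$lambda,
      true_genotypes = dgv_accuracy(compute_dgv(fit$mu, fit$g, Xval_true), dtd_val),
      imputed_best_guess = dgv_accuracy(compute_dgv(fit$mu, fit$g,
                                                    imp$best_guess), dtd_val),
      imputed_dosage = dgv_accuracy(compute_dgv(fit$mu, fit$g, imp$dosage),
                                    dtd_val)
    )
    # low-density-only fit on the typed subset alone
    Xtr_ld <- Xtr[, mk$typed_markers, drop = FALSE]
    cv_ld <- cross_validate_lambda(ytr, Xtr_ld, rtr,
                                   grid = default_lambda_grid(ncol(Xtr_ld),
                                                              traits[[1]]$h2),
                                   seed = sseed("predict_cv_ld"))
    fit_ld <- solve_mme(ytr, Xtr_ld, rtr, cv_ld$lambda)
    acc$low_density_subset <- dgv_accuracy(
      compute_dgv(fit_ld$mu, fit_ld$g,
                  Xval_true[, mk$typed_markers, drop = FALSE]), dtd_val
    )
    jsonlite::write_json(acc, file.path(outdir, "prediction_accuracy.json"),
                         auto_unbox = TRUE, digits = NA)
    results$prediction <- acc
  }

  # --- manifest -------------------------------------------------------------
  say("manifest", "writing checksums")
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  writeLines(log_lines, file.path(outdir, "run.log"))
  jsonlite::write_json(log_events, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE)
  files <- setdiff(list.files(outdir), "manifest.json")
  inventory <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("imputeBench")),
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = config$seed,
    stage_seeds = seeds,
    files = inventory,
    results = results
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
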