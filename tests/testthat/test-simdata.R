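test_that("simulate_pedigree produces ordered pedigrees with designated sires", {
  # base case: one generation means founders only
  ped1 <- simulate_pedigree(n_founders = 6, n_generations = 1, seed = 3)
  expect_true(all(ped1$sire_id == "0" & ped1$dam_id == "0"))

  # determinism
  a <- simulate_pedigree(10, 3, n_sires = 2, seed = 11)
  b <- simulate_pedigree(10, 3, n_sires = 2, seed = 11)
  expect_identical(a, b)

  # every non-founder's sire is among that generation's designated sires
  sires <- attr(a, "sires_by_generation")
  for (g in 2:3) {
    rows <- a[a$generation == g, ]
    expect_true(all(rows$sire_id %in% sires[[as.character(g)]]))
    expect_lte(length(unique(rows$sire_id)), 2)
  }
  # topological order and parent sexes hold by construction
  expect_silent(validate_pedigree(a))
  expect_true(all(a$birth_year == 2000 + a$generation - 1))

  expect_error(simulate_pedigree(1, 2), "n_founders")
  expect_error(simulate_pedigree(10, 0), "n_generations")
})

test_that("founder haplotypes are pool mosaics with the requested MAF", {
  map <- uniform_genome_map(n_chrom = 1, markers_per_chrom = 100)

  # no switching: every founder haplotype is an exact pool row
  fh0 <- simulate_founder_haplotypes(map, maf_spectrum = c(0.1, 0.5),
                                     n_ancestral = 8, mosaic_switch_rate = 0,
                                     n_founders = 20, seed = 5)
  for (h in seq_len(nrow(fh0$founder_haplotypes))) {
    matches <- apply(fh0$pool, 1, function(p) {
      all(p == fh0$founder_haplotypes[h, ])
    })
    expect_true(any(matches))
  }

  # fixed MAF 0.5: realized mean frequency near 0.5 at large n
  fh <- simulate_founder_haplotypes(map, maf_spectrum = 0.5, n_ancestral = 50,
                                    mosaic_switch_rate = 1,
                                    n_founders = 1000, seed = 7)
  realized <- colMeans(fh$founder_haplotypes)
  # founder frequencies are correlated within markers (pool copying), so
  # use the empirical between-marker spread for the Monte-Carlo bound
  expect_lt(abs(mean(realized) - 0.5),
            3 * stats::sd(realized) / sqrt(length(realized)))

  expect_error(simulate_founder_haplotypes(map, n_ancestral = 1,
                                           n_founders = 5), "n_ancestral")
})

test_that("founder LD decays with genetic distance", {
  # long chromosome so that well-separated pairs exist
  map <- uniform_genome_map(n_chrom = 1, markers_per_chrom = 200,
                            chrom_length_mb = 20)
  fh <- simulate_founder_haplotypes(map, maf_spectrum = c(0.2, 0.5),
                                    n_ancestral = 20, mosaic_switch_rate = 1,
                                    n_founders = 1000, seed = 13)
  H <- fh$founder_haplotypes
  keep <- apply(H, 2, stats::sd) > 0
  H <- H[, keep]
  cm <- map$cM[keep]
  r2 <- stats::cor(H)^2
  d <- abs(outer(cm, cm, "-"))
  near <- r2[d > 0 & d < 0.5]
  far <- r2[d > 10]
  # the ancestral-mosaic model caps mean r2 near 1/pool-size for close
  # pairs and leaves distant pairs essentially independent
  expect_gt(mean(near), 3 * mean(far))
  expect_lt(mean(far), 0.01)
})

test_that("gene_drop transmits legal recombinant gametes", {
  ped <- simulate_pedigree(20, 3, n_sires = 4, seed = 2)
  nf <- sum(ped$sire_id == "0")

  # zero-length chromosome: offspring inherit an intact parental haplotype
  map0 <- genome_map(rep("1", 50), paste0("m", 1:50), seq_len(50) * 1000,
                     rep(0, 50))
  fh <- simulate_founder_haplotypes(map0, c(0.2, 0.5), 10, 1, nf, seed = 3)
  pop0 <- gene_drop(ped, fh$founder_haplotypes, map0, seed = 4)
  expect_true(all(attr(pop0, "meioses")$n_crossovers == 0))
  for (i in which(ped$sire_id != "0")) {
    s <- match(ped$sire_id[i], ped$animal_id)
    child_pat <- pop0$haplotypes[2 * i - 1, ]
    expect_true(identical(child_pat, pop0$haplotypes[2 * s - 1, ]) ||
                  identical(child_pat, pop0$haplotypes[2 * s, ]))
  }

  # Haldane: mean crossover count equals map length in Morgans
  map1 <- uniform_genome_map(n_chrom = 1, markers_per_chrom = 100,
                             chrom_length_mb = 100)  # 100 cM = 1 Morgan
  big <- simulate_pedigree(400, 2, n_sires = 10, n_offspring = 2500, seed = 5)
  fh1 <- simulate_founder_haplotypes(map1, c(0.2, 0.5), 10, 1, 400, seed = 6)
  pop1 <- gene_drop(big, fh1$founder_haplotypes, map1, seed = 7)
  nxo <- attr(pop1, "meioses")$n_crossovers
  expect_gte(length(nxo), 5000)
  expect_lt(abs(mean(nxo) - 1), 3 * stats::sd(nxo) / sqrt(length(nxo)))

  expect_error(gene_drop(ped, NULL, map0), "founder_haplotypes")
})

test_that("gene-dropped genotypes are Mendelian-consistent for every trio", {
  pop <- toy_population(seed = 9)
  g <- true_genotypes(pop)
  ped <- pop$pedigree
  for (i in which(ped$sire_id != "0")) {
    go <- g[i, ]
    for (p in match(c(ped$sire_id[i], ped$dam_id[i]), ped$animal_id)) {
      gp <- g[p, ]
      expect_false(any((gp == 0 & go == 2) | (gp == 2 & go == 0)))
    }
  }
})

test_that("phenotypes calibrate reliability and heritability", {
  map <- uniform_genome_map(n_chrom = 2, markers_per_chrom = 500)
  pop <- simulate_population(n_animals = 2000, n_generations = 4, map = map,
                             seed = 21)

  # near-perfect reliabilities make DTD track TBV
  ph_hi <- simulate_phenotypes(pop, trait_spec("t", h2 = 0.4, n_qtl = 200),
                               reliability_range = c(0.989, 0.99), seed = 1)
  tbv <- attr(ph_hi, "tbv")
  expect_gt(stats::cor(tbv, ph_hi$dtd), 0.99)

  # regression of DTD on TBV has slope 1 (unbiased phenotype model)
  ph <- simulate_phenotypes(pop, trait_spec("t", h2 = 0.25, n_qtl = 200),
                            seed = 2)
  slope <- unname(stats::coef(stats::lm(ph$dtd ~ attr(ph, "tbv")))[2])
  se <- summary(stats::lm(ph$dtd ~ attr(ph, "tbv")))$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se)

  # heritability -> 0 limit: tiny TBV variance, DTD dominated by noise
  ph_lo <- simulate_phenotypes(pop, trait_spec("t", h2 = 0.001, n_qtl = 200),
                               reliability_range = c(0.01, 0.99), seed = 3)
  expect_lt(stats::var(attr(ph_lo, "tbv")), 0.0011)
  expect_lt(stats::var(attr(ph_lo, "tbv")) / stats::var(ph_lo$dtd), 0.15)

  # determinism and reliability bounds
  ph2 <- simulate_phenotypes(pop, trait_spec("t", h2 = 0.25, n_qtl = 200),
                             seed = 2)
  expect_identical(ph$dtd, ph2$dtd)
  expect_true(all(ph$reliability > 0 & ph$reliability < 1))
  expect_error(trait_spec("t", h2 = 1.2), "heritability")
})

test_that("apply_genotyping perturbs truth at the requested rates", {
  pop <- toy_population(seed = 4, n_animals = 100, n_markers = 100)
  panel <- snp_panel("all", pop$map$marker_id, pop$map)
  truth <- true_genotypes(pop)

  # identity when clean
  g0 <- apply_genotyping(pop, panel, 0, 0, seed = 1)
  expect_identical(unname(g0), unname(truth))

  # missingness within binomial bounds
  g_miss <- apply_genotyping(pop, panel, missing_rate = 0.5, seed = 2)
  n <- length(g_miss)
  expect_lt(abs(mean(is.na(g_miss)) - 0.5), 3 * sqrt(0.25 / n))

  # error_rate = 1: nothing equals truth
  g_err <- apply_genotyping(pop, panel, error_rate = 1, seed = 3)
  expect_true(all(g_err != truth))

  expect_error(apply_genotyping(pop, panel, missing_rate = 1.5), "rate")
})
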