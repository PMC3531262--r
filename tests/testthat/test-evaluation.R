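test_that("split_reference_test honours fractions, predicates and disjointness", {
  pop <- toy_population(seed = 61, n_animals = 200, n_markers = 50)
  n <- nrow(pop$pedigree)
  scn <- scenario("half", reference = list(fraction = 0.5))
  sp <- split_reference_test(pop, scn, seed = 1)
  expect_length(sp$reference, round(0.5 * n))
  expect_length(sp$test, n - round(0.5 * n))
  expect_length(intersect(sp$reference, sp$test), 0)

  ped <- pop$pedigree
  # birth-year split: old bulls reference, young bulls test
  scn2 <- scenario("years",
                   reference = list(sex = "M", born_before = 2002),
                   test = list(sex = "M", born_between = c(2002, 2003)))
  sp2 <- split_reference_test(pop, scn2, seed = 2)
  ref_years <- ped$birth_year[match(sp2$reference, ped$animal_id)]
  test_years <- ped$birth_year[match(sp2$test, ped$animal_id)]
  expect_true(all(ref_years < 2002))
  expect_true(all(test_years >= 2002 & test_years <= 2003))
  expect_true(all(ped$sex[match(c(sp2$reference, sp2$test),
                                ped$animal_id)] == "M"))

  # key ancestors: the animals with the most descendants
  scn3 <- scenario("key", reference = list(sex = "M", key_ancestors = 5))
  sp3 <- split_reference_test(pop, scn3, seed = 3)
  expect_length(sp3$reference, 5)

  expect_error(split_reference_test(pop,
                                    scenario("bad", reference = list(count = 10000)),
                                    seed = 1),
               "unsatisfiable")
})

test_that("mask_genotypes partitions markers into typed and truth stores", {
  pop <- toy_population(seed = 62, n_animals = 20, n_markers = 100)
  g <- true_genotypes(pop)
  panel <- snp_panel("typed", pop$map$marker_id[seq(1, 100, 5)], pop$map)

  mk <- mask_genotypes(g, panel)
  expect_setequal(c(mk$typed_markers, mk$masked_markers), colnames(g))
  expect_length(intersect(mk$typed_markers, mk$masked_markers), 0)
  expect_true(all(is.na(mk$masked_geno[, mk$masked_markers])))
  expect_identical(mk$masked_geno[, mk$typed_markers],
                   g[, mk$typed_markers])
  expect_identical(mk$truth[, mk$masked_markers], g[, mk$masked_markers])

  # full panel: nothing masked
  mk_full <- mask_genotypes(g, snp_panel("all", pop$map$marker_id, pop$map))
  expect_length(mk_full$masked_markers, 0)

  # every-10th rule masks exactly 10 of 100
  mk10 <- mask_genotypes(g, list(every_nth = 10))
  expect_length(mk10$masked_markers, 10)
  expect_length(mk10$typed_markers, 90)

  expect_error(mask_genotypes(g, snp_panel("none", character(0), pop$map)),
               "no markers")
})

test_that("error rates match hand counts and their algebraic bounds", {
  expect_equal(allelic_error_rate(c(0, 1, 2), c(0, 1, 2)), 0)
  # truth (0,1,2) vs (0,2,0): mismatches 0+1+2 of 6 alleles = 50%
  expect_equal(allelic_error_rate(c(0, 1, 2), c(0, 2, 0)), 50)
  expect_equal(genotypic_error_rate(c(0, 1, 2), c(0, 2, 0)), 200 / 3)
  # single het called hom: one of two alleles wrong
  expect_equal(allelic_error_rate(1, 0), 50)

  set.seed(63)
  for (case in 1:200) {
    m <- sample(2:10, 1)
    truth <- matrix(sample(0:2, 5 * m, TRUE), nrow = 5)
    imp <- matrix(sample(0:2, 5 * m, TRUE), nrow = 5)
    a <- allelic_error_rate(truth, imp)
    g <- genotypic_error_rate(truth, imp)
    expect_lte(a, g + 1e-12)
    expect_lte(g, 2 * a + 1e-12)
  }

  # permutation invariance
  truth <- matrix(sample(0:2, 60, TRUE), 6, 10,
                  dimnames = list(paste0("a", 1:6), paste0("m", 1:10)))
  imp <- matrix(sample(0:2, 60, TRUE), 6, 10, dimnames = dimnames(truth))
  pr <- sample(6); pc <- sample(10)
  expect_equal(allelic_error_rate(truth, imp),
               allelic_error_rate(truth[pr, pc], imp[pr, pc]))

  # missing truth excluded from denominators
  t2 <- c(0, NA, 2); i2 <- c(2, 1, 2)
  expect_equal(allelic_error_rate(t2, i2), 100 * 2 / 4)

  expect_error(allelic_error_rate(c(0, 1), c(0, 1, 2)), "shape")
})

test_that("error_report aggregates by chromosome, marker and animal", {
  pop <- toy_population(seed = 64, n_animals = 12, n_markers = 40, n_chrom = 2)
  truth <- true_genotypes(pop)
  imp <- truth
  imp[1, 1:4] <- (truth[1, 1:4] + 1) %% 3  # corrupt one animal's first markers
  rep_ <- error_report(truth, imp, pop$map)
  expect_equal(nrow(rep_$per_chromosome), 2)
  expect_equal(sum(rep_$per_marker$n_genotypes), rep_$overall$n_genotypes)
  expect_gt(rep_$per_animal$allelic_error[1], 0)
  expect_true(all(rep_$per_animal$allelic_error[-1] == 0))
})

test_that("pedigree kinship reproduces textbook identities", {
  ped <- data.frame(
    animal_id = c("f1", "f2", "o1", "o2", "g1"),
    sire_id = c("0", "0", "f1", "f1", "o1"),
    dam_id = c("0", "0", "f2", "f2", "f2"),
    sex = c("M", "F", "M", "F", "F"),
    birth_year = c(2000, 2000, 2001, 2001, 2002),
    stringsAsFactors = FALSE
  )
  f <- pedigree_kinship(ped)
  expect_equal(f["f1", "f2"], 0)        # unrelated founders
  expect_equal(f["f1", "f1"], 0.5)      # non-inbred self-kinship
  expect_equal(f["f1", "o1"], 0.25)     # parent-offspring
  expect_equal(f["o1", "o2"], 0.25)     # full sibs
  # g1 = o1 x f2 mating: inbred because f2 is o1's dam
  expect_equal(f["g1", "g1"], 0.5 * (1 + 0.25))
  expect_true(isSymmetric(f))
})

test_that("pedigree kinship matches gene-dropping IBD estimates", {
  set.seed(65)
  for (rep in 1:3) {
    ped <- simulate_pedigree(6, 3, n_sires = 2, n_offspring = 6,
                             seed = 100 + rep)
    f <- pedigree_kinship(ped)
    est <- gene_drop_kinship(ped, n_rep = 1e5)
    # binomial-ish bound on each pairwise estimate
    se <- sqrt(0.25 / 1e5)
    expect_lt(max(abs(f - est)), 5 * se)
  }
})

test_that("kinship stratification and sire comparison summarise test animals", {
  pop <- toy_population(seed = 66, n_animals = 150, n_markers = 60)
  ped <- pop$pedigree
  kin <- pedigree_kinship(ped)
  set.seed(1)
  ref_ids <- sample(ped$animal_id[ped$sex == "M"], 30)
  test_ids <- setdiff(ped$animal_id, ref_ids)
  err <- stats::setNames(stats::runif(length(test_ids), 0, 10), test_ids)

  strat <- stratify_error_by_kinship(err, kin, ref_ids)
  expect_identical(strat$bin, c("0-0.01", "0.01-0.1", "0.1-0.2", "0.2-0.4"))
  expect_equal(sum(strat$n), length(test_ids))
  expect_true(all(is.na(strat$mean_allelic_error[strat$n == 0])))

  # degenerate binning: one bin holding everyone reproduces the overall mean
  one <- stratify_error_by_kinship(err, kin, ref_ids, bins = c(0, 0.5))
  expect_equal(one$mean_allelic_error[1], mean(err))
  expect_equal(one$n[1], length(test_ids))

  cmp <- sire_in_reference_comparison(err, ped, ref_ids)
  expect_equal(sum(cmp$n), length(test_ids))  # groups partition the test set
  cmp_none <- sire_in_reference_comparison(err, ped, character(0))
  expect_equal(cmp_none$n[cmp_none$sire_in_reference], 0)
  expect_true(is.na(cmp_none$mean_allelic_error[cmp_none$sire_in_reference]))
})

test_that("test animals with sire in the reference are imputed more accurately", {
  cfg <- hmm_config(max_ref_haplotypes = 100)
  with_means <- without_means <- numeric(5)
  for (seed in 1:5) {
    tp <- tier_population(seed)
    ped <- tp$pop$pedigree
    set.seed(700 + seed)
    ref_ids <- sample(ped$animal_id, 60)
    test_ids <- sample(setdiff(ped$animal_id, ref_ids), 60)
    truth <- true_genotypes(tp$pop, markers = tp$panels$md$markers,
                            animal_ids = test_ids)
    mk <- mask_genotypes(truth, tp$panels$ld7)
    imp <- impute_diploid(mk$masked_geno,
                          population_reference(tp$pop, tp$panels$md, ref_ids),
                          cfg)
    rep_ <- error_report(mk$truth, imp$best_guess)
    per_animal <- stats::setNames(rep_$per_animal$allelic_error,
                                  rep_$per_animal$animal_id)
    cmp <- sire_in_reference_comparison(per_animal, ped, ref_ids)
    with_means[seed] <- cmp$mean_allelic_error[cmp$sire_in_reference]
    without_means[seed] <- cmp$mean_allelic_error[!cmp$sire_in_reference]
  }
  expect_lt(mean(with_means, na.rm = TRUE), mean(without_means, na.rm = TRUE))
})
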