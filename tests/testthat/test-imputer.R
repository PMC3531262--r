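test_that("transition_rates follows the Li-Stephens closed form", {
  # zero distance collapses to the floor; huge distance saturates toward 1
  expect_equal(transition_rates(0, K = 10), 1e-8)
  expect_gt(transition_rates(100, K = 10), 1 - 1e-12)
  # Ne = 100, K = 100, c = 0.01 M -> 1 - exp(-0.04)
  expect_equal(transition_rates(0.01, K = 100, ne = 100),
               1 - exp(-0.04), tolerance = 1e-12)
  expect_error(transition_rates(-0.1, K = 10), "non-negative")
  expect_error(transition_rates(0.1, K = 1), "K")
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(101)
  worst <- 0
  for (case in 1:200) {
    K <- sample(2:3, 1)
    L <- sample(2:4, 1)
    H <- matrix(stats::rbinom(K * L, 1, 0.5), K, L)
    obs <- sample(c(-1L, 0L, 1L, 2L), L, replace = TRUE)
    rho <- stats::runif(L - 1, 1e-4, 0.5)
    eps <- stats::runif(1, 1e-4, 0.1)
    fb <- imputeBench:::diploid_fb_cpp(H, obs, rho, eps)
    oracle <- brute_force_posterior(H, obs, rho, eps)
    worst <- max(worst, max(abs(fb$posterior - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("a perfect template copy is imputed without error", {
  set.seed(11)
  L <- 60
  map <- uniform_genome_map(n_chrom = 1, markers_per_chrom = L)
  H <- matrix(stats::rbinom(8 * L, 1, 0.5), 8, L)
  ref <- reference_panel(H, map[, c("chrom", "marker_id", "cM")])
  truth <- H[3, ] + H[7, ]
  test <- truth
  masked <- seq(3, L, by = 3)
  test[masked] <- NA
  test <- matrix(test, 1, dimnames = list("t1", map$marker_id))
  imp <- impute_diploid(test, ref, hmm_config(eps = 0.001))
  expect_identical(unname(imp$best_guess[1, masked]),
                   unname(truth[masked]))
  # posterior triples sum to 1 everywhere
  expect_lt(max(abs(apply(imp$posterior, 1:2, sum) - 1)), 1e-8)
  expect_error(impute_diploid(matrix(1L, 1, 1, dimnames = list(NULL, "zz")),
                              ref), "not present")
})

test_that("best_guess and dosage implement their formulas and tie rules", {
  expect_identical(best_guess(c(0.1, 0.2, 0.7)), 2L)
  expect_identical(best_guess(c(0.5, 0.5, 0.0)), 0L)  # tie -> lower B count
  expect_identical(best_guess(c(0, 1, 0)), 1L)
  expect_equal(dosage(c(0.4, 0.2, 0.4)), 1.0)
  expect_equal(dosage(c(0, 0, 1)), 2.0)
  expect_equal(dosage(c(1, 1, 1) / 3), 1.0)
  expect_error(best_guess(c(0.5, 0.2, 0.1)), "sum to 1")
  expect_error(dosage(c(0.7, 0.4, -0.1)), "non-negative")
  # matrix form
  expect_identical(best_guess(rbind(c(1, 0, 0), c(0, 0, 1))), c(0L, 2L))
})

test_that("imputation result satisfies its internal contracts", {
  tp <- tier_population(1)
  set.seed(42)
  ids <- tp$pop$pedigree$animal_id
  ref_ids <- sample(ids, 80)
  test_ids <- sample(setdiff(ids, ref_ids), 8)
  truth <- true_genotypes(tp$pop, markers = tp$panels$md$markers,
                          animal_ids = test_ids)
  mk <- mask_genotypes(truth, tp$panels$ld7)
  ref <- population_reference(tp$pop, tp$panels$md, ref_ids)
  imp <- impute_diploid(mk$masked_geno, ref, hmm_config(max_ref_haplotypes = 60))
  # best_guess is the argmax of the posterior, dosage its expectation
  expect_identical(imp$best_guess,
                   imputeBench:::posterior_argmax(imp$posterior))
  expect_equal(imp$dosage,
               imp$posterior[, , 2] + 2 * imp$posterior[, , 3])
  expect_true(all(imp$dosage >= 0 & imp$dosage <= 2))
  expect_lt(max(abs(apply(imp$posterior, 1:2, sum) - 1)), 1e-8)
  # deterministic: same inputs give identical output
  imp2 <- impute_diploid(mk$masked_geno, ref, hmm_config(max_ref_haplotypes = 60))
  expect_identical(imp$posterior, imp2$posterior)
})

test_that("tiered imputation degenerates to diploid imputation without a middle tier", {
  tp <- tier_population(2)
  set.seed(7)
  ids <- tp$pop$pedigree$animal_id
  top_ids <- sample(ids, 40)
  test_ids <- sample(setdiff(ids, top_ids), 5)
  truth <- true_genotypes(tp$pop, animal_ids = test_ids)
  mk <- mask_genotypes(truth, tp$panels$ld7)
  top <- population_reference(tp$pop, tp$pop$map$marker_id, top_ids)
  cfg <- hmm_config(max_ref_haplotypes = 60)
  direct <- impute_diploid(mk$masked_geno, top, cfg)
  tiered <- impute_tiered(mk$masked_geno, NULL, top, cfg)
  expect_identical(direct$posterior, tiered$posterior)
  tiered0 <- impute_tiered(mk$masked_geno,
                           mk$masked_geno[0, , drop = FALSE], top, cfg)
  expect_identical(direct$posterior, tiered0$posterior)

  # nesting violation: middle tier typed at markers missing from the top
  bad_mid <- matrix(1L, 2, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  expect_error(impute_tiered(mk$masked_geno, bad_mid, top, cfg), "nesting")
})

test_that("sampling baseline draws Hardy-Weinberg genotypes at reference frequencies", {
  masked <- matrix(TRUE, 100, 100)
  # degenerate frequencies are copied exactly
  g0 <- sampling_baseline(masked, rep(0, 100), seed = 1)
  expect_true(all(g0 == 0))
  g2 <- sampling_baseline(masked, rep(1, 100), seed = 1)
  expect_true(all(g2 == 2))
  # p = 0.5: mean allelic error vs an independent HWE truth is 37.5%
  set.seed(2)
  truth <- matrix(stats::rbinom(10000, 2, 0.5), 100, 100)
  bl <- sampling_baseline(masked, rep(0.5, 100), seed = 3)
  err <- allelic_error_rate(truth, bl)
  # per-genotype allele mismatch has mean 0.75, variance 0.6875
  se <- 100 * sqrt(0.6875 / 10000) / 2
  expect_lt(abs(err - 37.5), 3 * se)
  expect_error(sampling_baseline(masked, rep(1.5, 100)), "frequencies")
})

test_that("imputation error falls with typed density and beats the baseline", {
  tp <- tier_population(3)
  set.seed(9)
  ids <- tp$pop$pedigree$animal_id
  bulls <- ids[tp$pop$pedigree$sex == "M"]
  ref_ids <- sample(bulls, 200)
  test_ids <- sample(setdiff(ids, ref_ids), 25)
  truth <- true_genotypes(tp$pop, markers = tp$panels$md$markers,
                          animal_ids = test_ids)
  ref <- population_reference(tp$pop, tp$panels$md, ref_ids)
  cfg <- hmm_config(max_ref_haplotypes = 100)
  errs <- vapply(c("ld7", "md"), function(tpanel) {
    if (tpanel == "md") return(0)  # fully typed: nothing to impute
    mk <- mask_genotypes(truth, tp$panels[[tpanel]])
    imp <- impute_diploid(mk$masked_geno, ref, cfg)
    allelic_error_rate(mk$truth, imp$best_guess)
  }, numeric(1))
  mk <- mask_genotypes(truth, tp$panels$ld7)
  bl <- sampling_baseline(is.na(mk$masked_geno),
                          tp$freq[tp$panels$md$markers], seed = 4)
  expect_lt(errs["ld7"], allelic_error_rate(mk$truth, bl))
  expect_gt(allelic_error_rate(mk$truth, bl), 15)
})
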