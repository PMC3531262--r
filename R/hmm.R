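#' Haplotype-copying HMM configuration
#'
#' @param ne effective population size scaling the per-interval switch rate.
#'   Default 100, the value typical of Holstein-Friesian dairy cattle.
#' @param eps per-allele emission error probability, in `[0, 0.5)`; the
#'   genotyping-error channel between template alleles and an observed
#'   genotype. Default 0.005, the scale of chip genotyping error.
#' @param rho_floor minimum per-interval switch probability (keeps zero-cM
#'   intervals connected). Default 1e-8.
#' @param max_ref_haplotypes cap K on the number of reference haplotypes
#'   used per test animal; beyond the cap the haplotypes closest by
#'   allele-sharing at the animal's typed loci are retained. Controls the
#'   O(L*K^2) cost. Default 400.
#' @return A list of class `hmm_config`.
#' @export
hmm_config <- function(ne = 100, eps = 0.005, rho_floor = 1e-8,
                       max_ref_haplotypes = 400) {
  if (ne <= 0) stop("ne must be positive", call. = FALSE)
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)", call. = FALSE)
  if (rho_floor < 0 || rho_floor >= 1) stop("rho_floor must lie in [0, 1)",
                                            call. = FALSE)
  if (max_ref_haplotypes < 2) stop("max_ref_haplotypes must be >= 2",
                                   call. = FALSE)
  structure(list(ne = ne, eps = eps, rho_floor = rho_floor,
                 max_ref_haplotypes = as.integer(max_ref_haplotypes)),
            class = "hmm_config")
}

#' Per-interval haplotype switch probabilities
#'
#' The Li-Stephens convention: over a genetic distance of `c` Morgans with
#' `K` reference haplotypes and effective population size `Ne`, the copying
#' process switches templates with probability `1 - exp(-4 * Ne * c / K)`,
#' floored at a small positive value so adjacent identical positions remain
#' connected.
#'
#' @param c_morgans non-negative inter-marker distances in Morgans.
#' @param K number of reference haplotypes (>= 2).
#' @param ne effective population size.
#' @param floor minimum switch probability.
#' @return Numeric vector of switch probabilities in `[floor, 1)`.
#' @export
transition_rates <- function(c_morgans, K, ne = 100, floor = 1e-8) {
  if (any(c_morgans < 0)) stop("genetic distances must be non-negative",
                               call. = FALSE)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  pmax(floor, 1 - exp(-4 * ne * c_morgans / K))
}

#' Phased reference panel
#'
#' @param haplotypes K x M matrix of 0/1 alleles, one row per phased
#'   haplotype, columns in map order; K >= 2.
#' @param map_info data.frame with columns `chrom`, `marker_id`, `cM` (map
#'   rows for the panel's markers, in order).
#' @return A list of class `reference_panel`.
#' @export
reference_panel <- function(haplotypes, map_info) {
  if (nrow(haplotypes) < 2L) {
    stop("a reference panel needs at least 2 haplotypes", call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(map_info)) {
    stop("haplotype columns must match map_info rows", call. = FALSE)
  }
  if (any(!(haplotypes %in% 0:1))) {
    stop("reference haplotypes must be 0/1", call. = FALSE)
  }
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- map_info$marker_id
  structure(list(haplotypes = haplotypes, map_info = map_info),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "markers\n")
  invisible(x)
}

#' Reference panel from a simulated population
#'
#' Extracts the (true-phase) haplotypes of the given animals at the markers
#' of a panel.
#'
#' @param pop a `sim_population`.
#' @param panel a [snp_panel()] or marker-id vector.
#' @param animal_ids reference animals.
#' @return A [reference_panel()].
#' @export
population_reference <- function(pop, panel, animal_ids) {
  markers <- panel_markers(panel)
  j <- match(markers, pop$map$marker_id)
  if (anyNA(j)) stop("panel markers not on the population map", call. = FALSE)
  j <- sort(j)
  H <- pop$haplotypes[haplotype_rows(pop, animal_ids), j, drop = FALSE]
  reference_panel(H, pop$map[j, c("chrom", "marker_id", "cM")])
}

# rank reference haplotypes by allele-sharing with an animal's typed
# genotypes; a haplotype allele is consistent with genotype g unless it is
# excluded by a homozygote (g=0 excludes allele 1, g=2 excludes allele 0)
select_ref_haplotypes <- function(H, geno, cap) {
  K <- nrow(H)
  if (K <= cap) return(seq_len(K))
  typed <- which(!is.na(geno))
  if (length(typed) == 0L) return(seq_len(cap))
  g <- geno[typed]
  Ht <- H[, typed, drop = FALSE]
  score <- Ht %*% (g >= 1) + (1L - Ht) %*% (g <= 1)
  order(score, decreasing = TRUE)[seq_len(cap)]
}

#' Impute genotypes with the diploid haplotype-copying HMM
#'
#' For each test animal the hidden state is an ordered pair of reference
#' haplotypes; forward-backward over the whole chromosome in a single pass
#' yields a genotype posterior triple at every marker. Typed loci constrain
#' the copying path through the allele-error emission channel; untyped or
#' missing loci emit uniformly and receive posteriors by marginalising the
#' state distribution through the same channel.
#'
#' @param test_geno n x m matrix of 0/1/2/`NA` genotypes; columns must be
#'   named with marker ids present in the reference panel. `NA` marks
#'   untyped or missing entries to be imputed.
#' @param reference a [reference_panel()].
#' @param config an [hmm_config()].
#' @return A list of class `imputation_result`: `posterior` (n x M x 3 array
#'   over all reference markers, slices `p_AA`, `p_AB`, `p_BB`),
#'   `best_guess` (n x M, 0/1/2), `dosage` (n x M, `p_AB + 2 p_BB`),
#'   `phased` (2n x M max-posterior template alleles, rows 2i-1, 2i per
#'   animal), `masked` (n x M logical: entries that were imputed rather than
#'   observed), `markers`.
#' @export
impute_diploid <- function(test_geno, reference, config = hmm_config()) {
  if (!inherits(reference, "reference_panel")) {
    stop("reference must be a reference_panel", call. = FALSE)
  }
  if (is.null(dim(test_geno))) test_geno <- matrix(test_geno, nrow = 1)
  ref_markers <- reference$map_info$marker_id
  cn <- colnames(test_geno)
  if (is.null(cn)) {
    if (ncol(test_geno) != length(ref_markers)) {
      stop("unnamed test genotypes must cover all reference markers",
           call. = FALSE)
    }
    cn <- ref_markers
    colnames(test_geno) <- cn
  }
  if (any(!(cn %in% ref_markers))) {
    stop("test locus not present in the reference panel: ",
         paste(utils::head(setdiff(cn, ref_markers), 3), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(test_geno)
  M <- length(ref_markers)
  full <- matrix(NA_integer_, n, M, dimnames = list(rownames(test_geno),
                                                    ref_markers))
  full[, cn] <- as.integer(test_geno)
  masked <- is.na(full)

  K_all <- nrow(reference$haplotypes)
  idx_by_chrom <- split(seq_len(M),
                        factor(reference$map_info$chrom,
                               levels = unique(reference$map_info$chrom)))
  posterior <- array(NA_real_, dim = c(n, M, 3),
                     dimnames = list(rownames(test_geno), ref_markers,
                                     c("p_AA", "p_AB", "p_BB")))
  phased <- matrix(NA_integer_, 2L * n, M)
  colnames(phased) <- ref_markers

  for (cols in idx_by_chrom) {
    cm <- reference$map_info$cM[cols]
    for (i in seq_len(n)) {
      sel <- select_ref_haplotypes(reference$haplotypes[, cols, drop = FALSE],
                                   full[i, cols], config$max_ref_haplotypes)
      K <- length(sel)
      rho <- if (length(cols) > 1L) {
        transition_rates(diff(cm) / 100, K, config$ne, config$rho_floor)
      } else numeric(0)
      obs <- full[i, cols]
      obs[is.na(obs)] <- -1L
      fb <- diploid_fb_cpp(reference$haplotypes[sel, cols, drop = FALSE],
                           as.integer(obs), rho, config$eps)
      posterior[i, cols, ] <- t(fb$posterior)
      phased[2L * i - 1L, cols] <- fb$phased[1, ]
      phased[2L * i, cols] <- fb$phased[2, ]
    }
  }

  bg <- posterior_argmax(posterior)
  ds <- posterior[, , 2, drop = FALSE][, , 1] + 2 * posterior[, , 3, drop = FALSE][, , 1]
  ds <- matrix(ds, n, M, dimnames = list(rownames(test_geno), ref_markers))
  structure(list(posterior = posterior, best_guess = bg, dosage = ds,
                 phased = phased, masked = masked, markers = ref_markers),
            class = "imputation_result")
}

# argmax over the 3 genotype slices, ties toward the lower B-allele count
posterior_argmax <- function(posterior) {
  p0 <- posterior[, , 1, drop = FALSE][, , 1]
  p1 <- posterior[, , 2, drop = FALSE][, , 1]
  p2 <- posterior[, , 3, drop = FALSE][, , 1]
  g <- ifelse(p0 >= p1 & p0 >= p2, 0L, ifelse(p1 >= p2, 1L, 2L))
  matrix(as.integer(g), dim(posterior)[1], dim(posterior)[2],
         dimnames = dimnames(posterior)[1:2])
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result:", nrow(x$best_guess), "animals x",
      ncol(x$best_guess), "markers (", sum(x$masked), "imputed )\n")
  invisible(x)
}

check_posterior_triple <- function(p, tol = 1e-6) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3L) stop("a genotype posterior has three components",
                          call. = FALSE)
  if (any(p < -tol)) stop("posterior probabilities must be non-negative",
                          call. = FALSE)
  if (any(abs(rowSums(p) - 1) > tol)) {
    stop("posterior triples must sum to 1", call. = FALSE)
  }
  p
}

#' Most likely genotype from a posterior triple
#'
#' Argmax over `(p_AA, p_AB, p_BB)`; ties are broken toward the lower
#' B-allele count so the result is deterministic.
#'
#' @param posterior length-3 vector or n x 3 matrix of genotype posteriors.
#' @return Integer genotype(s) 0/1/2.
#' @export
best_guess <- function(posterior) {
  p <- check_posterior_triple(posterior)
  g <- ifelse(p[, 1] >= p[, 2] & p[, 1] >= p[, 3], 0L,
              ifelse(p[, 2] >= p[, 3], 1L, 2L))
  as.integer(g)
}

#' B-allele dosage from a posterior triple
#'
#' Expected B-allele count `p_AB + 2 * p_BB`, the uncertainty-aware genotype
#' appropriate for additive models.
#'
#' @param posterior length-3 vector or n x 3 matrix of genotype posteriors.
#' @return Numeric dosage(s) in `[0, 2]`.
#' @export
dosage <- function(posterior) {
  p <- check_posterior_triple(posterior)
  as.numeric(p[, 2] + 2 * p[, 3])
}

#' Tiered imputation through an intermediate reference panel
#'
#' Multi-tier imputation for the situation where a large cohort genotyped at
#' medium density sits between a small high-density reference and
#' low-density test animals. Stage 1 imputes the medium-density cohort up to
#' the high-density panel against the top reference; stage 2 appends their
#' max-posterior template haplotypes to the reference as pseudo-haplotypes;
#' stage 3 imputes the test animals against the enlarged reference. With an
#' empty middle cohort the result is identical to [impute_diploid()] against
#' the top reference alone.
#'
#' @param test_geno low-density test genotypes (columns named by typed
#'   markers, all of which must be typed in `mid_geno`'s marker set).
#' @param mid_geno medium-density genotypes of the middle cohort (columns
#'   named; marker set nested inside the top reference), or `NULL`/0-row for
#'   no middle tier.
#' @param top_reference a [reference_panel()] at the full target density.
#' @param config an [hmm_config()].
#' @return An `imputation_result` for the test animals (see
#'   [impute_diploid()]).
#' @export
impute_tiered <- function(test_geno, mid_geno, top_reference,
                          config = hmm_config()) {
  if (is.null(mid_geno) || nrow(mid_geno) == 0L) {
    return(impute_diploid(test_geno, top_reference, config))
  }
  ref_markers <- top_reference$map_info$marker_id
  mid_markers <- colnames(mid_geno)
  if (is.null(mid_markers) || any(!(mid_markers %in% ref_markers))) {
    stop("tier nesting violated: middle-tier markers must be a subset of ",
         "the top reference markers", call. = FALSE)
  }
  # typed test markers: columns carrying at least one observed genotype
  typed_cols <- colnames(test_geno)[colSums(!is.na(test_geno)) > 0]
  mid_typed <- mid_markers[colSums(!is.na(mid_geno)) > 0]
  if (!is.null(typed_cols) && any(!(typed_cols %in% mid_typed))) {
    stop("tier nesting violated: typed test markers must be a subset of ",
         "the middle tier's typed markers", call. = FALSE)
  }
  stage1 <- impute_diploid(mid_geno, top_reference, config)
  enlarged <- reference_panel(
    rbind(top_reference$haplotypes, stage1$phased),
    top_reference$map_info
  )
  impute_diploid(test_geno, enlarged, config)
}

#' Allele-frequency sampling baseline
#'
#' The no-LD control: every masked genotype is drawn as two independent
#' alleles at the reference B-allele frequency (a Hardy-Weinberg draw).
#' Haplotype-based imputation must beat this baseline by a wide margin for
#' LD information to be doing any work.
#'
#' @param masked logical matrix (n x m) flagging entries to impute.
#' @param ref_freq B-allele frequency per marker (length m), in `[0, 1]`.
#' @param seed integer seed.
#' @return Integer matrix like `masked` with sampled genotypes at masked
#'   entries and `NA` elsewhere.
#' @export
sampling_baseline <- function(masked, ref_freq, seed = 1) {
  if (any(ref_freq < 0 | ref_freq > 1)) {
    stop("reference frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (length(ref_freq) != ncol(masked)) {
    stop("ref_freq must have one entry per marker column", call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- matrix(NA_integer_, nrow(masked), ncol(masked),
                dimnames = dimnames(masked))
  idx <- which(masked)
  if (length(idx)) {
    pcol <- ref_freq[(idx - 1L) %/% nrow(masked) + 1L]
    out[idx] <- stats::rbinom(length(idx), 2L, pcol)
  }
  out
}
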