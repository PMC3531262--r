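#' Reference/test scenario definition
#'
#' A scenario bundles the recipe of an imputation experiment: how reference
#' animals are selected, how test animals are selected, which panel the test
#' animals are typed on, and which markers are masked for scoring.
#'
#' Selection rules are lists with any of: `sex` (`"M"`/`"F"`), `born_before`
#' (year, exclusive), `born_between` (`c(from, to)`, inclusive), `fraction`
#' or `count` (random subset of the qualifying pool), `key_ancestors`
#' (count: the qualifying animals with the most pedigree descendants). The
#' test rule defaults to the complement of the reference set, optionally
#' filtered by its own predicates.
#'
#' @param name scenario label.
#' @param reference reference-selection rule.
#' @param test test-selection rule (`NULL` = everything else).
#' @param typed_panel the [snp_panel()] (or name) test animals are typed on.
#' @param mask `"panel_complement"` (default: all reference-panel markers
#'   not on the typed panel) or `list(every_nth = k)`.
#' @return A list of class `scenario`.
#' @export
scenario <- function(name, reference, test = NULL, typed_panel = NULL,
                     mask = "panel_complement") {
  structure(list(name = name, reference = reference, test = test,
                 typed_panel = typed_panel, mask = mask),
            class = "scenario")
}

apply_rule <- function(ped, rule, pool = ped$animal_id) {
  keep <- ped$animal_id %in% pool
  if (!is.null(rule$sex)) keep <- keep & ped$sex %in% rule$sex
  if (!is.null(rule$born_before)) keep <- keep & ped$birth_year < rule$born_before
  if (!is.null(rule$born_between)) {
    keep <- keep & ped$birth_year >= rule$born_between[1] &
      ped$birth_year <= rule$born_between[2]
  }
  cand <- ped$animal_id[keep]
  if (!is.null(rule$key_ancestors)) {
    k <- rule$key_ancestors
    if (length(cand) < k) {
      stop("selection rule unsatisfiable: only ", length(cand),
           " candidates for ", k, " key ancestors", call. = FALSE)
    }
    ndesc <- count_descendants(ped)
    cand <- cand[order(ndesc[cand], decreasing = TRUE)][seq_len(k)]
    return(cand)
  }
  want <- if (!is.null(rule$count)) {
    rule$count
  } else if (!is.null(rule$fraction)) {
    round(rule$fraction * length(cand))
  } else {
    length(cand)
  }
  if (want > length(cand)) {
    stop("selection rule unsatisfiable: wanted ", want, " of ",
         length(cand), " candidates", call. = FALSE)
  }
  if (want < length(cand)) cand <- sample(cand, want)
  cand
}

count_descendants <- function(ped) {
  n <- nrow(ped)
  ids <- ped$animal_id
  si <- match(ped$sire_id, ids)
  di <- match(ped$dam_id, ids)
  # descendant sets via reverse topological sweep over logical matrix would
  # be O(n^2) memory at scale; count transitively with repeated propagation
  ndesc <- integer(n)
  anc <- vector("list", n)
  for (i in seq_len(n)) {
    a <- integer(0)
    if (!is.na(si[i])) a <- c(si[i], anc[[si[i]]])
    if (!is.na(di[i])) a <- c(a, di[i], anc[[di[i]]])
    a <- unique(a)
    anc[[i]] <- a
    ndesc[a] <- ndesc[a] + 1L
  }
  stats::setNames(ndesc, ids)
}

#' Split a population into reference and test sets
#'
#' @param pop a `sim_population` (or a bare pedigree data.frame).
#' @param scn a [scenario()].
#' @param seed integer seed for the random parts of the selection rules.
#' @return A list with `reference` and `test` character id vectors
#'   (disjoint).
#' @export
split_reference_test <- function(pop, scn, seed = 1) {
  ped <- if (inherits(pop, "sim_population")) pop$pedigree else pop
  set.seed(as.integer(seed))
  ref <- apply_rule(ped, scn$reference)
  rest <- setdiff(ped$animal_id, ref)
  test <- if (is.null(scn$test)) rest else apply_rule(ped, scn$test, pool = rest)
  if (length(intersect(ref, test))) {
    stop("reference and test sets overlap", call. = FALSE)
  }
  list(reference = ref, test = test)
}

#' Mask genotypes outside a typed panel
#'
#' Produces the low-density view of test animals: typed loci are retained,
#' every other genotype is recorded in a truth store and set missing.
#'
#' @param geno_full animals x markers matrix over the full (reference) panel;
#'   column names are marker ids.
#' @param typed a [snp_panel()], marker-id vector, or `list(every_nth = k)`
#'   to *mask* every k-th marker (keeping the rest typed).
#' @return A list: `masked_geno` (typed loci kept, others `NA`), `truth`
#'   (complementary matrix: masked loci kept, others `NA`), `masked_markers`.
#' @export
mask_genotypes <- function(geno_full, typed) {
  all_markers <- colnames(geno_full)
  if (is.null(all_markers)) stop("geno_full must have marker-id colnames",
                                 call. = FALSE)
  if (is.list(typed) && !inherits(typed, "snp_panel")) {
    k <- typed$every_nth
    if (is.null(k) || k < 2) stop("every_nth must be >= 2", call. = FALSE)
    masked_idx <- seq(k, length(all_markers), by = k)
    typed_markers <- all_markers[-masked_idx]
  } else {
    typed_markers <- intersect(all_markers, panel_markers(typed))
    if (length(typed_markers) == 0L) {
      stop("typed panel shares no markers with the genotype matrix",
           call. = FALSE)
    }
  }
  masked_markers <- setdiff(all_markers, typed_markers)
  masked_geno <- geno_full
  masked_geno[, masked_markers] <- NA_integer_
  truth <- geno_full
  truth[, typed_markers] <- NA_integer_
  list(masked_geno = masked_geno, truth = truth,
       masked_markers = masked_markers, typed_markers = typed_markers)
}

check_same_shape <- function(truth, imputed) {
  if (!identical(dim(truth), dim(imputed)) ||
      length(truth) != length(imputed)) {
    stop("truth and imputed matrices must have identical shape", call. = FALSE)
  }
}

#' Allelic error rate of imputation
#'
#' Per genotype, the number of incorrectly predicted alleles is the absolute
#' difference in B-allele count (opposite homozygotes count 2, a
#' homozygote/heterozygote mismatch counts 1). The rate is the total over
#' all scored genotypes divided by twice their number, as a percentage.
#' Entries where the truth is missing are excluded from the denominator.
#'
#' @param truth,imputed matrices (or vectors) of 0/1/2 genotypes.
#' @return Percentage in `[0, 100]`.
#' @export
allelic_error_rate <- function(truth, imputed) {
  check_same_shape(truth, imputed)
  ok <- !is.na(truth) & !is.na(imputed)
  if (!any(ok)) return(NA_real_)
  100 * sum(abs(truth[ok] - imputed[ok])) / (2 * sum(ok))
}

#' Genotypic error rate of imputation
#'
#' Percentage of scored genotypes whose predicted (best-guess) genotype
#' differs from the truth. Always between one and two times the allelic
#' error rate on the same masked set.
#'
#' @inheritParams allelic_error_rate
#' @return Percentage in `[0, 100]`.
#' @export
genotypic_error_rate <- function(truth, imputed) {
  check_same_shape(truth, imputed)
  ok <- !is.na(truth) & !is.na(imputed)
  if (!any(ok)) return(NA_real_)
  100 * sum(truth[ok] != imputed[ok]) / sum(ok)
}

#' Full imputation error report
#'
#' Overall, per-chromosome, per-marker and per-animal allelic and genotypic
#' error rates for a scored truth/imputed pair.
#'
#' @param truth,imputed animals x markers 0/1/2 matrices (`NA` in truth =
#'   excluded from scoring); dimnames required.
#' @param map optional [genome_map()] for the per-chromosome breakdown.
#' @return A list of class `error_report` with data.frames `overall`,
#'   `per_chromosome`, `per_marker`, `per_animal`.
#' @export
error_report <- function(truth, imputed, map = NULL) {
  check_same_shape(truth, imputed)
  ok <- !is.na(truth) & !is.na(imputed)
  mism <- abs(truth - imputed)
  mism[!ok] <- NA
  overall <- data.frame(
    allelic_error = allelic_error_rate(truth, imputed),
    genotypic_error = genotypic_error_rate(truth, imputed),
    n_genotypes = sum(ok), n_alleles = 2L * sum(ok)
  )
  per_marker <- data.frame(
    marker_id = colnames(truth),
    allelic_error = 100 * colSums(mism, na.rm = TRUE) / (2 * colSums(ok)),
    genotypic_error = 100 * colSums(mism > 0, na.rm = TRUE) / colSums(ok),
    n_genotypes = colSums(ok), stringsAsFactors = FALSE
  )
  per_animal <- data.frame(
    animal_id = rownames(truth),
    allelic_error = 100 * rowSums(mism, na.rm = TRUE) / (2 * rowSums(ok)),
    genotypic_error = 100 * rowSums(mism > 0, na.rm = TRUE) / rowSums(ok),
    n_genotypes = rowSums(ok), stringsAsFactors = FALSE
  )
  per_chromosome <- NULL
  if (!is.null(map)) {
    chrom <- map$chrom[match(colnames(truth), map$marker_id)]
    per_chromosome <- do.call(rbind, lapply(unique(chrom), function(ch) {
      cols <- which(chrom == ch)
      data.frame(
        chrom = ch,
        allelic_error = allelic_error_rate(truth[, cols, drop = FALSE],
                                           imputed[, cols, drop = FALSE]),
        genotypic_error = genotypic_error_rate(truth[, cols, drop = FALSE],
                                               imputed[, cols, drop = FALSE]),
        n_genotypes = sum(ok[, cols]), stringsAsFactors = FALSE
      )
    }))
  }
  structure(list(overall = overall, per_chromosome = per_chromosome,
                 per_marker = per_marker, per_animal = per_animal),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("imputation error: allelic", round(x$overall$allelic_error, 3),
      "% / genotypic", round(x$overall$genotypic_error, 3), "% over",
      x$overall$n_genotypes, "genotypes\n")
  invisible(x)
}

#' Stratify imputation error by maximum kinship with the reference
#'
#' Each test animal is assigned its highest pedigree kinship with any
#' reference animal and binned; the default bins are the four intervals
#' 0-0.01, 0.01-0.1, 0.1-0.2 and 0.2-0.4 commonly used to express "how
#' related is this animal to the reference". Closely related test animals
#' are expected to be imputed more accurately.
#'
#' @param per_animal_error named numeric vector of per-animal allelic error
#'   (names = test animal ids).
#' @param kinship kinship matrix from [pedigree_kinship()].
#' @param reference_ids reference animal ids.
#' @param bins increasing break points; default `c(0, 0.01, 0.1, 0.2, 0.4)`.
#' @return data.frame with `bin`, `n`, `mean_allelic_error` (NA for empty
#'   bins), `max_kinship_range`.
#' @export
stratify_error_by_kinship <- function(per_animal_error, kinship,
                                      reference_ids,
                                      bins = c(0, 0.01, 0.1, 0.2, 0.4)) {
  test_ids <- names(per_animal_error)
  if (is.null(test_ids)) stop("per_animal_error must be named by animal id",
                              call. = FALSE)
  kin <- kinship[test_ids, reference_ids, drop = FALSE]
  max_kin <- apply(kin, 1, max)
  top <- max(bins)
  if (any(max_kin > top)) {
    warning("maximum kinship exceeds the top bin; capping at ", top,
            call. = FALSE)
    max_kin <- pmin(max_kin, top)
  }
  lab <- paste(utils::head(bins, -1), bins[-1], sep = "-")
  grp <- cut(max_kin, breaks = bins, labels = lab, include.lowest = TRUE)
  n <- as.integer(table(grp))
  means <- tapply(per_animal_error, grp, mean)
  data.frame(bin = lab, n = n,
             mean_allelic_error = as.numeric(means),
             stringsAsFactors = FALSE)
}

#' Compare imputation error for animals with vs without sire in reference
#'
#' @param per_animal_error named numeric vector (test animal ids).
#' @param pedigree the pedigree.
#' @param reference_ids reference animal ids.
#' @return data.frame with one row per group (`sire_in_reference`
#'   TRUE/FALSE), `n` and `mean_allelic_error` (NA for empty groups).
#' @export
sire_in_reference_comparison <- function(per_animal_error, pedigree,
                                         reference_ids) {
  test_ids <- names(per_animal_error)
  sire <- pedigree$sire_id[match(test_ids, pedigree$animal_id)]
  with_sire <- !is.na(sire) & sire %in% reference_ids
  data.frame(
    sire_in_reference = c(TRUE, FALSE),
    n = c(sum(with_sire), sum(!with_sire)),
    mean_allelic_error = c(
      if (any(with_sire)) mean(per_animal_error[with_sire]) else NA_real_,
      if (any(!with_sire)) mean(per_animal_error[!with_sire]) else NA_real_
    ),
    stringsAsFactors = FALSE
  )
}
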