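#' Simulate founder haplotypes with controllable linkage disequilibrium
#'
#' Founder haplotypes are built as recombinant mosaics of a small pool of
#' ancestral haplotypes. Because nearby markers tend to be copied from the
#' same pool haplotype, adjacent markers are correlated and the correlation
#' decays with genetic distance at the mosaic switch rate -- the LD structure
#' a haplotype-copying imputation model exploits. A small pool and a low
#' switch rate emulate the long-range LD of livestock populations.
#'
#' @param map a [genome_map()].
#' @param maf_spectrum allele-frequency spectrum for the ancestral pool:
#'   either a single frequency applied to every marker or a `c(lo, hi)` range
#'   sampled uniformly per marker. Default `c(0.05, 0.5)`.
#' @param n_ancestral pool size H (>= 2). Default 20.
#' @param mosaic_switch_rate expected pool switches per cM along a founder
#'   haplotype. Default 1.
#' @param n_founders number of founder animals (two haplotypes each).
#' @param seed integer seed.
#' @return A list with `pool` (H x M 0/1 matrix), `founder_haplotypes`
#'   (2*n_founders x M 0/1 matrix, rows 2i-1 and 2i belong to founder i) and
#'   `target_freq` (length-M vector of pool B-allele frequencies).
#' @export
simulate_founder_haplotypes <- function(map, maf_spectrum = c(0.05, 0.5),
                                        n_ancestral = 20,
                                        mosaic_switch_rate = 1,
                                        n_founders, seed = 1) {
  if (!inherits(map, "genome_map")) stop("map must be a genome_map", call. = FALSE)
  if (nrow(map) == 0L) stop("map is empty", call. = FALSE)
  if (n_ancestral < 2) stop("n_ancestral must be >= 2", call. = FALSE)
  if (mosaic_switch_rate < 0) stop("mosaic_switch_rate must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))

  m <- nrow(map)
  freq <- if (length(maf_spectrum) == 1L) {
    rep(maf_spectrum, m)
  } else {
    stats::runif(m, min(maf_spectrum), max(maf_spectrum))
  }
  pool <- matrix(stats::rbinom(n_ancestral * m, 1L, rep(freq, each = n_ancestral)),
                 nrow = n_ancestral, ncol = m)

  n_hap <- 2L * n_founders
  founders <- matrix(0L, nrow = n_hap, ncol = m)
  idx <- chrom_index(map)
  for (cols in idx) {
    cm <- map$cM[cols]
    len <- max(cm) - min(cm)
    for (h in seq_len(n_hap)) {
      n_sw <- stats::rpois(1L, mosaic_switch_rate * len)
      if (n_sw == 0L) {
        founders[h, cols] <- pool[sample.int(n_ancestral, 1L), cols]
      } else {
        cuts <- sort(stats::runif(n_sw, min(cm), max(cm)))
        seg <- findInterval(cm, cuts) + 1L
        src <- sample.int(n_ancestral, n_sw + 1L, replace = TRUE)
        founders[h, cols] <- pool[cbind(src[seg], cols)]
      }
    }
  }
  list(pool = pool, founder_haplotypes = founders, target_freq = freq)
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Simulates Mendelian inheritance of whole haplotypes: every non-founder
#' receives one recombinant gamete from each parent. Crossovers follow the
#' Haldane (no-interference) model -- the number per chromosome is Poisson
#' with mean equal to the genetic length in Morgans and positions are uniform
#' in genetic distance.
#'
#' @param pedigree a topologically ordered pedigree (see
#'   [simulate_pedigree()]).
#' @param founder_haplotypes 2*n_founders x M 0/1 matrix; rows 2i-1, 2i are
#'   the two haplotypes of the i-th founder in pedigree order.
#' @param map a [genome_map()] with M markers.
#' @param seed integer seed.
#' @return A list of class `sim_population`: `haplotypes` (2*n_animals x M
#'   integer 0/1, rows 2i-1, 2i per animal in pedigree order), `pedigree`,
#'   `map`, `phase_known = TRUE`. Attribute `meioses` records the crossover
#'   count of every transmitted gamete per chromosome for audits.
#' @export
gene_drop <- function(pedigree, founder_haplotypes, map, seed = 1) {
  validate_pedigree(pedigree)
  if (!inherits(map, "genome_map")) stop("map must be a genome_map", call. = FALSE)
  founder <- is_founder(pedigree)
  n_founder <- sum(founder)
  if (is.null(founder_haplotypes) || nrow(founder_haplotypes) < 2L * n_founder) {
    stop("founder_haplotypes must supply two rows per founder (",
         2L * n_founder, " needed)", call. = FALSE)
  }
  if (ncol(founder_haplotypes) != nrow(map)) {
    stop("founder_haplotypes column count does not match the map", call. = FALSE)
  }
  set.seed(as.integer(seed))

  n <- nrow(pedigree)
  m <- nrow(map)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  colnames(H) <- map$marker_id
  row_of <- function(i) 2L * i - 1L
  f_rows <- which(founder)
  H[c(row_of(f_rows), row_of(f_rows) + 1L), ] <-
    founder_haplotypes[c(row_of(seq_len(n_founder)),
                         row_of(seq_len(n_founder)) + 1L), ]

  idx <- chrom_index(map)
  cm_by_chrom <- lapply(idx, function(cols) map$cM[cols])
  pos <- seq_len(n)
  names(pos) <- pedigree$animal_id

  rec_animal <- character(0)
  rec_parent <- character(0)
  rec_chrom <- character(0)
  rec_nxo <- integer(0)

  gamete <- function(p_idx, cols, cm) {
    len_m <- (max(cm) - min(cm)) / 100  # Morgans
    n_xo <- stats::rpois(1L, len_m)
    start <- sample.int(2L, 1L)
    if (n_xo == 0L) {
      list(h = H[row_of(p_idx) + start - 1L, cols], n_xo = 0L)
    } else {
      cuts <- sort(stats::runif(n_xo, min(cm), max(cm)))
      par_row <- row_of(p_idx) + (start - 1L + findInterval(cm, cuts)) %% 2L
      list(h = H[cbind(par_row, cols)], n_xo = n_xo)
    }
  }

  for (i in which(!founder)) {
    s <- pos[pedigree$sire_id[i]]
    d <- pos[pedigree$dam_id[i]]
    if (is.na(s) || is.na(d)) {
      stop("non-founder ", pedigree$animal_id[i],
           " must have both parents in the pedigree", call. = FALSE)
    }
    for (k in seq_along(idx)) {
      cols <- idx[[k]]
      cm <- cm_by_chrom[[k]]
      gs <- gamete(s, cols, cm)
      gd <- gamete(d, cols, cm)
      H[row_of(i), cols] <- gs$h
      H[row_of(i) + 1L, cols] <- gd$h
      rec_animal <- c(rec_animal, rep(pedigree$animal_id[i], 2L))
      rec_parent <- c(rec_parent, "sire", "dam")
      rec_chrom <- c(rec_chrom, rep(names(idx)[k], 2L))
      rec_nxo <- c(rec_nxo, gs$n_xo, gd$n_xo)
    }
  }

  pop <- structure(
    list(haplotypes = H, pedigree = pedigree, map = map, phase_known = TRUE),
    class = "sim_population"
  )
  attr(pop, "meioses") <- data.frame(
    animal_id = rec_animal, parent = rec_parent, chrom = rec_chrom,
    n_crossovers = rec_nxo, stringsAsFactors = FALSE
  )
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$pedigree), "animals,", nrow(x$map),
      "markers, phase", if (isTRUE(x$phase_known)) "known" else "unknown", "\n")
  invisible(x)
}

#' Haplotype rows of given animals
#'
#' @param pop a `sim_population`.
#' @param animal_ids animal identifiers (default: all animals).
#' @return Integer vector of row indices into `pop$haplotypes`, two per
#'   animal, in the order requested.
#' @export
haplotype_rows <- function(pop, animal_ids = pop$pedigree$animal_id) {
  i <- match(animal_ids, pop$pedigree$animal_id)
  if (anyNA(i)) stop("unknown animal id(s): ",
                     paste(animal_ids[is.na(i)], collapse = ", "), call. = FALSE)
  as.vector(rbind(2L * i - 1L, 2L * i))
}

#' True genotypes of a simulated population
#'
#' Allele counts of the B (ALT) allele, read directly off the simulated
#' haplotypes: the simulation truth against which imputation is scored.
#'
#' @param pop a `sim_population`.
#' @param markers marker ids to extract (default: all, in map order).
#' @param animal_ids animals to extract (default: all, in pedigree order).
#' @return Integer matrix animals x markers with entries 0/1/2, dimnames set
#'   to animal and marker ids.
#' @export
true_genotypes <- function(pop, markers = NULL, animal_ids = NULL) {
  if (is.null(animal_ids)) animal_ids <- pop$pedigree$animal_id
  cols <- if (is.null(markers)) seq_len(nrow(pop$map)) else {
    j <- match(markers, pop$map$marker_id)
    if (anyNA(j)) stop("marker(s) not on the map", call. = FALSE)
    j
  }
  i <- match(animal_ids, pop$pedigree$animal_id)
  g <- pop$haplotypes[2L * i - 1L, cols, drop = FALSE] +
    pop$haplotypes[2L * i, cols, drop = FALSE]
  dimnames(g) <- list(animal_ids, pop$map$marker_id[cols])
  g
}
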