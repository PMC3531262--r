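#' SNP panel
#'
#' A named ordered subset of the genome map standing in for a genotyping
#' chip of some density.
#'
#' @param name panel label (e.g. "hd", "md", "ld3k").
#' @param markers marker ids; stored in map order.
#' @param map the [genome_map()] the panel refers to.
#' @return A list of class `snp_panel` with `name` and `markers`.
#' @export
snp_panel <- function(name, markers, map) {
  j <- match(markers, map$marker_id)
  if (anyNA(j)) {
    stop("panel markers not on the map: ",
         paste(utils::head(markers[is.na(j)], 3), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, markers = map$marker_id[sort(j)]),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel '", x$name, "': ", length(x$markers), " markers\n", sep = "")
  invisible(x)
}

panel_markers <- function(panel) {
  if (inherits(panel, "snp_panel")) panel$markers else as.character(panel)
}

#' Quality-control thresholds
#'
#' Markers must exceed every threshold to survive filtering: minor allele
#' frequency > `maf_min`, call rate > `call_rate_min`, Hardy-Weinberg exact
#' goodness-of-fit P > `hwe_p_min`.
#'
#' @param maf_min minimum minor allele frequency (exclusive). Default 0.01.
#' @param call_rate_min minimum call rate (exclusive). Default 0.9.
#' @param hwe_p_min minimum HWE chi-square P value (exclusive). Default 1e-4.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.9,
                          hwe_p_min = 1e-4) {
  vals <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(vals < 0 | vals > 1)) {
    stop("all thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

# HWE chi-square goodness-of-fit (1 df) on observed genotype counts
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), NA_real_)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chi <- rep(0, length(n))
  ok <- !is.na(p) & p > 0 & p < 1
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  out <- rep(NA_real_, length(n))
  out[n > 0] <- stats::pchisq(chi[n > 0], df = 1, lower.tail = FALSE)
  out
}

# set offspring genotypes inconsistent with parental genotypes to missing;
# returns the masked matrix plus per-marker mask counts
mendel_mask <- function(geno, pedigree) {
  counts <- integer(ncol(geno))
  ids <- rownames(geno)
  if (is.null(ids)) stop("genotype matrix must have animal-id rownames",
                         call. = FALSE)
  row_of <- function(x) match(x, ids)
  for (i in seq_len(nrow(pedigree))) {
    o <- row_of(pedigree$animal_id[i])
    if (is.na(o)) next
    s <- if (pedigree$sire_id[i] != "0") row_of(pedigree$sire_id[i]) else NA
    d <- if (pedigree$dam_id[i] != "0") row_of(pedigree$dam_id[i]) else NA
    go <- geno[o, ]
    bad <- rep(FALSE, length(go))
    for (p in c(s, d)) {
      if (is.na(p)) next
      gp <- geno[p, ]
      # an opposite-homozygote parent cannot produce a homozygous offspring
      bad <- bad | (!is.na(gp) & ((gp == 0L & go == 2L) | (gp == 2L & go == 0L)))
    }
    if (!is.na(s) && !is.na(d)) {
      gs <- geno[s, ]; gd <- geno[d, ]
      both <- !is.na(gs) & !is.na(gd)
      bad <- bad | (both & gs == 0L & gd == 0L & go != 0L) |
        (both & gs == 2L & gd == 2L & go != 2L) |
        (both & ((gs == 0L & gd == 2L) | (gs == 2L & gd == 0L)) & go != 1L)
    }
    bad <- bad & !is.na(go)
    if (any(bad)) {
      geno[o, bad] <- NA_integer_
      counts[bad] <- counts[bad] + 1L
    }
  }
  list(geno = geno, masked = counts)
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard chip QC pipeline: genotypes showing Mendelian
#' inconsistencies with the pedigree are set to missing first, then per-marker
#' minor allele frequency, call rate and a Hardy-Weinberg chi-square
#' goodness-of-fit (1 df) are computed on the cleaned matrix and markers
#' failing any threshold are removed.
#'
#' @param geno animals x markers matrix, entries 0/1/2/`NA`, dimnames set.
#' @param thresholds a [qc_thresholds()].
#' @param pedigree optional pedigree for Mendelian masking; when `NULL` no
#'   genotypes are masked.
#' @return A list: `markers` (surviving marker ids), `genotypes` (cleaned
#'   matrix restricted to survivors), `report` (one row per input marker with
#'   `marker_id`, `maf`, `call_rate`, `hwe_p`, `mendel_masked_count`,
#'   `status`, `reason`).
#' @export
qc_filter <- function(geno, thresholds = qc_thresholds(), pedigree = NULL) {
  if (is.null(dim(geno)) || nrow(geno) == 0L || ncol(geno) == 0L) {
    stop("genotype matrix is empty", call. = FALSE)
  }
  if (any(!is.na(geno) & !(geno %in% 0:2))) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  masked <- integer(ncol(geno))
  if (!is.null(pedigree)) {
    mm <- mendel_mask(geno, pedigree)
    geno <- mm$geno
    masked <- mm$masked
  }
  n0 <- colSums(geno == 0L, na.rm = TRUE)
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n2 <- colSums(geno == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  call_rate <- n / nrow(geno)
  p <- ifelse(n > 0, (n1 + 2 * n2) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  fail_maf <- is.na(maf) | maf <= thresholds$maf_min
  fail_cr <- call_rate <= thresholds$call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p <= thresholds$hwe_p_min
  pass <- !(fail_maf | fail_cr | fail_hwe)

  reason <- character(ncol(geno))
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- trimws(paste(reason[fail_cr], "call_rate"))
  reason[fail_hwe] <- trimws(paste(reason[fail_hwe], "hwe"))

  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(geno)))
  report <- data.frame(
    marker_id = ids, maf = maf, call_rate = call_rate, hwe_p = hwe_p,
    mendel_masked_count = masked,
    status = ifelse(pass, "pass", "fail"), reason = reason,
    stringsAsFactors = FALSE
  )
  list(markers = ids[pass],
       genotypes = geno[, pass, drop = FALSE],
       report = report)
}

#' Evenly spaced panel thinning by iterative closest-pair removal
#'
#' Reduces a marker set to a target count by repeatedly locating the pair of
#' adjacent markers with the smallest physical interval (within chromosomes
#' only) and discarding the member with the lower minor allele frequency.
#' This iterative rule spreads the surviving markers as evenly as possible
#' while preferring informative (high-MAF) SNPs.
#'
#' Tie rules, applied deterministically: among equally small intervals the
#' pair with the smallest (chromosome, left position) wins; within a pair
#' with equal MAF the right member is removed.
#'
#' @param markers data.frame with columns `chrom`, `marker_id`, `bp`, `maf`.
#' @param target_count number of markers to retain (>= 1, <= input count).
#' @param name label for the resulting panel.
#' @return A list of class `snp_panel` whose `markers` are the survivors in
#'   (chrom, bp) order.
#' @export
thin_evenly <- function(markers, target_count, name = "thinned") {
  if (target_count <= 0) stop("target_count must be positive", call. = FALSE)
  if (target_count > nrow(markers)) {
    stop("target_count exceeds the number of input markers", call. = FALSE)
  }
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$bp)
  chrom <- markers$chrom[ord]
  bp <- as.numeric(markers$bp[ord])
  maf <- as.numeric(markers$maf[ord])
  ids <- as.character(markers$marker_id[ord])
  n <- length(ids)

  if (n == 1L) {
    return(structure(list(name = name, markers = ids), class = "snp_panel"))
  }
  nxt <- c(seq_len(n - 1L) + 1L, NA_integer_)
  prv <- c(NA_integer_, seq_len(n - 1L))
  alive <- rep(TRUE, n)
  gap <- rep(Inf, n)  # gap[i] = interval to the next live marker, same chrom
  same <- which(chrom[-n] == chrom[-1L])
  gap[same] <- bp[same + 1L] - bp[same]

  n_alive <- n
  while (n_alive > target_count) {
    i <- which.min(gap)           # first minimum = smallest (chrom, left bp)
    if (!is.finite(gap[i])) {
      stop("cannot thin below one marker per chromosome: no within-",
           "chromosome pair left to remove", call. = FALSE)
    }
    j <- nxt[i]
    drop <- if (maf[i] < maf[j]) i else j   # equal MAF: remove right member
    p <- prv[drop]; q <- nxt[drop]
    if (!is.na(p)) nxt[p] <- q
    if (!is.na(q)) prv[q] <- p
    alive[drop] <- FALSE
    gap[drop] <- Inf
    if (!is.na(p)) {
      gap[p] <- if (!is.na(q) && chrom[p] == chrom[q]) bp[q] - bp[p] else Inf
    }
    n_alive <- n_alive - 1L
  }
  structure(list(name = name, markers = ids[alive]), class = "snp_panel")
}

#' Intersect two SNP panels
#'
#' Markers present on both panels, in the order of `panel_a` (map order if
#' both panels respect it). An empty intersection is allowed but warned
#' about.
#'
#' @param panel_a,panel_b [snp_panel()]s referring to the same map.
#' @param name label for the result; default `"a_and_b"` style.
#' @return A `snp_panel`.
#' @export
intersect_panels <- function(panel_a, panel_b,
                             name = paste0(panel_a$name, "_x_", panel_b$name)) {
  common <- panel_a$markers[panel_a$markers %in% panel_b$markers]
  if (length(common) == 0L) {
    warning("panels '", panel_a$name, "' and '", panel_b$name,
            "' share no markers", call. = FALSE)
  }
  structure(list(name = name, markers = common), class = "snp_panel")
}

#' Nested density ladder of panels
#'
#' Builds a family of chip-like panels by thinning successively: each lower
#' density is an evenly spaced, MAF-preferring subset of the one above, so
#' the ladder is nested the way commercial low-density chips are designed as
#' subsets of denser ones.
#'
#' @param map a [genome_map()].
#' @param maf per-marker minor allele frequency (named by marker or in map
#'   order) used by the thinning rule.
#' @param counts named integer vector of target sizes in decreasing order,
#'   e.g. `c(md = 667, ld7k = 92, ld3k = 40)`; the full map is always
#'   included as panel `"hd"`.
#' @return Named list of `snp_panel`s, `"hd"` first.
#' @export
build_panels <- function(map, maf, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector", call. = FALSE)
  }
  if (is.unsorted(rev(counts))) {
    stop("counts must be in decreasing order for nesting", call. = FALSE)
  }
  maf_vec <- if (!is.null(names(maf))) maf[map$marker_id] else maf
  panels <- list(hd = snp_panel("hd", map$marker_id, map))
  cur <- data.frame(chrom = map$chrom, marker_id = map$marker_id,
                    bp = map$bp, maf = as.numeric(maf_vec),
                    stringsAsFactors = FALSE)
  for (k in seq_along(counts)) {
    pnl <- thin_evenly(cur, counts[[k]], name = names(counts)[k])
    panels[[names(counts)[k]]] <- pnl
    cur <- cur[cur$marker_id %in% pnl$markers, , drop = FALSE]
  }
  panels
}
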