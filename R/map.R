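#' Construct a genome map
#'
#' A genome map is the marker scaffold every other object in the package is
#' aligned to: ordered biallelic SNPs with physical (bp) and genetic (cM)
#' coordinates per chromosome.
#'
#' @param chrom integer or character chromosome labels, one per marker.
#' @param marker_id unique marker identifiers.
#' @param bp physical positions in base pairs, strictly increasing within
#'   chromosome (1-based).
#' @param cM genetic positions in centimorgans, non-decreasing within
#'   chromosome.
#' @return A `data.frame` of class `genome_map` with columns `chrom`,
#'   `marker_id`, `bp`, `cM`, ordered by (chrom, bp).
#' @export
genome_map <- function(chrom, marker_id, bp, cM) {
  n <- length(marker_id)
  if (length(chrom) != n || length(bp) != n || length(cM) != n) {
    stop("chrom, marker_id, bp and cM must have equal length", call. = FALSE)
  }
  if (n == 0L) stop("a genome map must contain at least one marker", call. = FALSE)
  if (anyDuplicated(marker_id)) {
    stop("marker ids must be unique genome-wide", call. = FALSE)
  }
  map <- data.frame(
    chrom = as.character(chrom),
    marker_id = as.character(marker_id),
    bp = as.integer(bp),
    cM = as.numeric(cM),
    stringsAsFactors = FALSE
  )
  map <- map[order(match(map$chrom, unique(map$chrom)), map$bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (is.unsorted(sub$bp, strictly = TRUE)) {
      stop("physical positions must be strictly increasing within chromosome ",
           ch, call. = FALSE)
    }
    if (is.unsorted(sub$cM)) {
      stop("genetic positions must be non-decreasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  class(map) <- c("genome_map", "data.frame")
  map
}

#' Uniform synthetic genome map
#'
#' Equally spaced markers with a constant cM/Mb ratio, the standard cattle
#' approximation of roughly 1 cM per Mb. The default scale -- 5 chromosomes
#' of 2,000 markers over 8 Mb (8 cM) each -- is the package's high-density
#' truth map: each chromosome emulates a contiguous chromosome segment typed
#' at high-density-chip marker spacing (about 250 markers per cM), so that
#' thinned panels reproduce the per-cM densities of the commercial medium-
#' and low-density chips. Keeping density per cM faithful, rather than
#' chromosome length, is what preserves the difficulty of imputation when
#' the marker count is scaled down.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_mb chromosome length in megabases.
#' @param cm_per_mb genetic map density in cM per Mb.
#' @return A [genome_map()].
#' @export
uniform_genome_map <- function(n_chrom = 5, markers_per_chrom = 2000,
                               chrom_length_mb = 8, cm_per_mb = 1) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1)
  bp1 <- round(seq(1, chrom_length_mb * 1e6, length.out = markers_per_chrom))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = markers_per_chrom)
  ids <- paste0("snp_", rep(seq_len(n_chrom), each = markers_per_chrom), "_",
                rep(seq_len(markers_per_chrom), n_chrom))
  genome_map(chrom = chrom, marker_id = ids,
             bp = rep(bp1, n_chrom),
             cM = rep(bp1 / 1e6 * cm_per_mb, n_chrom))
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x), "markers on", length(unique(x$chrom)),
      "chromosome(s)\n")
  cat("  genetic length:", round(sum(tapply(x$cM, x$chrom, function(z) {
    max(z) - min(z)
  })), 1), "cM total\n")
  invisible(x)
}

# split marker indices by chromosome, preserving map order
chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
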