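#' Read and write tab-separated pedigree, phenotype, map and panel tables
#'
#' Pedigree files have columns `animal_id`, `sire_id`, `dam_id`, `sex`,
#' `birth_year` with `"0"` marking an unknown parent. Phenotype files have
#' `animal_id`, `trait`, `dtd`, `reliability`. Map files have `chrom`,
#' `marker_id`, `bp`, `cM`. Panel files have `chrom`, `marker_id`.
#' Violations are reported with the offending row.
#'
#' @param path file path.
#' @return `read_pedigree` a `pedigree` data.frame; `read_phenotypes` a
#'   phenotype data.frame; `read_map` a [genome_map()]; `read_panel` a
#'   two-column data.frame.
#' @name tables
NULL

read_tsv_checked <- function(path, required) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = NA, stringsAsFactors = FALSE,
                         check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname tables
#' @export
read_pedigree <- function(path) {
  x <- read_tsv_checked(path, c("animal_id", "sire_id", "dam_id"))
  for (col in c("animal_id", "sire_id", "dam_id")) {
    x[[col]] <- as.character(x[[col]])
  }
  class(x) <- c("pedigree", "data.frame")
  validate_pedigree(x)
  x
}

#' @rdname tables
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped)[, c("animal_id", "sire_id", "dam_id",
                                            "sex", "birth_year")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tables
#' @export
read_phenotypes <- function(path) {
  x <- read_tsv_checked(path, c("animal_id", "trait", "dtd", "reliability"))
  bad <- which(x$reliability <= 0 | x$reliability >= 1)
  if (length(bad)) {
    stop(basename(path), ": row ", bad[1],
         ": reliability must lie strictly inside (0, 1)", call. = FALSE)
  }
  x
}

#' @rdname tables
#' @param phen phenotype data.frame to write.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen[, c("animal_id", "trait", "dtd", "reliability")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tables
#' @export
read_map <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "marker_id", "bp", "cM"))
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, ]
    if (is.unsorted(sub$bp, strictly = TRUE)) {
      row <- which(x$chrom == ch)[which(diff(sub$bp) <= 0)[1] + 1L]
      stop(basename(path), ": row ", row,
           ": physical positions out of order on chromosome ", ch,
           call. = FALSE)
    }
  }
  genome_map(x$chrom, x$marker_id, x$bp, x$cM)
}

#' @rdname tables
#' @param map genome map to write.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tables
#' @param panel [snp_panel()] to write.
#' @param map genome map supplying chromosome labels.
#' @export
write_panel <- function(panel, map, path) {
  j <- match(panel$markers, map$marker_id)
  utils::write.table(
    data.frame(chrom = map$chrom[j], marker_id = panel$markers),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname tables
#' @export
read_panel <- function(path) {
  read_tsv_checked(path, c("chrom", "marker_id"))
}

#' Write genotypes or haplotypes to VCF
#'
#' Biallelic SNPs, VCF v4.2 with alleles A (REF) and B (ALT). Phased
#' haplotypes are written as `0|1`-style GT; unphased genotypes as `0/1`
#' with `./.` for missing. Optional per-genotype dosage (`DS`, 3 decimals)
#' and genotype-posterior (`GP`, 4 decimals) fields carry imputation output.
#' Output is bgzip-free gzip when `path` ends in `.gz`, plain text
#' otherwise.
#'
#' @param path output path.
#' @param geno animals x markers matrix: 0/1/2/`NA` genotypes, or `NULL`
#'   when writing `haplotypes`.
#' @param map [genome_map()] rows for the markers written (same order).
#' @param haplotypes optional 2n x markers 0/1 matrix of phased haplotypes
#'   (rows 2i-1, 2i per animal); takes precedence over `geno` for GT.
#' @param animal_ids sample names.
#' @param ds optional dosage matrix like `geno`.
#' @param gp optional n x markers x 3 posterior array.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, geno, map, haplotypes = NULL,
                      animal_ids = NULL, ds = NULL, gp = NULL) {
  phased <- !is.null(haplotypes)
  n <- if (phased) nrow(haplotypes) / 2L else nrow(geno)
  m <- nrow(map)
  if (is.null(animal_ids)) animal_ids <- paste0("S", seq_len(n))

  if (phased) {
    a1 <- haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    a2 <- haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), n, m)
  } else {
    gt <- matrix("./.", n, m)
    ok <- !is.na(geno)
    code <- c("0/0", "0/1", "1/1")
    gt[ok] <- code[geno[ok] + 1L]
  }
  fmt <- "GT"
  if (!is.null(ds)) {
    gt <- matrix(paste0(gt, ":", sprintf("%.3f", ds)), n, m)
    fmt <- paste0(fmt, ":DS")
  }
  if (!is.null(gp)) {
    gps <- matrix(sprintf("%.4f,%.4f,%.4f", gp[, , 1], gp[, , 2], gp[, , 3]),
                  n, m)
    gt <- matrix(paste0(gt, ":", gps), n, m)
    fmt <- paste0(fmt, ":GP")
  }

  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=imputeBench",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(ds)) '##FORMAT=<ID=DS,Number=1,Type=Float,Description="B-allele dosage">',
    if (!is.null(gp)) '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype posterior probabilities">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", animal_ids), collapse = "\t")
  ), con)
  body <- cbind(map$chrom, map$bp, map$marker_id, "A", "B", ".", ".", ".",
                fmt, t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF of biallelic SNPs
#'
#' Parses GT (phased or unphased), and DS/GP when present, via `vcfR`.
#' Multi-allelic records are skipped with a warning.
#'
#' @param path VCF path (optionally gzipped).
#' @return A list: `map` (chrom/marker_id/bp data.frame), `genotypes`
#'   (animals x markers 0/1/2/`NA`), `haplotypes` (2n x markers, only when
#'   every genotype is phased), `ds`, `gp` (or `NULL`), `animal_ids`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = markers, cols = samples
  phased_all <- all(grepl("\\|", gt[!is.na(gt) & gt != "."]))
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(z) {
      if (length(z) != 2L || any(z == ".")) NA_integer_
      else sum(as.integer(z))
    }, integer(1))
  }
  gmat <- apply(gt, 2, alleles)
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = 1)
  geno <- t(gmat)  # animals x markers
  colnames(geno) <- fix[, "ID"]
  rownames(geno) <- colnames(gt)

  haps <- NULL
  if (phased_all && !anyNA(geno)) {
    split1 <- function(x, k) as.integer(vapply(strsplit(x, "\\|"),
                                               `[[`, character(1), k))
    n <- ncol(gt)
    haps <- matrix(0L, 2L * n, nrow(gt))
    for (s in seq_len(n)) {
      haps[2L * s - 1L, ] <- split1(gt[, s], 1L)
      haps[2L * s, ] <- split1(gt[, s], 2L)
    }
    colnames(haps) <- fix[, "ID"]
  }

  ds <- gp <- NULL
  fmt <- v@gt[1, "FORMAT"]
  if (grepl("\\bDS\\b", fmt)) {
    dsr <- vcfR::extract.gt(v, element = "DS")
    ds <- t(apply(dsr, 2, as.numeric))
    if (ncol(gt) == 1L) ds <- matrix(as.numeric(dsr), nrow = 1)
    dimnames(ds) <- dimnames(geno)
  }
  if (grepl("\\bGP\\b", fmt)) {
    gpr <- vcfR::extract.gt(v, element = "GP")
    n <- ncol(gpr); m <- nrow(gpr)
    gp <- array(NA_real_, c(n, m, 3))
    for (s in seq_len(n)) {
      parts <- do.call(rbind, lapply(strsplit(gpr[, s], ","), as.numeric))
      gp[s, , ] <- parts
    }
    dimnames(gp) <- c(dimnames(geno), list(c("p_AA", "p_AB", "p_BB")))
  }

  list(
    map = data.frame(chrom = fix[, "CHROM"], marker_id = fix[, "ID"],
                     bp = as.integer(fix[, "POS"]), stringsAsFactors = FALSE),
    genotypes = geno, haplotypes = haps, ds = ds, gp = gp,
    animal_ids = colnames(gt)
  )
}
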