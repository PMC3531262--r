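#' Simulate a multi-generation pedigree with overlapping sire families
#'
#' Produces a topologically ordered pedigree in which a small number of sires
#' per generation each father many offspring (half-sib families), the mating
#' structure typical of dairy cattle breeding schemes. Founders form
#' generation 1 with unknown parents; each later generation is produced by
#' designated sires drawn from males of all earlier generations and dams drawn
#' from females of all earlier generations, so generations overlap on the
#' male side exactly as successful bulls are reused across years.
#'
#' @param n_founders number of founder animals (>= 2; split evenly male/female).
#' @param n_generations number of generations including the founders (>= 1).
#' @param n_sires number of designated sires used per non-founder generation.
#' @param n_offspring number of offspring born per non-founder generation;
#'   defaults to `n_founders`.
#' @param prop_male probability an offspring is male.
#' @param base_year birth year assigned to founders; each generation is born
#'   one year later.
#' @param seed integer seed; the pedigree is a pure function of its arguments.
#' @return A `data.frame` of class `pedigree` with columns `animal_id`,
#'   `sire_id`, `dam_id` (`"0"` = unknown), `sex` (`"M"`/`"F"`), `birth_year`,
#'   `generation`. Attribute `sires_by_generation` records the designated
#'   sires of each non-founder generation.
#' @export
simulate_pedigree <- function(n_founders, n_generations, n_sires = 25,
                              n_offspring = n_founders, prop_male = 0.5,
                              base_year = 2000, seed = 1) {
  if (n_founders < 2) stop("n_founders must be >= 2", call. = FALSE)
  if (n_generations < 1) stop("n_generations must be >= 1", call. = FALSE)
  if (n_sires < 1 || n_offspring < 1) {
    stop("n_sires and n_offspring must be positive", call. = FALSE)
  }
  set.seed(as.integer(seed))

  id <- function(i) sprintf("A%05d", i)
  n_total <- n_founders + (n_generations - 1L) * n_offspring
  animal_id <- id(seq_len(n_total))
  sire_id <- rep("0", n_total)
  dam_id <- rep("0", n_total)
  sex <- rep(NA_character_, n_total)
  generation <- rep(NA_integer_, n_total)

  # founders: alternate sexes so both are always available
  sex[seq_len(n_founders)] <- rep_len(c("M", "F"), n_founders)
  generation[seq_len(n_founders)] <- 1L

  sires_by_generation <- list()
  nxt <- n_founders + 1L
  for (g in seq_len(n_generations - 1L) + 1L) {
    prev <- which(generation < g)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) == 0L || length(females) == 0L) {
      stop("generation ", g, " has no available sires or dams", call. = FALSE)
    }
    sires <- males[sample.int(length(males), min(n_sires, length(males)))]
    sires_by_generation[[as.character(g)]] <- animal_id[sires]
    rows <- seq.int(nxt, nxt + n_offspring - 1L)
    sire_id[rows] <-
      animal_id[sires[sample.int(length(sires), n_offspring, replace = TRUE)]]
    dam_id[rows] <-
      animal_id[females[sample.int(length(females), n_offspring, replace = TRUE)]]
    sex[rows] <- ifelse(stats::runif(n_offspring) < prop_male, "M", "F")
    generation[rows] <- g
    nxt <- nxt + n_offspring
  }

  ped <- data.frame(
    animal_id = animal_id, sire_id = sire_id, dam_id = dam_id,
    sex = sex, birth_year = base_year + generation - 1L,
    generation = generation, stringsAsFactors = FALSE
  )
  attr(ped, "sires_by_generation") <- sires_by_generation
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree ordering and parent integrity
#'
#' Checks the invariants every pedigree consumer in the package relies on:
#' parents precede offspring, nobody is their own ancestor (implied by
#' ordering), sires are male and dams female where sex is known.
#'
#' @param ped pedigree data.frame (`animal_id`, `sire_id`, `dam_id`, `sex`,
#'   `birth_year`).
#' @return `ped`, invisibly; errors describe the offending row.
#' @export
validate_pedigree <- function(ped) {
  req <- c("animal_id", "sire_id", "dam_id")
  if (!all(req %in% names(ped))) {
    stop("pedigree must have columns animal_id, sire_id, dam_id", call. = FALSE)
  }
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal_id
  for (col in c("sire_id", "dam_id")) {
    p <- ped[[col]]
    known <- p != "0"
    if (any(known & !(p %in% ped$animal_id))) {
      bad <- which(known & !(p %in% ped$animal_id))[1]
      stop("row ", bad, ": ", col, " ", p[bad],
           " not declared in the pedigree (use \"0\" for unknown)",
           call. = FALSE)
    }
    late <- known & pos[p] >= pos
    if (any(late, na.rm = TRUE)) {
      stop("row ", which(late)[1], ": parent appears at or after offspring; ",
           "pedigree must be topologically ordered", call. = FALSE)
    }
  }
  if ("sex" %in% names(ped)) {
    sx <- ped$sex[match(ped$sire_id, ped$animal_id)]
    if (any(!is.na(sx) & sx != "M")) {
      stop("a recorded sire is not male", call. = FALSE)
    }
    dx <- ped$sex[match(ped$dam_id, ped$animal_id)]
    if (any(!is.na(dx) & dx != "F")) {
      stop("a recorded dam is not female", call. = FALSE)
    }
  }
  invisible(ped)
}

is_founder <- function(ped) ped$sire_id == "0" & ped$dam_id == "0"
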