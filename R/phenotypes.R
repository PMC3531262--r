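#' Trait specification
#'
#' @param name trait label.
#' @param h2 narrow-sense heritability in (0, 1).
#' @param n_qtl number of causal markers drawn from the map.
#' @param effect_dist distribution of causal effects before scaling;
#'   currently `"normal"`.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name = "trait", h2 = 0.25, n_qtl = 300,
                       effect_dist = "normal") {
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1) {
    stop("heritability must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (n_qtl < 1) stop("n_qtl must be positive", call. = FALSE)
  structure(list(name = name, h2 = h2, n_qtl = as.integer(n_qtl),
                 effect_dist = match.arg(effect_dist, "normal")),
            class = "trait_spec")
}

#' Simulate daughter-trait-deviation phenotypes
#'
#' Generates the phenotype a progeny-testing scheme attaches to a bull: a
#' daughter trait deviation (DTD) equal to the animal's true breeding value
#' plus a residual whose variance shrinks as the DTD's reliability grows.
#'
#' The model: `n_qtl` causal markers receive normal effects, scaled so the
#' true breeding values (TBV) have variance `h2` on a phenotypic-variance-1
#' scale. Each animal is assigned a daughter-group size, from which the DTD
#' reliability follows the standard progeny-test formula
#' `rel = n*t / (1 + (n-1)*t)` with `t = h2/4`; reliabilities are then
#' clamped into `reliability_range`. The DTD residual variance is
#' `h2 * (1 - rel) / rel`, so that `Var(TBV)/Var(DTD) = rel` animal by
#' animal. Low-heritability traits therefore carry noisier DTDs, which is
#' what depresses their genomic prediction accuracy downstream.
#'
#' @param pop a `sim_population`.
#' @param trait a [trait_spec()].
#' @param reliability_range clamp interval for reliabilities; kept inside
#'   `[0.01, 0.99]` so downstream mixed-model weights stay finite.
#' @param daughters_range range of daughter-group sizes sampled
#'   log-uniformly per animal.
#' @param seed integer seed.
#' @return A `data.frame` with columns `animal_id`, `trait`, `dtd`,
#'   `reliability`. Attributes `tbv` (named vector, simulation truth),
#'   `qtl_markers` and `qtl_effects` are retained for validation.
#' @export
simulate_phenotypes <- function(pop, trait = trait_spec(),
                                reliability_range = c(0.3, 0.99),
                                daughters_range = c(20, 300), seed = 1) {
  if (!inherits(trait, "trait_spec")) {
    trait <- do.call(trait_spec, as.list(trait))
  }
  set.seed(as.integer(seed))
  m <- nrow(pop$map)
  n_qtl <- min(trait$n_qtl, m)
  qtl <- sort(sample.int(m, n_qtl))
  qtl_ids <- pop$map$marker_id[qtl]
  beta <- stats::rnorm(n_qtl)

  g <- true_genotypes(pop, markers = qtl_ids)
  tbv <- drop(g %*% beta)
  v <- stats::var(tbv)
  if (v > 0) {
    sc <- sqrt(trait$h2 / v)
    tbv <- (tbv - mean(tbv)) * sc
    beta <- beta * sc
  }

  n <- nrow(pop$pedigree)
  lo <- max(min(reliability_range), 0.01)
  hi <- min(max(reliability_range), 0.99)
  t4 <- trait$h2 / 4
  nd <- round(exp(stats::runif(n, log(min(daughters_range)),
                               log(max(daughters_range)))))
  rel <- pmin(pmax(nd * t4 / (1 + (nd - 1) * t4), lo), hi)
  resid_sd <- sqrt(trait$h2 * (1 - rel) / rel)
  dtd <- tbv + stats::rnorm(n, sd = resid_sd)

  out <- data.frame(
    animal_id = pop$pedigree$animal_id, trait = trait$name,
    dtd = dtd, reliability = rel, stringsAsFactors = FALSE
  )
  attr(out, "tbv") <- stats::setNames(tbv, pop$pedigree$animal_id)
  attr(out, "qtl_markers") <- qtl_ids
  attr(out, "qtl_effects") <- beta
  out
}
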