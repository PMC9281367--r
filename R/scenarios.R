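# Seeded synthetic-scenario generator: random kinetic schemes with the
# statistical structure the analyses assume (log-uniform rates over
# 1e-5..1e-1 s^-1, association constants over 1e-4..1e6 uM^-1, binder:
# substrate ratios from <<1 to >>1, uniform vs negative-catalysis
# variants). All property-style tests run on these schemes, with no
# external input.

#' Configuration for the synthetic-scenario generator
#'
#' @param seed Integer seed; every sampled scheme is a pure function of
#'   `(seed, index)`.
#' @param kind Scheme kind: `"uniform_binder"`, `"two_product"` or
#'   `"coupled"`.
#' @param uniform If `TRUE`, bound conversion rates equal free ones
#'   (nc_fold = 1) regardless of the nc_fold range.
#' @param k_range Log-uniform range for first-order rate constants, s^-1.
#' @param K_range Log-uniform range for association constants, uM^-1.
#' @param conc_range Log-uniform range for S0 and Q0/U0, uM.
#' @param nc_range Log-uniform range for the negative-catalysis fold.
#' @param k_on Association on-rate, uM^-1 s^-1 (fixed, not sampled).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            kind = c("two_product", "uniform_binder", "coupled"),
                            uniform = FALSE,
                            k_range = c(1e-5, 1e-1),
                            K_range = c(1e-4, 1e6),
                            conc_range = c(0.1, 100),
                            nc_range = c(1, 1e4),
                            k_on = KTRAP_DEFAULT_KON) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  for (r in list(k_range, K_range, conc_range, nc_range)) {
    stopifnot(length(r) == 2L, all(r > 0), r[1] < r[2] || all(r == r[1]))
  }
  structure(list(seed = as.integer(seed), kind = kind, uniform = isTRUE(uniform),
                 k_range = k_range, K_range = K_range,
                 conc_range = conc_range, nc_range = nc_range, k_on = k_on),
            class = "scenario_config")
}

# Run `expr` under a derived, reproducible RNG substream without touching
# the caller's global RNG state. Stream = Mersenne-Twister seeded with a
# 31-bit hash of (seed, index).
with_scenario_rng <- function(seed, index, expr) {
  derived <- (as.numeric(seed) * 2654435761 + as.numeric(index) * 97561) %%
    2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  expr
}

runif_log <- function(n, range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Sample a random kinetic scheme
#'
#' Deterministic given `(cfg$seed, index)`. Two-product and coupled schemes
#' set k2 = 10 k1 (the solution bias toward the undesired product) and
#' derive the bound rates as k1_bound = k1, k2_bound = k2 / nc_fold.
#'
#' @param cfg A [scenario_config()].
#' @param index Scenario index (positive integer).
#' @return A `kinetic_scheme` that passes [validate_scheme()].
#' @examples
#' cfg <- scenario_config(seed = 42)
#' identical(sample_scheme(cfg, 1)$conversions, sample_scheme(cfg, 1)$conversions)
#' @export
sample_scheme <- function(cfg, index) {
  stopifnot(inherits(cfg, "scenario_config"), index == round(index), index >= 1)
  with_scenario_rng(cfg$seed, index, {
    K <- runif_log(1, cfg$K_range)
    S0 <- runif_log(1, cfg$conc_range)
    B0 <- runif_log(1, cfg$conc_range)
    if (cfg$kind == "uniform_binder") {
      k <- runif_log(1, cfg$k_range)
      return(uniform_binder_scheme(k = k, K = K, k_on = cfg$k_on,
                                   S0 = S0, U0 = B0))
    }
    k1 <- runif_log(1, cfg$k_range)
    k2 <- 10 * k1
    nc <- if (cfg$uniform) 1 else runif_log(1, cfg$nc_range)
    if (cfg$kind == "two_product") {
      two_product_scheme(k1_non = k1, k2_non = k2, k1_bound = k1,
                         k2_bound = k2 / nc, K = K, k_on = cfg$k_on,
                         S0 = S0, Q0 = B0)
    } else {
      k_f <- runif_log(1, cfg$k_range)
      coupled_scheme(k1_non = k1, k2_non = k2, k1_bound = k1,
                     k2_bound = k2 / nc, K = K, k_on = cfg$k_on,
                     S0 = S0, Q0 = B0, k_f = k_f)
    }
  })
}

#' Matched uniform-binder control of a scheme
#'
#' Returns the same scheme with every bound conversion rate reset to its
#' free-solution counterpart (nc_fold = 1), preserving binding constants,
#' on-rate and concentrations. The control's completion product ratio is
#' k1_non / k2_non whatever the binding parameters.
#'
#' @param scheme A two-product or coupled `kinetic_scheme`.
#' @return A `kinetic_scheme` with `metadata$is_uniform = TRUE`.
#' @export
paired_uniform_control <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sp <- scheme$species
  if (!any(sp$lineage == "P1")) {
    stop("control is defined for two-product or coupled schemes", call. = FALSE)
  }
  cv <- scheme$conversions
  cplx <- sp$name[sp$role == "complex"]
  bd <- scheme$bindings
  ligand_of <- stats::setNames(bd$ligand, bd$complex)
  for (i in seq_len(nrow(cv))) {
    if (cv$from[i] %in% cplx) {
      free_from <- ligand_of[[cv$from[i]]]
      free_to <- ligand_of[[cv$to[i]]]
      j <- which(cv$from == free_from & cv$to == free_to)
      if (length(j) != 1L) {
        stop(sprintf("no unique free counterpart for conversion %s -> %s",
                     cv$from[i], cv$to[i]), call. = FALSE)
      }
      cv$k[i] <- cv$k[j]
    }
  }
  md <- scheme$metadata
  md$is_uniform <- TRUE
  md$nc_fold <- 1
  kinetic_scheme(sp, bd, cv, metadata = md)
}
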