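# Transition-state-theory conversions between free energies and first-order
# rate constants, plus free-energy-profile bookkeeping and binder
# classification (uniform binding vs negative/positive catalysis).

#' Thermal context for free-energy/rate conversions
#'
#' Bundles the gas constant and absolute temperature used in every
#' transition-state-theory conversion. Defaults give RT = 0.592 kcal/mol,
#' under which a 10-fold rate ratio corresponds to RT ln(10) = 1.364
#' kcal/mol of barrier destabilization.
#'
#' @param temperature Absolute temperature in K. Must be positive.
#' @param gas_constant Gas constant in kcal mol^-1 K^-1.
#' @return An object of class `thermal_context` with fields
#'   `temperature`, `gas_constant` and the derived product `rt` (kcal/mol).
#' @examples
#' ctx <- thermal_context()
#' ctx$rt * log(10) # ~1.364 kcal/mol per decade of rate
#' @export
thermal_context <- function(temperature = 298, gas_constant = 1.987e-3) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0,
            is.numeric(gas_constant), length(gas_constant) == 1L, gas_constant > 0)
  structure(
    list(temperature = temperature, gas_constant = gas_constant,
         rt = gas_constant * temperature),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("<thermal_context> T = %g K, R = %g kcal/mol/K, RT = %.4g kcal/mol\n",
              x$temperature, x$gas_constant, x$rt))
  invisible(x)
}

#' Barrier destabilization implied by a fold rate reduction
#'
#' Under transition-state theory a first-order rate constant is proportional
#' to exp(-dG/RT), so slowing a reaction `fold`-fold corresponds to raising
#' its activation barrier by RT ln(fold).
#'
#' @param fold Dimensionless rate ratio (slow relative to fast), >= 1.
#' @param ctx A [thermal_context()].
#' @return Barrier increase in kcal/mol. Vectorized over `fold`.
#' @seealso [fold_from_ddg()] for the inverse.
#' @examples
#' ddg_from_fold(10)  # 1.364, i.e. ~1.4 kcal/mol per 10-fold slowdown
#' ddg_from_fold(100) # 2.727
#' @export
ddg_from_fold <- function(fold, ctx = thermal_context()) {
  stopifnot(is.numeric(fold), inherits(ctx, "thermal_context"))
  if (any(fold < 1)) {
    stop("`fold` must be >= 1: a destabilization slows a reaction, it cannot speed it up",
         call. = FALSE)
  }
  ctx$rt * log(fold)
}

#' Fold rate reduction implied by a barrier destabilization
#'
#' Inverse of [ddg_from_fold()]: exp(ddg / RT).
#'
#' @param ddg Barrier increase in kcal/mol, >= 0.
#' @param ctx A [thermal_context()].
#' @return Dimensionless fold reduction, >= 1. Vectorized over `ddg`.
#' @examples
#' fold_from_ddg(1.364) # ~10
#' fold_from_ddg(1.4)   # 10.63: the quoted 1.4 is itself a rounded value
#' @export
fold_from_ddg <- function(ddg, ctx = thermal_context()) {
  stopifnot(is.numeric(ddg), inherits(ctx, "thermal_context"))
  if (any(ddg < 0)) stop("`ddg` must be >= 0", call. = FALSE)
  exp(ddg / ctx$rt)
}

#' First-order rate constant from a half-life
#'
#' An irreversible unimolecular conversion is a decay: each substrate
#' molecule, bound or free, has half-life t_1/2 and hazard ln(2)/t_1/2.
#'
#' @param t_half Half-life in seconds, > 0.
#' @return Rate constant in s^-1. Vectorized.
#' @seealso [halflife_from_rate()]
#' @export
rate_from_halflife <- function(t_half) {
  stopifnot(is.numeric(t_half))
  if (any(t_half <= 0)) stop("`t_half` must be > 0", call. = FALSE)
  log(2) / t_half
}

#' Half-life from a first-order rate constant
#' @param k Rate constant in s^-1, > 0.
#' @return Half-life in seconds. Vectorized.
#' @export
halflife_from_rate <- function(k) {
  stopifnot(is.numeric(k))
  if (any(k <= 0)) stop("`k` must be > 0", call. = FALSE)
  log(2) / k
}

#' Free-energy profile of a reaction branch
#'
#' An ordered ladder of state free energies along a reaction coordinate,
#' alternating ground states and barriers (transition states). Profiles come
#' in pairs: an `unbound` branch for the solution reaction and a `bound`
#' branch for the same chemistry inside a binder complex.
#'
#' @param states A data.frame with columns `name` (unique state labels),
#'   `kind` (`"ground"` or `"barrier"`, strictly alternating, starting and
#'   ending on `"ground"`), and `G` (free energy, kcal/mol; barriers must not
#'   lie below either flanking ground state).
#' @param branch `"unbound"` or `"bound"`.
#' @return An object of class `free_energy_profile`.
#' @examples
#' p <- free_energy_profile(data.frame(
#'   name = c("S", "Sdd", "P"), kind = c("ground", "barrier", "ground"),
#'   G = c(0, 15, -5)))
#' barrier_heights(p)
#' @export
free_energy_profile <- function(states, branch = c("unbound", "bound")) {
  branch <- match.arg(branch)
  stopifnot(is.data.frame(states),
            all(c("name", "kind", "G") %in% names(states)))
  states <- data.frame(name = as.character(states$name),
                       kind = as.character(states$kind),
                       G = as.numeric(states$G),
                       stringsAsFactors = FALSE)
  n <- nrow(states)
  if (n < 1L) stop("profile needs at least one state", call. = FALSE)
  if (anyDuplicated(states$name)) stop("state names must be unique", call. = FALSE)
  if (!all(states$kind %in% c("ground", "barrier"))) {
    stop("state kind must be 'ground' or 'barrier'", call. = FALSE)
  }
  expected <- rep(c("ground", "barrier"), length.out = n)
  if (!identical(states$kind, expected) || states$kind[n] != "ground") {
    stop("states must alternate ground/barrier/ground..., starting and ending on a ground state",
         call. = FALSE)
  }
  for (i in which(states$kind == "barrier")) {
    if (states$G[i] < states$G[i - 1L] || states$G[i] < states$G[i + 1L]) {
      stop(sprintf("barrier '%s' lies below a flanking ground state", states$name[i]),
           call. = FALSE)
    }
  }
  structure(list(branch = branch, states = states), class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> branch: %s\n", x$branch))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Forward activation energies of a profile
#'
#' Height of each barrier above its preceding ground state, the quantity a
#' forward rate constant depends on.
#'
#' @param profile A [free_energy_profile()].
#' @return Named numeric vector (kcal/mol), one entry per barrier.
#' @export
barrier_heights <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  st <- profile$states
  idx <- which(st$kind == "barrier")
  stats::setNames(st$G[idx] - st$G[idx - 1L], st$name[idx])
}

#' Rate constant from a barrier crossing
#'
#' k = prefactor * exp(-(G_barrier - G_ground)/RT). The prefactor is the
#' symbolic attempt frequency of the barrier crossing; only ratios of such
#' rates are physically meaningful here, so it defaults to 1 s^-1 as a pure
#' convention.
#'
#' @param profile A [free_energy_profile()].
#' @param ground,barrier State names present in the profile.
#' @param prefactor Attempt frequency in s^-1 (convention, default 1).
#' @param ctx A [thermal_context()].
#' @return A `rate_constant`: list with `value` (s^-1) and `label`.
#' @export
barrier_rate <- function(profile, ground, barrier, prefactor = 1,
                         ctx = thermal_context()) {
  stopifnot(inherits(profile, "free_energy_profile"), prefactor >= 0)
  st <- profile$states
  ig <- match(ground, st$name)
  ib <- match(barrier, st$name)
  if (is.na(ig)) stop(sprintf("unknown state '%s'", ground), call. = FALSE)
  if (is.na(ib)) stop(sprintf("unknown state '%s'", barrier), call. = FALSE)
  dg <- st$G[ib] - st$G[ig]
  if (dg < 0) stop("barrier lies below the ground state", call. = FALSE)
  rate_constant(prefactor * exp(-dg / ctx$rt),
                label = sprintf("k(%s->%s|%s)", ground, barrier, profile$branch))
}

#' Labelled first-order rate constant
#' @param value Rate in s^-1, >= 0.
#' @param label Optional label, e.g. `"k2_NC"`.
#' @return An object of class `rate_constant`.
#' @export
rate_constant <- function(value, label = "") {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(value = value, label = label), class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("<rate_constant> %s = %g s^-1\n",
              if (nzchar(x$label)) x$label else "k", x$value))
  invisible(x)
}

#' Shift every state of a profile by the same amount
#'
#' Uniform binding stabilizes substrate, transition state(s) and product
#' equally; the profile drops rigidly and every activation energy -- hence
#' every [barrier_rate()] -- is unchanged.
#'
#' @param profile A [free_energy_profile()].
#' @param shift Stabilization in kcal/mol (positive lowers all states).
#' @return A new profile with `G - shift` everywhere.
#' @export
apply_uniform_shift <- function(profile, shift) {
  stopifnot(inherits(profile, "free_energy_profile"),
            is.numeric(shift), length(shift) == 1L)
  st <- profile$states
  st$G <- st$G - shift
  free_energy_profile(st, branch = profile$branch)
}

#' Classify a binder from its bound vs unbound free-energy profiles
#'
#' Compares state-by-state stabilizations and forward activation energies:
#' * `uniform` -- all states stabilized equally (all barriers unchanged);
#' * `negative_catalysis` -- some activation energy is larger on the bound
#'   branch (a route is slowed), none smaller;
#' * `positive_catalysis` -- some activation energy is smaller, none larger;
#' * `mixed` -- anything else (e.g. one route slowed and another sped up,
#'   or unequal ground-state stabilizations with unchanged barriers).
#'
#' @param unbound,bound [free_energy_profile()]s sharing state names.
#' @param tol Tolerance in kcal/mol for "equal".
#' @return One of `"uniform"`, `"negative_catalysis"`,
#'   `"positive_catalysis"`, `"mixed"`.
#' @examples
#' un <- free_energy_profile(data.frame(
#'   name = c("S", "Ts", "P"), kind = c("ground", "barrier", "ground"),
#'   G = c(0, 18, -3)))
#' classify_binder(un, apply_uniform_shift(un, 3)) # "uniform"
#' @export
classify_binder <- function(unbound, bound, tol = 1e-6) {
  stopifnot(inherits(unbound, "free_energy_profile"),
            inherits(bound, "free_energy_profile"), tol >= 0)
  su <- unbound$states
  sb <- bound$states
  if (!identical(su$name, sb$name) || !identical(su$kind, sb$kind)) {
    stop("profiles must share the same ordered state names and kinds", call. = FALSE)
  }
  shifts <- su$G - sb$G # stabilization of each state by binding
  if (diff(range(shifts)) <= tol) return("uniform")
  dh <- barrier_heights(bound) - barrier_heights(unbound)
  raised  <- any(dh > tol)
  lowered <- any(dh < -tol)
  if (raised && !lowered) return("negative_catalysis")
  if (lowered && !raised) return("positive_catalysis")
  "mixed"
}
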