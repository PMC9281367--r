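# Observables: total product, lineage totals, product ratios, binder
# occupancy, the binding-strength invariance metric, and an independent
# rapid-equilibrium product-ratio approximation used for cross-checks.

#' Total product time series (single-route schemes)
#'
#' P_tot = free product + binder-bound product. Only defined for schemes
#' with a single product route; for two-product schemes use
#' [lineage_totals()].
#'
#' @param traj A `trajectory`.
#' @return Numeric time series, uM.
#' @export
total_product <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- traj$scheme$species
  if (any(sp$lineage == "P2")) {
    stop("scheme has two product routes; use lineage_totals()", call. = FALSE)
  }
  prod <- sp$name[sp$role %in% c("product", "downstream")]
  bd <- traj$scheme$bindings
  prod_cplx <- bd$complex[bd$ligand %in% prod]
  rowSums(traj$conc[, c(prod, prod_cplx), drop = FALSE])
}

#' Per-route product totals
#'
#' Sums every species carrying each lineage label: the P1 lineage is
#' free P1 + Q.P1 + the downstream product; the P2 lineage is P2 + Q.P2.
#' Both totals are monotonically non-decreasing (all conversions are
#' irreversible), and lineage totals plus unconverted substrate equal the
#' initial substrate at every time.
#'
#' @param traj A `trajectory` of a two-product or coupled scheme.
#' @return data.frame with columns `time_s`, `P1`, `P2`, `total`.
#' @export
lineage_totals <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- traj$scheme$species
  if (!any(sp$lineage == "P1")) {
    stop("scheme has no lineage labels; use total_product()", call. = FALSE)
  }
  p1 <- rowSums(traj$conc[, sp$name[sp$lineage == "P1"], drop = FALSE])
  p2 <- rowSums(traj$conc[, sp$name[sp$lineage == "P2"], drop = FALSE])
  data.frame(time_s = traj$time, P1 = p1, P2 = p2, total = p1 + p2)
}

#' Product ratio P1:P2
#'
#' Ratio of the P1-lineage total to the P2-lineage total, by default at
#' completion (requires a trajectory from [simulate_to_completion()] or one
#' that has effectively completed), or at the final reported time, or at an
#' arbitrary time by linear interpolation.
#'
#' @param traj A `trajectory` of a two-product or coupled scheme.
#' @param at `"completion"`, `"end"`, or a single numeric time in seconds.
#' @param threshold Completion threshold (fraction of initial substrate)
#'   used to verify completion when the trajectory carries no completion
#'   flag.
#' @return Dimensionless ratio; `Inf` with a warning if the P2 lineage is
#'   zero.
#' @export
product_ratio <- function(traj, at = "completion", threshold = 1e-4) {
  stopifnot(inherits(traj, "trajectory"))
  lt <- lineage_totals(traj)
  if (is.numeric(at)) {
    p1 <- stats::approx(lt$time_s, lt$P1, xout = at)$y
    p2 <- stats::approx(lt$time_s, lt$P2, xout = at)$y
  } else {
    at <- match.arg(at, c("completion", "end"))
    i <- nrow(lt)
    if (at == "completion") {
      if (isFALSE(traj$completed)) {
        warning("trajectory did not reach completion; using final time point")
      } else if (is.na(traj$completed)) {
        rem <- unconverted_substrate(traj)
        s0 <- sum(initial_state(traj$scheme)[
          traj$scheme$species$role == "substrate"])
        if (rem[i] >= threshold * s0) {
          warning(sprintf(
            "unconverted substrate still %.3g%% of S0 at final time; ratio is not a completion value",
            100 * rem[i] / s0))
        }
      }
    }
    p1 <- lt$P1[i]; p2 <- lt$P2[i]
  }
  if (p2 <= 0) {
    warning("P2 lineage is zero; returning Inf")
    return(Inf)
  }
  p1 / p2
}

#' Binder occupancy fractions over time
#'
#' Partition of total binder material between the free binder and each of
#' its complexes. Fractions sum to 1 at every time point.
#'
#' @param traj A `trajectory` of a scheme containing a binder.
#' @return data.frame: `time_s`, one column per binder-material species
#'   (free binder first), values as fractions of total binder.
#' @export
binder_state <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sp <- traj$scheme$species
  b <- sp$name[sp$role == "binder"]
  if (!length(b)) stop("scheme contains no binder", call. = FALSE)
  cols <- c(b, sp$name[sp$role == "complex"])
  m <- traj$conc[, cols, drop = FALSE]
  tot <- rowSums(m)
  out <- data.frame(time_s = traj$time, sweep(m, 1, tot, "/"),
                    check.names = FALSE)
  out
}

#' Invariance of total product with respect to binding strength
#'
#' Simulates a set of uniform-binder schemes that differ only in their
#' association constants, on a common time grid, and returns the largest
#' pairwise deviation of the P_tot curves relative to the initial substrate
#' concentration. For a genuinely uniform binder this is zero up to
#' integration error: every substrate molecule carries the same conversion
#' hazard whether bound or free.
#'
#' @param schemes List of >= 2 `kinetic_scheme`s identical except for the
#'   `K_assoc`/`k_off` of their binding steps (anything else differing is a
#'   structural error).
#' @param t_end,n_points,rel_tol,abs_tol,t_min Passed to
#'   [simulate_scheme()].
#' @return List with `metric` (max over time and scheme pairs of
#'   |delta P_tot| / S0) and `P_tot` (time x scheme matrix).
#' @export
invariance_metric <- function(schemes, t_end, n_points = 300,
                              rel_tol = 1e-10, abs_tol = 1e-14, t_min = 1e-2) {
  stopifnot(is.list(schemes), length(schemes) >= 2)
  ref <- schemes[[1]]
  for (s in schemes[-1]) {
    same <- identical(ref$species, s$species) &&
      identical(ref$conversions, s$conversions) &&
      identical(ref$bindings[c("binder", "ligand", "complex", "k_on")],
                s$bindings[c("binder", "ligand", "complex", "k_on")])
    if (!same) {
      stop("schemes must be identical except for binding constants", call. = FALSE)
    }
  }
  s0 <- sum(initial_state(ref)[ref$species$role == "substrate"])
  pt <- vapply(schemes, function(s) {
    total_product(simulate_scheme(s, t_end = t_end, n_points = n_points,
                                  rel_tol = rel_tol, abs_tol = abs_tol,
                                  t_min = t_min))
  }, numeric(n_points + 1L))
  metric <- 0
  for (i in seq_len(ncol(pt) - 1L)) {
    for (j in seq(i + 1L, ncol(pt))) {
      metric <- max(metric, max(abs(pt[, i] - pt[, j])) / s0)
    }
  }
  list(metric = metric, P_tot = pt)
}

#' Rapid-equilibrium product-ratio approximation
#'
#' Independent approximation to the completion product ratio of the
#' two-product scheme: binding is taken as instantaneously equilibrated, so
#' the state reduces to the three material totals (unconverted substrate,
#' P1 lineage, P2 lineage). Because the binder binds S, P1 and P2 with the
#' same K, total ligand is constant and the free fraction follows from one
#' quadratic in the free binder concentration. The reduced system is
#' integrated with a plain fixed-step RK4 scheme. Intended as a
#' cross-validation oracle for [product_ratio()], not as the primary
#' implementation.
#'
#' @param k1_non,k2_non,k1_bound,k2_bound Conversion rates, s^-1.
#' @param K Association constant, uM^-1.
#' @param S0,Q0 Initial concentrations, uM.
#' @param threshold Completion threshold (fraction of S0).
#' @param n_steps Fixed RK4 steps per substrate mean lifetime.
#' @return Dimensionless P1:P2 ratio at completion.
#' @export
qe_product_ratio <- function(k1_non, k2_non, k1_bound = k1_non,
                             k2_bound = k2_non, K, S0 = 1, Q0 = 1,
                             threshold = 1e-4, n_steps = 200) {
  stopifnot(k1_non >= 0, k2_non >= 0, k1_bound >= 0, k2_bound >= 0,
            K > 0, S0 > 0, Q0 >= 0)
  free_frac <- function() {
    # free binder from Q0 = Qf (1 + K * L / (1 + K Qf)), L = S0 (constant)
    b <- 1 + K * (S0 - Q0)
    qf <- (-b + sqrt(b * b + 4 * K * Q0)) / (2 * K)
    1 / (1 + K * qf)
  }
  f <- free_frac() # constant in time: total ligand never changes
  h1 <- k1_non * f + k1_bound * (1 - f)
  h2 <- k2_non * f + k2_bound * (1 - f)
  deriv <- function(y) {
    c(-(h1 + h2) * y[1], h1 * y[1], h2 * y[1])
  }
  htot <- h1 + h2
  if (htot <= 0) stop("no conversion route has a positive rate", call. = FALSE)
  dt <- 1 / (htot * n_steps)
  y <- c(S0, 0, 0)
  t_max <- 2 * log(1 / threshold) / htot
  nmax <- ceiling(t_max / dt)
  for (i in seq_len(nmax)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (y[1] < threshold * S0) break
  }
  y[2] / y[3]
}

#' Fraction of conversion flux carried by the free-substrate pool
#'
#' Trapezoidal estimate of the total material converted out of free
#' (unbound) substrate, as a fraction of initial substrate. In a tight,
#' fast-equilibrating binding regime this leakage is small and the bound
#' rates control the outcome.
#'
#' @param traj A `trajectory`.
#' @return Dimensionless fraction in [0, 1].
#' @export
free_conversion_fraction <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sch <- traj$scheme
  sub <- sch$species$name[sch$species$role == "substrate"]
  ks <- sum(sch$conversions$k[sch$conversions$from %in% sub])
  s_free <- rowSums(traj$conc[, sub, drop = FALSE])
  s0 <- sum(initial_state(sch)[sch$species$role == "substrate"])
  tt <- traj$time
  integral <- sum(diff(tt) * (s_free[-1] + s_free[-length(s_free)]) / 2)
  ks * integral / s0
}
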