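# Mass-action compilation and stiff ODE integration of kinetic schemes.
# The rate constants in one scheme can span nine orders of magnitude
# (diffusion-limited k_off ~1e3 s^-1 down to conversions ~1e-5 s^-1), so
# integration uses deSolve's stiff-capable lsoda with tight tolerances and
# reports on a logarithmically spaced time grid.

# Precompile index vectors so the RHS closure does no name lookups per call.
compile_rhs <- function(scheme) {
  sp <- scheme$species$name
  bd <- scheme$bindings
  cv <- scheme$conversions
  bi <- match(bd$binder, sp); li <- match(bd$ligand, sp); ci <- match(bd$complex, sp)
  kon <- bd$k_on; koff <- bd$k_off
  fi <- match(cv$from, sp); ti <- match(cv$to, sp); kc <- cv$k
  n <- length(sp)
  function(t, y, parms) {
    dy <- numeric(n)
    if (length(kon)) {
      v <- kon * y[bi] * y[li] - koff * y[ci] # net association flux, uM/s
      for (j in seq_along(v)) {
        dy[bi[j]] <- dy[bi[j]] - v[j]
        dy[li[j]] <- dy[li[j]] - v[j]
        dy[ci[j]] <- dy[ci[j]] + v[j]
      }
    }
    if (length(kc)) {
      w <- kc * y[fi]
      for (j in seq_along(w)) {
        dy[fi[j]] <- dy[fi[j]] - w[j]
        dy[ti[j]] <- dy[ti[j]] + w[j]
      }
    }
    list(dy)
  }
}

#' Mass-action derivative of a scheme at a given state
#'
#' Each binding step contributes +/- (k_on [binder][ligand] - k_off
#' [complex]); each conversion contributes +/- k [reactant]. Derivatives sum
#' to zero over every conservation group.
#'
#' @param scheme A `kinetic_scheme`.
#' @param state Numeric concentration vector (uM), in species order.
#' @return Named numeric derivative vector (uM/s).
#' @export
mass_action_rhs <- function(scheme, state) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            is.numeric(state), length(state) == nrow(scheme$species))
  rhs <- compile_rhs(scheme)
  stats::setNames(rhs(0, as.numeric(state), NULL)[[1]], scheme$species$name)
}

#' Simulate a kinetic scheme
#'
#' Integrates the mass-action ODE system with a stiff-capable adaptive
#' method (lsoda) and samples the solution on a logarithmically spaced time
#' grid, which resolves both the fast binding equilibration and the slow
#' conversions in one trajectory.
#'
#' @param scheme A `kinetic_scheme`.
#' @param t_end Final time, s (> 0).
#' @param n_points Number of reporting points (besides t = 0).
#' @param rel_tol,abs_tol Integrator tolerances (relative; absolute in uM).
#' @param t_min First positive reporting time, s.
#' @param times Optional explicit reporting times (must start at 0 and be
#'   strictly increasing); overrides `t_end`/`n_points`/`t_min`.
#' @return A `trajectory`: list with `time` (s), `conc` (time x species
#'   matrix, uM; tiny negative values clamped to 0 on output) and `scheme`.
#' @examples
#' traj <- simulate_scheme(uniform_binder_scheme(), t_end = 1e4)
#' head(as.data.frame(traj))
#' @export
simulate_scheme <- function(scheme, t_end, n_points = 400,
                            rel_tol = 1e-8, abs_tol = 1e-12, t_min = 1e-2,
                            times = NULL) {
  if (is.null(times)) {
    stopifnot(inherits(scheme, "kinetic_scheme"), t_end > 0, n_points >= 2)
    times <- time_grid(t_end, n_points, t_min)
  } else {
    stopifnot(inherits(scheme, "kinetic_scheme"), times[1] == 0,
              all(diff(times) > 0))
  }
  rhs <- compile_rhs(scheme)
  y0 <- initial_state(scheme)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol,
                      maxsteps = 50000)
  if (nrow(out) < length(times)) {
    stop(sprintf("integration failed at t = %g s (step-size collapse)",
                 out[nrow(out), 1]), call. = FALSE)
  }
  conc <- out[, -1, drop = FALSE]
  worst <- min(conc)
  if (worst < -1e-9) {
    warning(sprintf("concentration undershoot below numerical floor: %.3g uM", worst))
  }
  conc[conc < 0] <- 0
  new_trajectory(times, conc, scheme)
}

time_grid <- function(t_end, n_points, t_min) {
  if (t_end <= t_min) return(seq(0, t_end, length.out = n_points + 1L))
  c(0, 10^seq(log10(t_min), log10(t_end), length.out = n_points))
}

new_trajectory <- function(time, conc, scheme, completed = NA,
                           completion_time = NA_real_) {
  colnames(conc) <- scheme$species$name
  structure(list(time = time, conc = conc, scheme = scheme,
                 completed = completed, completion_time = completion_time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over [0, %g] s, %d species\n",
              length(x$time), max(x$time), ncol(x$conc)))
  if (!is.na(x$completed)) {
    cat(if (isTRUE(x$completed))
      sprintf("  reaction complete at t = %g s\n", x$completion_time)
      else "  reaction did NOT reach completion (time cap hit)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$time, x$conc, check.names = FALSE)
}

#' @export
plot.trajectory <- function(x, log = "x", ...) {
  tt <- x$time
  keep <- tt > 0
  graphics::matplot(tt[keep], x$conc[keep, , drop = FALSE], type = "l",
                    log = log, xlab = "time (s)",
                    ylab = "concentration (uM)", ...)
  graphics::legend("topleft", legend = colnames(x$conc), lty = seq_len(ncol(x$conc)),
                   col = seq_len(ncol(x$conc)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Total unconverted substrate of a trajectory
#'
#' Free substrate plus substrate sequestered in binder complexes
#' (identified as complexes whose ligand has the substrate role).
#'
#' @param traj A `trajectory`.
#' @return Numeric time series, uM.
#' @export
unconverted_substrate <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sch <- traj$scheme
  sub <- sch$species$name[sch$species$role == "substrate"]
  bd <- sch$bindings
  sub_cplx <- bd$complex[bd$ligand %in% sub]
  rowSums(traj$conc[, c(sub, sub_cplx), drop = FALSE])
}

#' Simulate until the substrate pool is exhausted
#'
#' Integrates until total unconverted substrate (free + bound) falls below
#' `threshold` times its initial amount ("completion"), extending the time
#' horizon geometrically as needed up to `t_cap`.
#'
#' @param scheme A `kinetic_scheme`.
#' @param threshold Completion threshold as a fraction of initial substrate
#'   (0 < threshold < 1).
#' @param t_cap Hard time cap, s.
#' @param n_points,rel_tol,abs_tol,t_min Passed to [simulate_scheme()].
#' @return A `trajectory` with `completed` (logical) and `completion_time`
#'   (first reported time below threshold; NA if the cap was reached first,
#'   in which case a warning is raised and the partial trajectory returned).
#' @examples
#' traj <- simulate_to_completion(uniform_binder_scheme(k = 1e-3))
#' traj$completion_time # ~ log(1e4)/1e-3 s
#' @export
simulate_to_completion <- function(scheme, threshold = 1e-4, t_cap = 1e12,
                                   n_points = 400, rel_tol = 1e-8,
                                   abs_tol = 1e-12, t_min = 1e-2) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            threshold > 0, threshold < 1, t_cap > 0)
  h <- substrate_hazards(scheme)
  t_guess <- if (any(h > 0)) 2 * log(1 / threshold) / min(h[h > 0]) else t_cap
  t_guess <- min(t_guess, t_cap)
  s0 <- sum(initial_state(scheme)[c(which(scheme$species$role == "substrate"))])
  repeat {
    traj <- simulate_scheme(scheme, t_end = t_guess, n_points = n_points,
                            rel_tol = rel_tol, abs_tol = abs_tol, t_min = t_min)
    rem <- unconverted_substrate(traj)
    hit <- which(rem < threshold * s0)
    if (length(hit)) {
      traj$completed <- TRUE
      traj$completion_time <- traj$time[hit[1]]
      return(traj)
    }
    if (t_guess >= t_cap) {
      warning("time cap reached before completion; returning partial trajectory")
      traj$completed <- FALSE
      return(traj)
    }
    t_guess <- min(t_guess * 10, t_cap)
  }
}

# Total conversion hazard out of each substrate pool (free and bound).
substrate_hazards <- function(scheme) {
  sub <- scheme$species$name[scheme$species$role == "substrate"]
  bd <- scheme$bindings
  pools <- c(sub, bd$complex[bd$ligand %in% sub])
  vapply(pools, function(p) sum(scheme$conversions$k[scheme$conversions$from == p]),
         numeric(1))
}

#' Maximum conservation-group drift of a trajectory
#'
#' Largest relative deviation of the binder-material and substrate-material
#' totals from their initial values, over all reported times.
#'
#' @param traj A `trajectory`.
#' @return Named numeric vector (`binder`, `substrate`); NA for an empty
#'   group.
#' @export
conservation_drift <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  grps <- conservation_groups(traj$scheme)
  vapply(grps, function(g) {
    if (!length(g)) return(NA_real_)
    tot <- rowSums(traj$conc[, g, drop = FALSE])
    if (tot[1] == 0) return(max(abs(tot)))
    max(abs(tot - tot[1]) / tot[1])
  }, numeric(1))
}
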