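# Independent oracles for the ODE engine. Deliberately naive: the
# derivative is assembled by name-indexed loops straight from the scheme
# tables, and the integrator is a plain fixed-step classical RK4 -- no code
# shared with the package's compiled RHS or adaptive solver.

oracle_deriv <- function(scheme, y) {
  dy <- stats::setNames(numeric(length(y)), names(y))
  bd <- scheme$bindings
  if (nrow(bd)) {
    for (i in seq_len(nrow(bd))) {
      b <- bd$binder[i]; l <- bd$ligand[i]; cx <- bd$complex[i]
      v <- bd$k_on[i] * y[[b]] * y[[l]] - bd$k_off[i] * y[[cx]]
      dy[[b]] <- dy[[b]] - v
      dy[[l]] <- dy[[l]] - v
      dy[[cx]] <- dy[[cx]] + v
    }
  }
  cv <- scheme$conversions
  if (nrow(cv)) {
    for (i in seq_len(nrow(cv))) {
      w <- cv$k[i] * y[[cv$from[i]]]
      dy[[cv$from[i]]] <- dy[[cv$from[i]]] - w
      dy[[cv$to[i]]] <- dy[[cv$to[i]]] + w
    }
  }
  dy
}

# Fixed-step RK4 from t = 0, recording every `record_every` steps.
# Returns list(time, conc) with the same layout as a trajectory.
oracle_rk4 <- function(scheme, dt, n_steps, record_every = 10L) {
  y <- initial_state(scheme)
  ntake <- floor(n_steps / record_every)
  times <- numeric(ntake + 1L)
  conc <- matrix(NA_real_, ntake + 1L, length(y),
                 dimnames = list(NULL, names(y)))
  conc[1L, ] <- y
  r <- 1L
  for (s in seq_len(n_steps)) {
    k1 <- oracle_deriv(scheme, y)
    k2 <- oracle_deriv(scheme, y + dt / 2 * k1)
    k3 <- oracle_deriv(scheme, y + dt / 2 * k2)
    k4 <- oracle_deriv(scheme, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% record_every == 0L) {
      r <- r + 1L
      times[r] <- s * dt
      conc[r, ] <- y
    }
  }
  list(time = times[seq_len(r)], conc = conc[seq_len(r), , drop = FALSE])
}

# Fastest first-order timescale in a scheme (for choosing the oracle step).
oracle_fastest_rate <- function(scheme) {
  conc_scale <- sum(initial_state(scheme))
  max(scheme$conversions$k,
      scheme$bindings$k_off,
      scheme$bindings$k_on * conc_scale)
}

# Compare the adaptive engine with the RK4 oracle over a truncated window.
# Returns the max relative deviation over all species and recorded times.
oracle_disagreement <- function(scheme, n_steps = 4000L, record_every = 40L) {
  dt <- 1e-3 / oracle_fastest_rate(scheme)
  ref <- oracle_rk4(scheme, dt, n_steps, record_every)
  traj <- simulate_scheme(scheme, rel_tol = 1e-10, abs_tol = 1e-14,
                          times = ref$time)
  floor_uM <- 1e-9 * sum(initial_state(scheme))
  max(abs(traj$conc - ref$conc) / pmax(abs(ref$conc), floor_uM))
}
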