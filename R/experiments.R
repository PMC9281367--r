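# End-to-end analysis pipelines: binding-strength invariance of an
# uncatalyzed conversion, two-product partitioning scenarios, the coupled
# downstream pull, and the product-ratio surface over binder excess and
# negative-catalysis fold. Each run is deterministic (no randomness
# anywhere in the engine).

#' Binding-strength invariance of total product formation
#'
#' Runs the uniform-binder scheme at several association constants and
#' verifies the hallmark of a non-catalytic uniform binder: the P_tot curve
#' is identical for every binding strength (and matches the closed form
#' S0 (1 - exp(-k t))), while the partition of product between free P and
#' bound U.P shifts dramatically with K.
#'
#' @param K_list Association constants to compare, uM^-1.
#' @param k Conversion rate constant, s^-1.
#' @param S0,U0 Initial concentrations, uM.
#' @param k_on Association on-rate, uM^-1 s^-1.
#' @param t_end,n_points Reporting grid (log-spaced).
#' @return List: `curves` (long data.frame with `time_s`, `K`, `P_tot`,
#'   `P_free`, `P_bound`), `metric` (max pairwise |delta P_tot| / S0),
#'   `closed_form_err` (max |P_tot - S0 (1 - exp(-k t))| / S0).
#' @export
run_binding_invariance <- function(K_list = c(1e-4, 1e-2, 1), k = 1e-3,
                                   S0 = 1, U0 = 1, k_on = KTRAP_DEFAULT_KON,
                                   t_end = 2e4, n_points = 300) {
  schemes <- lapply(K_list, function(K) {
    uniform_binder_scheme(k = k, K = K, k_on = k_on, S0 = S0, U0 = U0)
  })
  curves <- NULL
  cf_err <- 0
  for (i in seq_along(K_list)) {
    traj <- simulate_scheme(schemes[[i]], t_end = t_end, n_points = n_points,
                            rel_tol = 1e-10, abs_tol = 1e-14)
    pt <- total_product(traj)
    cf <- S0 * (1 - exp(-k * traj$time))
    cf_err <- max(cf_err, max(abs(pt - cf)) / S0)
    curves <- rbind(curves, data.frame(
      time_s = traj$time, K = K_list[i], P_tot = pt,
      P_free = traj$conc[, "P"], P_bound = traj$conc[, "U.P"]))
  }
  inv <- if (length(schemes) >= 2) {
    invariance_metric(schemes, t_end = t_end, n_points = n_points)$metric
  } else 0
  list(curves = curves, metric = inv, closed_form_err = cf_err)
}

#' Two-product partitioning scenarios
#'
#' Builds and runs the three canonical two-product scenarios: a uniform
#' binder (ratio stays at the solution value k1/k2), a 10-fold negative
#' catalyst of the S -> P2 route, and a 100-fold one. The `regime` argument
#' selects the binding strength: `"default"` uses K = 1e4 uM^-1 and
#' S0 = Q0 = 1 uM; `"tight"` raises K (1e6 uM^-1 for the 10-fold case,
#' 1e8 uM^-1 for the 100-fold case) so that under 2% of the conversion
#' flux leaks through the free-substrate pool and the bound rates control
#' the outcome.
#'
#' @param variant `"uniform"`, `"nc10"` or `"nc100"`.
#' @param regime `"tight"` or `"default"`.
#' @param k1,k2_non Free-solution rates, s^-1.
#' @param S0,Q0 Initial concentrations, uM.
#' @param k_on Association on-rate, uM^-1 s^-1.
#' @return List: `ratio` (completion P1:P2), `free_leak` (fraction of
#'   substrate converted in the free pool), `trajectory`, `params`.
#' @export
run_two_product <- function(variant = c("uniform", "nc10", "nc100"),
                            regime = c("tight", "default"),
                            k1 = 1e-3, k2_non = 1e-2, S0 = 1, Q0 = 1,
                            k_on = KTRAP_DEFAULT_KON) {
  variant <- match.arg(variant)
  regime <- match.arg(regime)
  k2_bound <- switch(variant, uniform = k2_non, nc10 = k2_non / 10,
                     nc100 = k2_non / 100)
  K <- if (regime == "default") 1e4 else
    switch(variant, uniform = 1e4, nc10 = 1e6, nc100 = 1e8)
  sch <- two_product_scheme(k1_non = k1, k2_non = k2_non, k1_bound = k1,
                            k2_bound = k2_bound, K = K, k_on = k_on,
                            S0 = S0, Q0 = Q0)
  traj <- simulate_to_completion(sch, rel_tol = 1e-10, abs_tol = 1e-14,
                                 t_min = 1e-4)
  list(ratio = product_ratio(traj),
       free_leak = free_conversion_fraction(traj),
       trajectory = traj,
       params = list(variant = variant, regime = regime, k1 = k1,
                     k2_non = k2_non, k2_bound = k2_bound, K = K,
                     k_on = k_on, S0 = S0, Q0 = Q0))
}

#' Coupled downstream reaction: trapping and release
#'
#' Runs the coupled scheme (1000-fold negative catalysis of the P2 route,
#' downstream pull k_f on free P1) over a short window, in which nearly all
#' substrate is converted and held as Q.P1, and a long window, in which the
#' downstream reaction drains the trap, Pstar dominates and the binder
#' returns to its free state.
#'
#' @param k1,k2_non,k2_bound,K,k_on,S0,Q0,k_f Scheme parameters (defaults:
#'   K = 1e4 uM^-1, k2_bound = 1e-5 s^-1 vs k2_non = 1e-2 s^-1,
#'   k_f = 0.1 s^-1).
#' @param t_short,t_long Window lengths, s (defaults 6000 s ~ 100 min, and
#'   3e6 s).
#' @return List: `short`, `long` (trajectories), `summary` (dominant
#'   product species in the short window, final free-binder fraction, final
#'   Pstar, final P2-lineage total).
#' @export
run_coupled <- function(k1 = 1e-3, k2_non = 1e-2, k2_bound = 1e-5,
                        K = 1e4, k_on = KTRAP_DEFAULT_KON, S0 = 1, Q0 = 1,
                        k_f = 0.1, t_short = 6000, t_long = 3e6) {
  sch <- coupled_scheme(k1_non = k1, k2_non = k2_non, k1_bound = k1,
                        k2_bound = k2_bound, K = K, k_on = k_on,
                        S0 = S0, Q0 = Q0, k_f = k_f)
  short <- simulate_scheme(sch, t_end = t_short, n_points = 300, t_min = 1e-3)
  long <- simulate_scheme(sch, t_end = t_long, n_points = 400, t_min = 1e-3)
  prod_cols <- c("P1", "P2", "Q.P1", "Q.P2", "Pstar")
  end_short <- short$conc[nrow(short$conc), prod_cols]
  bs <- binder_state(long)
  lt <- lineage_totals(long)
  nlast <- nrow(long$conc)
  list(short = short, long = long,
       summary = list(
         dominant_product_short = names(end_short)[which.max(end_short)],
         free_binder_final = bs$Q[nrow(bs)],
         Pstar_final = long$conc[nlast, "Pstar"],
         P2_lineage_final = lt$P2[nlast]))
}

#' Product-ratio surface over binder excess and negative-catalysis fold
#'
#' Completion P1:P2 ratio on a grid of Q0/S0 ratios and nc_fold values.
#' Both axes act monotonically: more binder sequesters more substrate, and
#' stronger negative catalysis slows the bound route to P2 further.
#'
#' @param q_over_s Binder:substrate ratios (grid rows).
#' @param nc_fold Negative-catalysis folds (grid columns).
#' @param k1,k2_non Free-solution rates, s^-1.
#' @param K Association constant, uM^-1.
#' @param k_on Association on-rate, uM^-1 s^-1.
#' @param S0 Substrate concentration, uM.
#' @return An object of class `ratio_grid`: list with `grid` (matrix,
#'   rownames Q0/S0, colnames nc_fold), `monotone_rows`, `monotone_cols`
#'   (logical).
#' @export
run_ratio_grid <- function(q_over_s = c(0.1, 0.3, 1, 3, 10),
                           nc_fold = c(1, 10, 100, 1000, 10000),
                           k1 = 1e-3, k2_non = 1e-2, K = 1e6,
                           k_on = KTRAP_DEFAULT_KON, S0 = 1) {
  grid <- matrix(NA_real_, length(q_over_s), length(nc_fold),
                 dimnames = list(Q0_over_S0 = as.character(q_over_s),
                                 nc_fold = as.character(nc_fold)))
  for (i in seq_along(q_over_s)) {
    for (j in seq_along(nc_fold)) {
      sch <- two_product_scheme(k1_non = k1, k2_non = k2_non, k1_bound = k1,
                                k2_bound = k2_non / nc_fold[j], K = K,
                                k_on = k_on, S0 = S0, Q0 = q_over_s[i] * S0)
      traj <- simulate_to_completion(sch, rel_tol = 1e-10, abs_tol = 1e-14,
                                     t_min = 1e-4)
      grid[i, j] <- product_ratio(traj)
    }
  }
  mono <- function(x) all(diff(x) >= -1e-9 * abs(x[-length(x)]))
  structure(list(grid = grid,
                 monotone_rows = all(apply(grid, 1, mono)),
                 monotone_cols = all(apply(grid, 2, mono)),
                 params = list(k1 = k1, k2_non = k2_non, K = K, k_on = k_on,
                               S0 = S0)),
            class = "ratio_grid")
}

#' @export
print.ratio_grid <- function(x, ...) {
  cat("<ratio_grid> completion P1:P2 over Q0/S0 (rows) x nc_fold (cols)\n")
  print(signif(x$grid, 4))
  cat(sprintf("monotone along rows: %s; along columns: %s\n",
              x$monotone_rows, x$monotone_cols))
  invisible(x)
}
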