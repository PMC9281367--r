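# Transition-state-theory conversions and binder classification.

test_that("ddg_from_fold reproduces the canonical fold correspondences", {
  ctx <- thermal_context() # 298 K
  # RT ln(10) at 298 K: 1.364 kcal/mol, quoted rounded as 1.4
  expect_equal(ddg_from_fold(10, ctx), 1.364, tolerance = 1e-3)
  expect_gte(ctx$rt * log(10), 1.36)
  expect_lte(ctx$rt * log(10), 1.37)
  expect_equal(round(ddg_from_fold(10, ctx), 1), 1.4)
  expect_equal(ddg_from_fold(1, ctx), 0)
  # RT ln(100) evaluated directly with R = 1.987e-3, T = 298
  expect_equal(ddg_from_fold(100, ctx), 1.987e-3 * 298 * log(100),
               tolerance = 1e-12)
  expect_equal(ddg_from_fold(100, ctx), 2.727, tolerance = 1e-3)
  expect_error(ddg_from_fold(0.5, ctx), "fold")
})

test_that("fold_from_ddg inverts ddg_from_fold and exposes the rounding gap", {
  ctx <- thermal_context()
  expect_equal(fold_from_ddg(0, ctx), 1)
  expect_equal(fold_from_ddg(1.364, ctx), 10, tolerance = 5e-3)
  # the quoted 1.4 kcal/mol is itself rounded: it implies 10.63-fold
  expect_equal(fold_from_ddg(1.4, ctx), 10.63, tolerance = 1e-3)
  expect_error(fold_from_ddg(-0.1, ctx), "ddg")
})

test_that("fold <-> ddg round trip is exact and monotone over six decades", {
  ctx <- thermal_context()
  folds <- 10^seq(0, 6, length.out = 61)
  back <- fold_from_ddg(ddg_from_fold(folds, ctx), ctx)
  expect_equal(back, folds, tolerance = 1e-12)
  expect_true(all(diff(ddg_from_fold(folds, ctx)) > 0))
  expect_true(all(diff(fold_from_ddg(seq(0, 5, by = 0.1), ctx)) > 0))
  # temperature enters through RT: hotter means larger fold per kcal
  hot <- thermal_context(temperature = 350)
  expect_lt(fold_from_ddg(1.4, hot), fold_from_ddg(1.4, ctx))
})

test_that("half-life conversions behave as an inverse pair", {
  expect_equal(rate_from_halflife(log(2)), 1)
  expect_equal(rate_from_halflife(693.15), 1e-3, tolerance = 1e-4)
  k <- 10^seq(-5, -1, length.out = 9)
  expect_equal(rate_from_halflife(halflife_from_rate(k)), k, tolerance = 1e-12)
  expect_error(rate_from_halflife(0))
  expect_error(rate_from_halflife(-1))
})

test_that("free-energy profiles enforce ladder structure", {
  expect_s3_class(profile_single(), "free_energy_profile")
  # barrier below a flanking ground state is rejected
  expect_error(profile_single(G = c(0, -1, -3)), "below a flanking")
  # non-alternating kinds are rejected
  expect_error(
    free_energy_profile(data.frame(name = c("a", "b"),
                                   kind = c("ground", "ground"),
                                   G = c(0, 1))),
    "alternate")
  expect_error(
    free_energy_profile(data.frame(name = c("a", "b"),
                                   kind = c("ground", "barrier"),
                                   G = c(0, 1))),
    "alternate")
})

test_that("barrier_rate follows exp(-dG/RT) and equal barriers give equal rates", {
  un <- profile_single()
  expect_equal(barrier_rate(un, "S", "S_ts")$value, exp(-18 / thermal_context()$rt))
  # barrier == ground: rate equals the prefactor
  flat <- free_energy_profile(data.frame(
    name = c("S", "ts", "P"), kind = c("ground", "barrier", "ground"),
    G = c(5, 5, 0)))
  expect_equal(barrier_rate(flat, "S", "ts", prefactor = 3)$value, 3)
  # uniform stabilization leaves the rate unchanged
  bo <- apply_uniform_shift(un, 4)
  expect_identical(barrier_rate(bo, "S", "S_ts")$value,
                   barrier_rate(un, "S", "S_ts")$value)
  # raising the bound barrier by RT ln(10) slows the bound branch 10-fold
  raised <- shift_states(un, "S_ts", ddg_from_fold(10))
  expect_equal(barrier_rate(un, "S", "S_ts")$value /
                 barrier_rate(raised, "S", "S_ts")$value,
               10, tolerance = 1e-10)
  expect_error(barrier_rate(un, "S", "nope"), "unknown state")
})

test_that("uniform shift leaves every barrier height bit-identical", {
  for (shift in c(0, 2, -1.5, 7.25)) {
    p <- profile_two_route()
    q <- apply_uniform_shift(p, shift)
    expect_identical(barrier_heights(q), barrier_heights(p))
    if (shift == 0) expect_equal(q$states, p$states)
  }
})

test_that("classify_binder distinguishes uniform, negative and positive catalysis", {
  un <- profile_two_route()
  expect_identical(classify_binder(un, apply_uniform_shift(un, 3)), "uniform")
  expect_identical(classify_binder(un, un), "uniform")
  # relative destabilization of the route-2 transition state
  nc <- shift_states(apply_uniform_shift(un, 3), "ts2", ddg_from_fold(10))
  expect_identical(classify_binder(un, nc), "negative_catalysis")
  # lowering one transition state only
  pc <- shift_states(apply_uniform_shift(un, 3), "ts1", -1)
  expect_identical(classify_binder(un, pc), "positive_catalysis")
  # one route slowed, the other sped up
  mx <- shift_states(shift_states(apply_uniform_shift(un, 3), "ts1", -1),
                     "ts2", 1)
  expect_identical(classify_binder(un, mx), "mixed")
  # unequal ground-state stabilization with untouched barriers: not uniform,
  # but no barrier changed either
  gs <- shift_states(apply_uniform_shift(un, 3), c("P1", "ts1"), -0.5)
  expect_identical(classify_binder(un, gs), "mixed")
  bad <- free_energy_profile(data.frame(name = "X", kind = "ground", G = 0))
  expect_error(classify_binder(un, bad), "share")
})
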