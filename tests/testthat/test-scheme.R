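# Scheme data model, builders, validation and serialization.

test_that("uniform binder scheme has the expected structure", {
  sch <- uniform_binder_scheme(k = 1e-3, K = 1e-4, k_on = 1, S0 = 1, U0 = 1)
  expect_setequal(species_names(sch), c("S", "P", "U", "U.S", "U.P"))
  expect_true(sch$metadata$is_uniform)
  # k_off derived from K and k_on
  expect_equal(sch$bindings$k_off, c(1e4, 1e4))
  expect_equal(sch$bindings$k_off * sch$bindings$K_assoc, sch$bindings$k_on,
               tolerance = 1e-13)
  # bound and free conversion share the rate constant
  expect_equal(unique(sch$conversions$k), 1e-3)
  # U0 = 0 degenerates to the pure solution reaction
  deg <- uniform_binder_scheme(U0 = 0)
  expect_equal(initial_state(deg)[["U"]], 0)
  expect_length(validate_scheme(deg), 0)
})

test_that("two-product builder records uniformity and the nc fold", {
  uni <- two_product_scheme(k1_non = 1e-3, k2_non = 1e-2)
  expect_true(uni$metadata$is_uniform)
  expect_equal(uni$metadata$nc_fold, 1)
  nc10 <- two_product_scheme(k2_bound = 1e-3)
  expect_false(nc10$metadata$is_uniform)
  expect_equal(nc10$metadata$nc_fold, 10)
  nc100 <- two_product_scheme(k2_bound = 1e-4)
  expect_equal(nc100$metadata$nc_fold, 100)
  # any strict reduction of the bound route-2 rate flags negative catalysis
  eps <- two_product_scheme(k2_bound = 1e-2 * 0.99)
  expect_false(eps$metadata$is_uniform)
  expect_gt(eps$metadata$nc_fold, 1)
  # dead bound route: +Inf sentinel, not a division error
  frozen <- two_product_scheme(k2_bound = 0)
  expect_identical(frozen$metadata$nc_fold, Inf)
})

test_that("coupled builder adds the downstream pull and nothing else", {
  sch <- coupled_scheme(k2_bound = 1e-5, K = 1e4, k_f = 0.1)
  expect_length(species_names(sch), 8)
  expect_setequal(species_names(sch),
                  c("S", "P1", "P2", "Q", "Q.S", "Q.P1", "Q.P2", "Pstar"))
  # Pstar carries the P1 lineage and does not bind Q
  sp <- sch$species
  expect_identical(sp$lineage[sp$name == "Pstar"], "P1")
  expect_false("Pstar" %in% sch$bindings$ligand)
  # k_f = 0 reduces exactly to the two-product scheme's steps
  base <- two_product_scheme(k2_bound = 1e-5, K = 1e4)
  z <- coupled_scheme(k2_bound = 1e-5, K = 1e4, k_f = 0)
  expect_identical(z$bindings, base$bindings)
  expect_identical(z$conversions$k[1:4], base$conversions$k)
  expect_identical(z$conversions$k[5], 0)
})

test_that("conservation groups partition binder and substrate material", {
  sch <- coupled_scheme()
  g <- conservation_groups(sch)
  expect_setequal(g$binder, c("Q", "Q.S", "Q.P1", "Q.P2"))
  expect_setequal(g$substrate,
                  c("S", "P1", "P2", "Pstar", "Q.S", "Q.P1", "Q.P2"))
  # complexes appear in both groups; every species is covered
  expect_setequal(intersect(g$binder, g$substrate), c("Q.S", "Q.P1", "Q.P2"))
  expect_setequal(union(g$binder, g$substrate), species_names(sch))
})

test_that("builders are pure: same parameters give identical schemes", {
  a <- two_product_scheme(k2_bound = 1e-4, K = 1e6, S0 = 2, Q0 = 3)
  b <- two_product_scheme(k2_bound = 1e-4, K = 1e6, S0 = 2, Q0 = 3)
  expect_identical(a, b)
})

test_that("validate_scheme reports violations as data", {
  good <- two_product_scheme()
  expect_length(validate_scheme(good), 0)
  # complex without a binding step
  broken <- good
  broken$bindings <- broken$bindings[-1, ]
  v <- validate_scheme(broken)
  expect_length(v, 1)
  expect_match(v, "Q.S.*no binding step")
  # inconsistent k_off
  broken2 <- good
  broken2$bindings$k_off[1] <- broken2$bindings$k_off[1] * 2
  expect_match(validate_scheme(broken2), "k_off")
  # conversion crossing the free/bound boundary
  broken3 <- good
  broken3$conversions$to[1] <- "Q.P1"
  expect_match(validate_scheme(broken3), "crosses")
  # constructor refuses to build invalid schemes outright
  expect_error(
    kinetic_scheme(good$species, good$bindings[-1, ], good$conversions),
    "invalid kinetic scheme")
})

test_that("scheme serialization round-trips losslessly (JSON and YAML)", {
  cfg <- scenario_config(seed = 11, kind = "coupled")
  for (i in 1:3) {
    sch <- sample_scheme(cfg, i)
    fj <- withr::local_tempfile(fileext = ".json")
    write_scheme(sch, fj)
    back <- read_scheme(fj)
    expect_equal(back$species, sch$species, tolerance = 1e-12)
    expect_equal(back$bindings, sch$bindings, tolerance = 1e-12)
    expect_equal(back$conversions, sch$conversions, tolerance = 1e-12)
    expect_equal(back$metadata[order(names(back$metadata))],
                 sch$metadata[order(names(sch$metadata))],
                 tolerance = 1e-12)
    fy <- withr::local_tempfile(fileext = ".yaml")
    write_scheme(sch, fy)
    # YAML carries ~12 significant digits; JSON is the exact dialect
    expect_equal(read_scheme(fy)$bindings, sch$bindings, tolerance = 1e-9)
  }
  # the shipped example config loads as a valid uniform-binder scheme
  ex <- system.file("extdata", "uniform_binder_example.yaml",
                    package = "kinetrap")
  sch <- read_scheme(ex)
  expect_true(sch$metadata$is_uniform)
  expect_equal(sch, uniform_binder_scheme(k = 1e-3, K = 1e-2),
               tolerance = 1e-12)
  # Inf nc_fold survives a round trip
  frozen <- two_product_scheme(k2_bound = 0)
  fj <- withr::local_tempfile(fileext = ".json")
  write_scheme(frozen, fj)
  expect_identical(read_scheme(fj)$metadata$nc_fold, Inf)
})
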