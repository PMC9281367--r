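# Kinetic-scheme data model and builders for the three model schemes:
# uniform binder on a single irreversible conversion, two-product kinetic
# partitioning with (optional) negative catalysis, and the coupled scheme
# with a downstream irreversible pull.
#
# Units are fixed package-wide: concentrations in uM, time in s, association
# constants in uM^-1, first-order rates in s^-1, on-rates in uM^-1 s^-1.

# Default association on-rate (uM^-1 s^-1). Diffusion-limited (~1e9 M^-1
# s^-1) so that binding genuinely equilibrates much faster than the
# 1e-5..1e-1 s^-1 conversions; at slow on-rates the second-order association
# tail at equimolar uM concentrations leaks several percent of substrate
# through the solution route before equilibrium is reached.
KTRAP_DEFAULT_KON <- 1000

#' Construct a kinetic scheme
#'
#' Low-level constructor; most users should call one of the builders
#' ([uniform_binder_scheme()], [two_product_scheme()], [coupled_scheme()]).
#'
#' @param species data.frame with columns `name`, `role` (one of
#'   `substrate`, `product`, `binder`, `complex`, `downstream`), `lineage`
#'   (`"P1"`, `"P2"` or `"none"`), `conc0` (initial concentration, uM >= 0).
#' @param bindings data.frame with columns `binder`, `ligand`, `complex`,
#'   `K_assoc` (uM^-1), `k_on` (uM^-1 s^-1); `k_off` (s^-1) is derived as
#'   `k_on / K_assoc` if absent.
#' @param conversions data.frame with columns `from`, `to`, `k` (s^-1).
#'   All conversions are irreversible.
#' @param metadata list; recognized entries: `kind`, `is_uniform`, `nc_fold`.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, bindings, conversions, metadata = list()) {
  stopifnot(is.data.frame(species), is.data.frame(conversions), is.list(metadata))
  species <- data.frame(name = as.character(species$name),
                        role = as.character(species$role),
                        lineage = as.character(species$lineage),
                        conc0 = as.numeric(species$conc0),
                        stringsAsFactors = FALSE)
  if (is.null(bindings) || nrow(bindings) == 0L) {
    bindings <- data.frame(binder = character(), ligand = character(),
                           complex = character(), K_assoc = numeric(),
                           k_on = numeric(), k_off = numeric(),
                           stringsAsFactors = FALSE)
  } else {
    bindings <- data.frame(binder = as.character(bindings$binder),
                           ligand = as.character(bindings$ligand),
                           complex = as.character(bindings$complex),
                           K_assoc = as.numeric(bindings$K_assoc),
                           k_on = as.numeric(bindings$k_on),
                           k_off = if ("k_off" %in% names(bindings))
                             as.numeric(bindings$k_off)
                           else as.numeric(bindings$k_on) / as.numeric(bindings$K_assoc),
                           stringsAsFactors = FALSE)
  }
  conversions <- data.frame(from = as.character(conversions$from),
                            to = as.character(conversions$to),
                            k = as.numeric(conversions$k),
                            stringsAsFactors = FALSE)
  obj <- structure(list(species = species, bindings = bindings,
                        conversions = conversions, metadata = metadata),
                   class = "kinetic_scheme")
  viol <- validate_scheme(obj)
  if (length(viol)) {
    stop("invalid kinetic scheme:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  obj
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<kinetic_scheme> %s: %d species, %d binding steps, %d conversions\n",
              if (!is.null(md$kind)) md$kind else "custom",
              nrow(x$species), nrow(x$bindings), nrow(x$conversions)))
  if (!is.null(md$is_uniform)) {
    cat(sprintf("  uniform binder: %s", md$is_uniform))
    if (!is.null(md$nc_fold)) cat(sprintf("  (nc_fold = %g)", md$nc_fold))
    cat("\n")
  }
  invisible(x)
}

#' Species names of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Character vector in scheme order.
#' @export
species_names <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  scheme$species$name
}

#' Initial concentration vector of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Named numeric vector (uM), in species order.
#' @export
initial_state <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  stats::setNames(scheme$species$conc0, scheme$species$name)
}

#' Material-conservation groups of a scheme
#'
#' Binder material (free binder plus every complex) and substrate material
#' (substrate, products, downstream product, plus every complex) are each
#' conserved by mass action; complexes belong to both groups.
#'
#' @param scheme A `kinetic_scheme`.
#' @return Named list of character vectors: `binder`, `substrate`.
#' @export
conservation_groups <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  sp <- scheme$species
  list(binder = sp$name[sp$role %in% c("binder", "complex")],
       substrate = sp$name[sp$role %in% c("substrate", "product", "downstream", "complex")])
}

#' Uniform binder acting on a single irreversible conversion
#'
#' Substrate S converts irreversibly to product P with rate constant `k`. A
#' binder U binds S and P with the same association constant `K`; because the
#' binder is uniform (it stabilizes substrate, transition state and product
#' equally), the bound conversion U.S -> U.P proceeds at the same `k`. Every
#' substrate molecule then carries the same conversion hazard whether bound
#' or free, so total product formation is independent of `K`, `k_on` and
#' `U0`.
#'
#' @param k Conversion rate constant, s^-1.
#' @param K Association constant of U for S and P, uM^-1.
#' @param k_on Association on-rate, uM^-1 s^-1.
#' @param S0,U0 Initial substrate / binder concentrations, uM.
#' @return A `kinetic_scheme` with species S, P, U, U.S, U.P.
#' @examples
#' sch <- uniform_binder_scheme(k = 1e-3, K = 1e-2)
#' validate_scheme(sch) # character(0)
#' @export
uniform_binder_scheme <- function(k = 1e-3, K = 1e-2, k_on = KTRAP_DEFAULT_KON,
                                  S0 = 1, U0 = 1) {
  stopifnot(k > 0, K > 0, k_on > 0, S0 > 0, U0 >= 0)
  species <- data.frame(
    name = c("S", "P", "U", "U.S", "U.P"),
    role = c("substrate", "product", "binder", "complex", "complex"),
    lineage = c("none", "none", "none", "none", "none"),
    conc0 = c(S0, 0, U0, 0, 0),
    stringsAsFactors = FALSE)
  bindings <- data.frame(
    binder = c("U", "U"), ligand = c("S", "P"), complex = c("U.S", "U.P"),
    K_assoc = c(K, K), k_on = c(k_on, k_on), stringsAsFactors = FALSE)
  conversions <- data.frame(
    from = c("S", "U.S"), to = c("P", "U.P"), k = c(k, k),
    stringsAsFactors = FALSE)
  kinetic_scheme(species, bindings, conversions,
                 metadata = list(kind = "uniform_binder", is_uniform = TRUE,
                                 nc_fold = 1))
}

#' Two-product kinetic partitioning with an optional negative catalyst
#'
#' Substrate S can react along two routes: S -> P1 (rate `k1_non`) and
#' S -> P2 (rate `k2_non`, typically 10 x `k1_non`: the route favored in
#' solution). A binder Q binds S, P1 and P2 uniformly with association
#' constant `K`; the bound substrate converts at `k1_bound` and `k2_bound`.
#' With `k2_bound < k2_non` the binder performs negative catalysis on the
#' S -> P2 route -- its transition state is relatively destabilized inside
#' the complex -- and the product ratio tilts toward P1.
#'
#' @param k1_non,k2_non Free-solution conversion rates, s^-1.
#' @param k1_bound,k2_bound Conversion rates in the Q.S complex, s^-1
#'   (default: equal to the free rates, i.e. a uniform binder).
#' @param K Association constant for S, P1 and P2, uM^-1.
#' @param k_on Association on-rate, uM^-1 s^-1.
#' @param S0,Q0 Initial substrate / binder concentrations, uM.
#' @return A `kinetic_scheme` with species S, P1, P2, Q, Q.S, Q.P1, Q.P2.
#'   `metadata$nc_fold` records `k2_non / k2_bound` (Inf if `k2_bound` is 0).
#' @examples
#' sch <- two_product_scheme(k2_bound = 1e-3) # 10-fold negative catalysis
#' sch$metadata$nc_fold
#' @export
two_product_scheme <- function(k1_non = 1e-3, k2_non = 1e-2,
                               k1_bound = k1_non, k2_bound = k2_non,
                               K = 1e4, k_on = KTRAP_DEFAULT_KON,
                               S0 = 1, Q0 = 1) {
  stopifnot(k1_non >= 0, k2_non >= 0, k1_bound >= 0, k2_bound >= 0,
            K > 0, k_on > 0, S0 > 0, Q0 >= 0)
  species <- data.frame(
    name = c("S", "P1", "P2", "Q", "Q.S", "Q.P1", "Q.P2"),
    role = c("substrate", "product", "product", "binder",
             "complex", "complex", "complex"),
    lineage = c("none", "P1", "P2", "none", "none", "P1", "P2"),
    conc0 = c(S0, 0, 0, Q0, 0, 0, 0),
    stringsAsFactors = FALSE)
  bindings <- data.frame(
    binder = rep("Q", 3), ligand = c("S", "P1", "P2"),
    complex = c("Q.S", "Q.P1", "Q.P2"),
    K_assoc = rep(K, 3), k_on = rep(k_on, 3), stringsAsFactors = FALSE)
  conversions <- data.frame(
    from = c("S", "S", "Q.S", "Q.S"),
    to = c("P1", "P2", "Q.P1", "Q.P2"),
    k = c(k1_non, k2_non, k1_bound, k2_bound),
    stringsAsFactors = FALSE)
  is_uniform <- isTRUE(all.equal(k1_bound, k1_non)) &&
    isTRUE(all.equal(k2_bound, k2_non))
  nc_fold <- if (k2_bound == 0) Inf else k2_non / k2_bound
  kinetic_scheme(species, bindings, conversions,
                 metadata = list(kind = "two_product", is_uniform = is_uniform,
                                 nc_fold = nc_fold))
}

#' Two-product scheme coupled to a downstream irreversible reaction
#'
#' Extends [two_product_scheme()] with a final product Pstar: free P1 reacts
#' irreversibly onward (P1 -> Pstar, rate `k_f`), and Pstar does not bind Q.
#' The downstream pull drains the Q.P1 kinetic trap through dissociation,
#' returning Q to its free state for further rounds of turnover.
#'
#' @inheritParams two_product_scheme
#' @param k_f Downstream rate constant for free P1 -> Pstar, s^-1.
#' @return A `kinetic_scheme` with 8 species (adds Pstar, lineage P1).
#' @examples
#' sch <- coupled_scheme(k2_bound = 1e-5, K = 1e4, k_f = 0.1)
#' species_names(sch)
#' @export
coupled_scheme <- function(k1_non = 1e-3, k2_non = 1e-2,
                           k1_bound = k1_non, k2_bound = k2_non,
                           K = 1e4, k_on = KTRAP_DEFAULT_KON,
                           S0 = 1, Q0 = 1, k_f = 0.1) {
  stopifnot(k_f >= 0)
  base <- two_product_scheme(k1_non, k2_non, k1_bound, k2_bound,
                             K, k_on, S0, Q0)
  species <- rbind(base$species,
                   data.frame(name = "Pstar", role = "downstream",
                              lineage = "P1", conc0 = 0,
                              stringsAsFactors = FALSE))
  conversions <- rbind(base$conversions,
                       data.frame(from = "P1", to = "Pstar", k = k_f,
                                  stringsAsFactors = FALSE))
  md <- base$metadata
  md$kind <- "coupled"
  md$k_f <- k_f
  kinetic_scheme(species, base$bindings, conversions, metadata = md)
}

#' Validate a kinetic scheme
#'
#' Checks the structural and consistency invariants of the data model.
#' Violations are returned as data, not raised.
#'
#' @param scheme A `kinetic_scheme` (or a bare list with the same fields).
#' @return Character vector of violation messages; empty if the scheme is
#'   valid.
#' @export
validate_scheme <- function(scheme) {
  sp <- scheme$species
  bd <- scheme$bindings
  cv <- scheme$conversions
  v <- character()
  if (anyDuplicated(sp$name)) {
    v <- c(v, sprintf("duplicate species name(s): %s",
                      paste(unique(sp$name[duplicated(sp$name)]), collapse = ", ")))
  }
  ok_roles <- c("substrate", "product", "binder", "complex", "downstream")
  bad <- !sp$role %in% ok_roles
  if (any(bad)) v <- c(v, sprintf("species '%s': unknown role '%s'",
                                  sp$name[bad], sp$role[bad]))
  if (any(sp$conc0 < 0)) {
    v <- c(v, sprintf("species '%s': negative initial concentration",
                      sp$name[sp$conc0 < 0]))
  }
  if (!all(sp$lineage %in% c("P1", "P2", "none"))) {
    v <- c(v, "lineage labels must be 'P1', 'P2' or 'none'")
  }
  if (nrow(bd)) {
    for (i in seq_len(nrow(bd))) {
      for (col in c("binder", "ligand", "complex")) {
        if (!bd[[col]][i] %in% sp$name) {
          v <- c(v, sprintf("binding step %d: unknown %s '%s'", i, col, bd[[col]][i]))
        }
      }
      if (bd$K_assoc[i] <= 0) v <- c(v, sprintf("binding step %d: K_assoc must be > 0", i))
      if (bd$k_on[i] <= 0) v <- c(v, sprintf("binding step %d: k_on must be > 0", i))
      if (bd$K_assoc[i] > 0 && bd$k_on[i] > 0) {
        rel <- abs(bd$k_off[i] * bd$K_assoc[i] - bd$k_on[i]) / bd$k_on[i]
        if (!is.finite(rel) || rel > 1e-12) {
          v <- c(v, sprintf("binding step %d: k_off * K_assoc != k_on (relative error %.3g)",
                            i, rel))
        }
      }
    }
    if (anyDuplicated(bd$complex)) {
      v <- c(v, "each complex must be formed by exactly one binding step")
    }
  }
  # every complex species is produced by exactly one binding step
  cplx <- sp$name[sp$role == "complex"]
  orphan <- setdiff(cplx, bd$complex)
  if (length(orphan)) {
    v <- c(v, sprintf("complex '%s' has no binding step", orphan))
  }
  not_cplx <- bd$complex[!bd$complex %in% cplx]
  if (length(not_cplx)) {
    v <- c(v, sprintf("binding product '%s' is not a complex-role species", not_cplx))
  }
  if (nrow(cv)) {
    complex_binder <- stats::setNames(bd$binder, bd$complex)
    for (i in seq_len(nrow(cv))) {
      for (col in c("from", "to")) {
        if (!cv[[col]][i] %in% sp$name) {
          v <- c(v, sprintf("conversion %d: unknown species '%s'", i, cv[[col]][i]))
        }
      }
      if (cv$k[i] < 0) v <- c(v, sprintf("conversion %d: negative rate", i))
      from <- cv$from[i]; to <- cv$to[i]
      if (from %in% sp$name && to %in% sp$name) {
        role_to <- sp$role[match(to, sp$name)]
        if (role_to != "downstream") { # downstream step is exempt
          from_cplx <- from %in% cplx
          to_cplx <- to %in% cplx
          if (from_cplx != to_cplx) {
            v <- c(v, sprintf("conversion %d (%s -> %s): crosses the free/bound boundary",
                              i, from, to))
          } else if (from_cplx) {
            bf <- complex_binder[match(from, names(complex_binder))]
            bt <- complex_binder[match(to, names(complex_binder))]
            if (!is.na(bf) && !is.na(bt) && bf != bt) {
              v <- c(v, sprintf("conversion %d (%s -> %s): complexes of different binders",
                                i, from, to))
            }
          }
        }
      }
    }
  }
  # conservation-group coverage: every species in >= 1 group, complexes in both
  grp_b <- sp$role %in% c("binder", "complex")
  grp_s <- sp$role %in% c("substrate", "product", "downstream", "complex")
  uncovered <- sp$name[!(grp_b | grp_s)]
  if (length(uncovered)) {
    v <- c(v, sprintf("species '%s' belongs to no conservation group", uncovered))
  }
  v
}
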