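#' Multicomponent Sanchez-Lacombe mixture
#'
#' Combines pure-component characteristic parameters into a mixture under the
#' lattice-fluid mixing rules: close-packed volume fractions
#' phi_i = (w_i/rhostar_i) / sum_j (w_j/rhostar_j), harmonic mixing of the
#' close-packed density (1/rhostar = sum w_i/rhostar_i) and of the mer volume
#' (1/vstar = sum phi_i/vstar_i), and a quadratic volume-fraction rule for the
#' characteristic pressure with geometric-mean cross terms
#' pstar_ij = (1 - kij) sqrt(pstar_i pstar_j). The characteristic temperature
#' follows as Tstar = pstar / sum_i (phi_i pstar_i / Tstar_i).
#'
#' @param components List of [sl_params()] objects.
#' @param mass_fractions Numeric vector, nonnegative, summing to 1.
#' @param kij Symmetric binary-interaction matrix with zero diagonal, or a
#'   single number for a binary mixture. Defaults to all zeros.
#' @return An object of class `sl_mixture` holding the component set, the
#'   composition and the mixed characteristic parameters.
#' @examples
#' mix <- sl_mixture(list(sl_gas("CO2"), sl_polymer("PHBV8")), c(0.02, 0.98))
#' sl_mixture_density(mix, 308.15, 3)
#' @seealso [sl_mixture_density()], [sl_chemical_potential()]
#' @export
sl_mixture <- function(components, mass_fractions, kij = NULL) {
  if (!is.list(components) || !all(vapply(components, inherits, TRUE, "sl_params"))) {
    abort("`components` must be a list of sl_params objects.")
  }
  nc <- length(components)
  w <- as.numeric(mass_fractions)
  if (length(w) != nc || any(w < -1e-12)) {
    abort("`mass_fractions` must be nonnegative with one entry per component.")
  }
  if (abs(sum(w) - 1) > 1e-8) abort("`mass_fractions` must sum to 1.")
  w <- pmax(w, 0) / sum(pmax(w, 0))
  if (is.null(kij)) kij <- matrix(0, nc, nc)
  if (is.matrix(kij)) {
    if (!isTRUE(all.equal(kij, t(kij))) || any(diag(kij) != 0)) {
      abort("`kij` must be symmetric with zero diagonal.")
    }
  } else if (nc == 2L && length(kij) == 1L) {
    kij <- matrix(c(0, kij, kij, 0), 2L, 2L)
  } else {
    abort("`kij` must be a matrix (or one number for a binary mixture).")
  }
  structure(
    c(.mix_struct(components, w, kij), list(components = components, kij = kij)),
    class = "sl_mixture"
  )
}

# Mixing-rule engine shared by sl_mixture() and the sorption solvers.
# Returns the mixed characteristic parameters and the per-component
# quantities needed by the chemical-potential expression.
.mix_struct <- function(components, w, kij) {
  Ts <- vapply(components, `[[`, 0, "Tstar")
  ps <- vapply(components, `[[`, 0, "pstar")
  rs <- vapply(components, `[[`, 0, "rhostar")
  M <- vapply(components, `[[`, 0, "molar_mass")
  vstar_i <- .R_GAS * Ts / ps            # mer volume, cm^3 per mol of sites
  r0 <- M * ps / (.R_GAS * Ts * rs)      # pure chain size (Inf for polymers)
  vol <- w / rs                          # close-packed volume per g of mixture
  phi <- vol / sum(vol)
  vstar <- 1 / sum(phi / vstar_i)
  pmat <- sqrt(outer(ps, ps)) * (1 - kij)
  pstar <- c(phi %*% pmat %*% phi)
  Tstar <- pstar / sum(phi * ps / Ts)
  # mixture-lattice chain sizes r_i = r0_i vstar_i / vstar; polymers stay Inf
  ri <- r0 * vstar_i / vstar
  rinv_bar <- sum(ifelse(is.finite(ri), phi / ri, 0))
  list(
    w = w, phi = phi, vstar_i = vstar_i, r0 = r0, ri = ri,
    vstar = vstar, pstar = pstar, Tstar = Tstar,
    rhostar = 1 / sum(w / rs), rinv_bar = rinv_bar,
    p_cross = c(pmat %*% phi)            # P_i = sum_k phi_k pstar_ik
  )
}

#' @export
print.sl_mixture <- function(x, ...) {
  labs <- vapply(x$components, function(c) {
    if (is.na(c$species)) "?" else c$species
  }, "")
  cat(sprintf(
    "<sl_mixture> %s\n  w = (%s)\n  T* = %.4g K, p* = %.4g MPa, rho* = %.4g g/cm3\n",
    paste(labs, collapse = " + "),
    paste(sprintf("%.4g", x$w), collapse = ", "),
    x$Tstar, x$pstar, x$rhostar
  ))
  invisible(x)
}

# Reduced-density roots of the mixture EoS at (T, p).
.mix_roots <- function(mix, T, p) {
  .sl_roots(T / mix$Tstar, p / mix$pstar, mix$rinv_bar)
}

# Reduced density of the mixed phase; phase = "liquid" | "vapor" | "auto".
.mix_rhotilde <- function(mix, T, p, phase = "liquid") {
  roots <- .mix_roots(mix, T, p)
  if (length(roots) == 0L) {
    abort(sprintf(
      "No mixture equation-of-state root at T = %g K, p = %g MPa.", T, p
    ))
  }
  switch(phase,
    liquid = max(roots),
    vapor = min(roots),
    auto = roots[which.min(
      .sl_gibbs_per_site(roots, T / mix$Tstar, p / mix$pstar, mix$rinv_bar)
    )]
  )
}

#' Mass density of a Sanchez-Lacombe mixture
#'
#' Solves the mixture equation of state at the mixed characteristic
#' parameters and returns the mass density of the phase. A single-component
#' "mixture" reduces exactly to [sl_density()].
#'
#' @param mix An [sl_mixture()] object.
#' @param T Temperature, K.
#' @param p Pressure, MPa.
#' @param phase `"liquid"` (default, the polymer-rich convention),
#'   `"vapor"` or `"auto"` (Gibbs-minimal).
#' @return Mass density, g/cm^3.
#' @export
sl_mixture_density <- function(mix, T, p, phase = c("liquid", "vapor", "auto")) {
  stopifnot(inherits(mix, "sl_mixture"))
  phase <- match.arg(phase)
  .mix_rhotilde(mix, T, p, phase) * mix$rhostar
}

# Chemical potential mu_i/RT for every component at reduced density rt.
# Exact composition derivative of the lattice-fluid Gibbs energy under the
# mixing rules of .mix_struct(); for a pure fluid it collapses to
# r (-rhotilde/Ttilde + ptilde vtilde / Ttilde + (vtilde - 1) log(1 - rhotilde))
# + log(rhotilde). Polymers (r0 = Inf) get -Inf, which never enters the
# sorption equalities (the polymer is nonvolatile).
.mu_over_RT <- function(mix, rt, T, p) {
  RT <- .R_GAS * T
  base <- log(rt * mix$phi) + 1 - mix$ri * mix$rinv_bar
  chain <- mix$r0 * (
    mix$vstar_i * rt * (mix$pstar - 2 * mix$p_cross) / RT +
      mix$vstar_i * p / (rt * RT) +
      ((1 - rt) / rt) * log1p(-rt)
  )
  base + chain
}

#' Chemical potential of mixture components
#'
#' Returns the dimensionless chemical potential mu/RT of one or all
#' components of a Sanchez-Lacombe mixture at (T, p), evaluated at the
#' equilibrium reduced density of the requested phase. The expression is the
#' exact composition derivative of the lattice-fluid Gibbs energy under the
#' package's mixing rules; for a pure fluid it reduces to the classical
#' pure-component form. Polymer components (infinite chains) have no finite
#' per-mole potential and return `-Inf`.
#'
#' @param mix An [sl_mixture()] object.
#' @param T Temperature, K.
#' @param p Pressure, MPa.
#' @param component Integer index; `NULL` (default) returns all components.
#' @param phase Root selection as in [sl_mixture_density()].
#' @return mu/RT, a numeric vector.
#' @export
sl_chemical_potential <- function(mix, T, p, component = NULL,
                                  phase = c("liquid", "vapor", "auto")) {
  stopifnot(inherits(mix, "sl_mixture"))
  phase <- match.arg(phase)
  rt <- .mix_rhotilde(mix, T, p, phase)
  mu <- .mu_over_RT(mix, rt, T, p)
  if (is.null(component)) {
    return(mu)
  }
  if (!component %in% seq_along(mix$w)) {
    abort(sprintf("`component` must be in 1..%d.", length(mix$w)))
  }
  mu[[component]]
}
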