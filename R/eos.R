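#' Sanchez-Lacombe equation-of-state residual
#'
#' Evaluates the lattice-fluid equation of state in reduced variables,
#'
#'   F(rhotilde) = rhotilde^2 + ptilde +
#'                 Ttilde * (log(1 - rhotilde) + (1 - 1/r) * rhotilde),
#'
#' which is zero at an equilibrium reduced density. For the polymer limit
#' (`r = Inf`) the factor (1 - 1/r) degenerates to 1 analytically.
#'
#' @param rhotilde Reduced density, strictly inside (0, 1). Vectorised.
#' @param Ttilde Reduced temperature T/Tstar (> 0).
#' @param ptilde Reduced pressure p/pstar (>= 0).
#' @param r Chain size (lattice sites per molecule); `Inf` for a polymer.
#' @return The residual (dimensionless), same length as `rhotilde`.
#' @examples
#' p <- sl_polymer("PHBV0")
#' rho <- sl_density(p, 298.15, 0.1)
#' sl_eos_residual(rho / p$rhostar, 298.15 / p$Tstar, 0.1 / p$pstar, Inf)
#' @export
sl_eos_residual <- function(rhotilde, Ttilde, ptilde, r = Inf) {
  if (any(rhotilde <= 0 | rhotilde >= 1)) {
    abort("`rhotilde` must lie strictly inside (0, 1).")
  }
  if (Ttilde <= 0 || ptilde < 0) abort("`Ttilde` must be > 0 and `ptilde` >= 0.")
  rinv <- if (is.infinite(r)) 0 else 1 / r
  rhotilde^2 + ptilde + Ttilde * (log1p(-rhotilde) + (1 - rinv) * rhotilde)
}

# Residual as a plain function of rhotilde with 1/r passed directly;
# no argument checking, used inside solvers.
.sl_resid <- function(rt, Tt, Pt, rinv) {
  rt^2 + Pt + Tt * (log1p(-rt) + (1 - rinv) * rt)
}

# All equation-of-state roots in (0, 1) at reduced conditions.
# Sign-change scan on a grid refined towards the rhotilde -> 1 log
# singularity, followed by uniroot bisection in each bracket.
.sl_roots <- function(Tt, Pt, rinv, n_scan = 400L) {
  grid <- sort(unique(c(
    seq(1e-8, 1 - 1e-7, length.out = n_scan),
    1 - exp(seq(log(1e-7), log(0.3), length.out = 120L))
  )))
  f <- .sl_resid(grid, Tt, Pt, rinv)
  ok <- is.finite(f)
  grid <- grid[ok]; f <- f[ok]
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(.sl_resid, c(grid[i], grid[i + 1L]),
      Tt = Tt, Pt = Pt, rinv = rinv, tol = 1e-14
    )$root
  }, numeric(1))
  # grid points that are themselves (numerically) roots
  exact <- grid[f == 0]
  sort(unique(c(roots, exact)))
}

# Vectorised liquid-root solve: safeguarded Newton on the EoS residual for
# many (Ttilde, ptilde) states at once, with a per-point fallback to the
# bracketed scan when Newton leaves the liquid branch. Used on the hot path
# of PVT fitting, where the same residual is solved at every grid state for
# every objective evaluation.
.liquid_root_vec <- function(Tt, Pt, rinv, start = 0.9) {
  n <- length(Tt)
  rt <- rep(start, n)
  for (k in 1:60) {
    f <- .sl_resid(rt, Tt, Pt, rinv)
    fp <- 2 * rt + Tt * (-1 / (1 - rt) + (1 - rinv))
    step <- f / fp
    rt_new <- pmin(pmax(rt - step, 1e-8), 1 - 1e-12)
    if (max(abs(rt_new - rt)) < 1e-14) {
      rt <- rt_new
      break
    }
    rt <- rt_new
  }
  bad <- abs(.sl_resid(rt, Tt, Pt, rinv)) > 1e-10 | rt < 0.2
  for (i in which(bad)) {
    roots <- .sl_roots(Tt[i], Pt[i], rinv)
    if (length(roots) == 0L) {
      abort(sprintf(
        "No equation-of-state root at reduced state (%g, %g).", Tt[i], Pt[i]
      ))
    }
    rt[i] <- max(roots)
  }
  rt
}

# Dimensionless Gibbs energy per lattice site (up to state-independent
# constants) used to pick among multiple roots of the pure-fluid EoS.
.sl_gibbs_per_site <- function(rt, Tt, Pt, rinv) {
  vt <- 1 / rt
  -rt + Pt * vt + Tt * ((vt - 1) * log1p(-rt) + rinv * log(rt))
}

#' Equilibrium density of a pure Sanchez-Lacombe fluid
#'
#' Solves the lattice-fluid equation of state for the reduced density at
#' temperature `T` and pressure `p` and returns the mass density
#' rhotilde * rhostar. When the state admits both a vapor-like and a
#' liquid-like root, `phase = "liquid"` selects the largest root,
#' `phase = "vapor"` the smallest, and the default `"auto"` the root of
#' lowest Gibbs energy.
#'
#' @param params An [sl_params()] object.
#' @param T Temperature, K. Vectorised together with `p`.
#' @param p Pressure, MPa.
#' @param phase `"auto"`, `"liquid"` or `"vapor"`.
#' @return Mass density in g/cm^3 (vector of `length(T)`).
#' @examples
#' sl_density(sl_polymer("PHBV0"), 298.15, 0.1)
#' @export
sl_density <- function(params, T, p, phase = c("auto", "liquid", "vapor")) {
  stopifnot(inherits(params, "sl_params"))
  phase <- match.arg(phase)
  if (length(p) == 1L) p <- rep(p, length(T))
  if (length(T) == 1L) T <- rep(T, length(p))
  if (length(T) != length(p)) abort("`T` and `p` must have matching lengths.")
  r <- sl_chain_size(params)
  rinv <- if (is.infinite(r)) 0 else 1 / r
  vapply(seq_along(T), function(i) {
    Tt <- T[i] / params$Tstar
    Pt <- p[i] / params$pstar
    roots <- .sl_roots(Tt, Pt, rinv)
    if (length(roots) == 0L) {
      abort(sprintf(
        "No equation-of-state root in (0, 1) at T = %g K, p = %g MPa for '%s'.",
        T[i], p[i], params$species
      ))
    }
    rt <- switch(phase,
      liquid = max(roots),
      vapor = min(roots),
      auto = roots[which.min(.sl_gibbs_per_site(roots, Tt, Pt, rinv))]
    )
    rt * params$rhostar
  }, numeric(1))
}

#' Reduced state of a pure fluid
#'
#' Scales (T, p, rho) by the characteristic parameters. The inverse map
#' recovers the inputs exactly, since the scaling is a pure division.
#'
#' @param params An [sl_params()] object.
#' @param T Temperature, K.
#' @param p Pressure, MPa.
#' @param rho Mass density, g/cm^3; if `NULL`, solved with [sl_density()].
#' @param phase Root selection passed to [sl_density()].
#' @return A tibble with `Ttilde`, `ptilde`, `rhotilde` and chain size `r`.
#' @export
sl_reduced_state <- function(params, T, p, rho = NULL,
                             phase = c("auto", "liquid", "vapor")) {
  phase <- match.arg(phase)
  if (is.null(rho)) rho <- sl_density(params, T, p, phase = phase)
  tibble(
    Ttilde = T / params$Tstar,
    ptilde = p / params$pstar,
    rhotilde = rho / params$rhostar,
    r = sl_chain_size(params)
  )
}
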