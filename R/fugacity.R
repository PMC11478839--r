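#' Peng-Robinson fugacities of a gas or gas mixture
#'
#' Computes vapor-phase fugacity coefficients and fugacities for a pure gas
#' or a binary/multinary mixture with the Peng-Robinson cubic equation of
#' state under van der Waals mixing, a_ij = (1 - k_ij) sqrt(a_i a_j). The
#' vapor root (largest compressibility) is selected; at the sub-30-bar,
#' 35 degC conditions of interest the gas phase is always vapor.
#'
#' @param T Temperature, K.
#' @param p Total pressure, MPa. Vectorised.
#' @param components List of [pr_component()] objects
#'   (default CO2 and CH4 from [pr_gas()]).
#' @param y Mole fractions, one per component, summing to 1. A pure gas is
#'   the single-component case `y = 1`.
#' @param k Binary interaction coefficient applied to every unlike pair
#'   (default 0.09, the CO2/CH4 value), or a full symmetric matrix.
#' @return A tibble with one row per component and pressure: `species`, `y`,
#'   `p_MPa`, `phi` (fugacity coefficient), `fugacity_MPa`, `fugacity_bar`.
#' @examples
#' pr_fugacity(308.15, 3, components = list(pr_gas("CO2")), y = 1)
#' pr_fugacity(308.15, 3, y = c(0.5, 0.5))
#' @export
pr_fugacity <- function(T, p, components = list(pr_gas("CO2"), pr_gas("CH4")),
                        y, k = 0.09) {
  if (!all(vapply(components, inherits, TRUE, "pr_component"))) {
    abort("`components` must be a list of pr_component objects.")
  }
  nc <- length(components)
  if (length(y) != nc) abort("`y` must have one mole fraction per component.")
  if (any(y < 0) || abs(sum(y) - 1) > 1e-8) {
    abort("`y` must be nonnegative and sum to 1.")
  }
  if (!is.matrix(k)) {
    km <- matrix(k, nc, nc)
    diag(km) <- 0
  } else {
    km <- k
  }
  Tc <- vapply(components, `[[`, 0, "Tc")
  Pc <- vapply(components, `[[`, 0, "Pc") * 1e6   # Pa
  om <- vapply(components, `[[`, 0, "omega")
  sp <- vapply(components, function(c) c$species %||% NA_character_, "")
  kap <- 0.37464 + 1.54226 * om - 0.26992 * om^2
  ai <- 0.45724 * .R_GAS^2 * Tc^2 / Pc * (1 + kap * (1 - sqrt(T / Tc)))^2
  bi <- 0.07780 * .R_GAS * Tc / Pc
  aij <- sqrt(outer(ai, ai)) * (1 - km)
  am <- c(y %*% aij %*% y)
  bm <- sum(y * bi)
  rows <- lapply(p, function(pk) {
    pp <- pk * 1e6
    A <- am * pp / (.R_GAS * T)^2
    B <- bm * pp / (.R_GAS * T)
    z <- polyroot(c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1))
    z <- Re(z[abs(Im(z)) < 1e-8])
    z <- z[z > B]
    if (length(z) == 0L) {
      abort(sprintf("No vapor root at T = %g K, p = %g MPa.", T, pk))
    }
    Z <- max(z)
    lnphi <- bi / bm * (Z - 1) - log(Z - B) -
      A / (2 * sqrt(2) * B) * (2 * c(aij %*% y) / am - bi / bm) *
        log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
    tibble(
      species = sp, y = y, p_MPa = pk,
      phi = exp(lnphi),
      fugacity_MPa = exp(lnphi) * y * pk,
      fugacity_bar = exp(lnphi) * y * pk * 10
    )
  })
  bind_rows(rows)
}
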