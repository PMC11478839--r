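#' HV mole fraction to mass fraction
#'
#' Converts the 3-hydroxyvalerate (HV) mole fraction of a PHBV copolymer to
#' the HV mass fraction using the repeat-unit molar masses,
#' w_hv = x m_hv / (x m_hv + (1 - x) m_hb).
#'
#' @param x_hv HV mole fraction in `[0, 1]`. Vectorised.
#' @param m_hb,m_hv Repeat-unit molar masses, g/mol (defaults 86.09, 100.12).
#' @return HV mass fraction, same length as `x_hv`.
#' @examples
#' hv_mass_fraction(0.25)
#' @export
hv_mass_fraction <- function(x_hv, m_hb = .M_HB, m_hv = .M_HV) {
  if (any(x_hv < 0 | x_hv > 1)) abort("`x_hv` must lie in [0, 1].")
  if (m_hb <= 0 || m_hv <= 0) abort("Monomer molar masses must be positive.")
  x_hv * m_hv / (x_hv * m_hv + (1 - x_hv) * m_hb)
}

#' Copolymer characteristic parameters from homopolymer endpoints
#'
#' Treats a PHBV copolymer as a pseudo-binary mixture of the PHB and PHV
#' homopolymers and applies the lattice-fluid mixing rules (see
#' [sl_mixture()]) at the mass composition implied by the HV mole fraction.
#' With the default `kij = 0` the cross interaction is the plain geometric
#' mean, which is the calibration found to describe the PHBV series.
#'
#' @param hb [sl_params()] of the PHB endpoint (0 mol% HV).
#' @param hv [sl_params()] of the PHV endpoint (100 mol% HV).
#' @param x_hv HV mole fraction in `[0, 1]`.
#' @param kij Binary interaction coefficient between the two monomer
#'   pseudo-components (default 0).
#' @param m_hb,m_hv Repeat-unit molar masses, g/mol.
#' @return An [sl_params()] object in the polymer limit.
#' @examples
#' sl_copolymer(sl_polymer("PHBV0"), sl_polymer("PHBV100"), 0.25)
#' @export
sl_copolymer <- function(hb, hv, x_hv, kij = 0, m_hb = .M_HB, m_hv = .M_HV) {
  stopifnot(inherits(hb, "sl_params"), inherits(hv, "sl_params"))
  if (length(x_hv) != 1L || x_hv < 0 || x_hv > 1) {
    abort("`x_hv` must be a single value in [0, 1].")
  }
  if (x_hv == 0) return(hb)
  if (x_hv == 1) return(hv)
  w_hv <- hv_mass_fraction(x_hv, m_hb, m_hv)
  mx <- .mix_struct(list(hb, hv), c(1 - w_hv, w_hv),
                    matrix(c(0, kij, kij, 0), 2L, 2L))
  sl_params(mx$Tstar, mx$pstar, mx$rhostar,
    molar_mass = Inf,
    species = sprintf("PHBV%g", round(100 * x_hv, 1))
  )
}

#' Characteristic parameters across the copolymer composition range
#'
#' Tabulates [sl_copolymer()] over a grid of HV mole fractions, for
#' reporting and plotting the composition trend of T*, p* and rho*.
#'
#' @param hb,hv Homopolymer endpoints as in [sl_copolymer()].
#' @param x_hv Grid of HV mole fractions (default 0 to 1 in steps of 0.05).
#' @param kij Binary interaction coefficient (default 0).
#' @return A tibble with columns `x_hv`, `w_hv`, `Tstar`, `pstar`, `rhostar`.
#' @examples
#' tr <- sl_parameter_trend(sl_polymer("PHBV0"), sl_polymer("PHBV100"))
#' head(tr)
#' @export
sl_parameter_trend <- function(hb, hv, x_hv = seq(0, 1, by = 0.05), kij = 0) {
  if (any(x_hv < 0 | x_hv > 1)) abort("`x_hv` grid must lie within [0, 1].")
  rows <- lapply(x_hv, function(x) {
    p <- sl_copolymer(hb, hv, x, kij = kij)
    tibble(
      x_hv = x, w_hv = hv_mass_fraction(x),
      Tstar = p$Tstar, pstar = p$pstar, rhostar = p$rhostar
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("sl_trend", class(out))
  out
}

#' Plot the composition trend of the characteristic parameters
#'
#' @param object A tibble from [sl_parameter_trend()].
#' @param ... Unused.
#' @return A ggplot object with one facet per characteristic parameter.
#' @method autoplot sl_trend
#' @export
autoplot.sl_trend <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("Tstar", "pstar", "rhostar"),
    names_to = "parameter", values_to = "value"
  )
  long$parameter <- factor(long$parameter,
    levels = c("Tstar", "pstar", "rhostar"),
    labels = c("T* (K)", "p* (MPa)", "rho* (g/cm3)")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x_hv, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(
      x = "HV mole fraction",
      y = NULL,
      title = "Lattice-fluid parameters across the PHBV composition range"
    )
}
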