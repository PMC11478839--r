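#' Sanchez-Lacombe characteristic parameters for one species
#'
#' Bundles the lattice-fluid characteristic triple of a pure fluid or polymer:
#' characteristic temperature `Tstar` (K), characteristic pressure `pstar`
#' (MPa) and close-packed mass density `rhostar` (g/cm^3), together with the
#' species molar mass. A polymer is represented by `molar_mass = Inf`, which
#' puts the chain size r at its infinite-chain limit analytically rather than
#' through a large finite number.
#'
#' The chain size r (lattice sites per molecule) follows from the triple as
#' r = M pstar / (R Tstar rhostar) and is reported by [sl_chain_size()].
#'
#' @param Tstar Characteristic temperature, K. Positive.
#' @param pstar Characteristic pressure, MPa. Positive.
#' @param rhostar Close-packed mass density, g/cm^3. Positive.
#' @param molar_mass Molar mass, g/mol; `Inf` (default) marks a high polymer.
#' @param species Optional species label used in printing and result tables.
#'
#' @return An object of class `sl_params`.
#' @examples
#' phb <- sl_params(859.4, 607.4, 1.226, species = "PHBV0")
#' co2 <- sl_gas("CO2")
#' sl_chain_size(co2)
#' @seealso [sl_gas()], [sl_polymer()], [sl_density()]
#' @export
sl_params <- function(Tstar, pstar, rhostar, molar_mass = Inf, species = NULL) {
  for (nm in c("Tstar", "pstar", "rhostar")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0) {
    abort("`molar_mass` must be a single positive number (Inf for polymers).")
  }
  structure(
    list(
      Tstar = as.numeric(Tstar), pstar = as.numeric(pstar),
      rhostar = as.numeric(rhostar), molar_mass = as.numeric(molar_mass),
      species = species %||% NA_character_
    ),
    class = "sl_params"
  )
}

#' @export
print.sl_params <- function(x, ...) {
  lab <- if (is.na(x$species)) "" else paste0(" [", x$species, "]")
  cat(sprintf(
    "<sl_params>%s T* = %.4g K, p* = %.4g MPa, rho* = %.4g g/cm3, M = %s\n",
    lab, x$Tstar, x$pstar, x$rhostar,
    if (is.infinite(x$molar_mass)) "Inf (polymer)" else format(x$molar_mass)
  ))
  invisible(x)
}

#' Chain size (lattice sites per molecule)
#'
#' r = M pstar / (R Tstar rhostar); `Inf` for the polymer limit.
#'
#' @param params An [sl_params()] object.
#' @return A single number (possibly `Inf`).
#' @export
sl_chain_size <- function(params) {
  stopifnot(inherits(params, "sl_params"))
  params$molar_mass * params$pstar / (.R_GAS * params$Tstar * params$rhostar)
}

#' Lattice-fluid parameters of common penetrant gases
#'
#' Characteristic parameters of CO2 and CH4 from the standard lattice-fluid
#' tabulation used throughout the polymer-sorption literature
#' (CO2: 300 K, 630 MPa, 1.515 g/cm^3; CH4: 215 K, 250 MPa, 0.500 g/cm^3).
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @return An [sl_params()] object.
#' @export
sl_gas <- function(gas = c("CO2", "CH4")) {
  gas <- match.arg(gas)
  switch(gas,
    CO2 = sl_params(300, 630, 1.515, molar_mass = 44.01, species = "CO2"),
    CH4 = sl_params(215, 250, 0.500, molar_mass = 16.04, species = "CH4")
  )
}

# Characteristic parameter library for the PHBV series: homopolymers and
# PHBV8/PHBV60 from direct fits to simulated PVT data, the remaining
# compositions from the kij = 0 mixing rules (see sl_copolymer()).
.PHBV_TABLE <- list(
  PHBV0   = c(859.4, 607.4, 1.226),
  PHBV8   = c(857.1, 595.8, 1.216),
  PHBV16  = c(852.5, 588.4, 1.211),
  PHBV25  = c(848.9, 578.5, 1.203),
  PHBV40  = c(843.3, 562.9, 1.191),
  PHBV60  = c(836.4, 546.4, 1.176),
  PHBV80  = c(830.3, 527.0, 1.161),
  PHBV100 = c(824.7, 511.5, 1.148)
)

#' Reference lattice-fluid parameters for PHBV copolymers
#'
#' Characteristic parameter sets for the PHBV composition series, from
#' PHBV0 (pure PHB) to PHBV100 (pure PHV). PHBV0, PHBV8, PHBV60 and PHBV100
#' come from direct fits to simulated PVT data of the amorphous melt; the
#' intermediate compositions are mixing-rule estimates with kij = 0.
#'
#' @param label One of `"PHBV0"`, `"PHBV8"`, `"PHBV16"`, `"PHBV25"`,
#'   `"PHBV40"`, `"PHBV60"`, `"PHBV80"`, `"PHBV100"`.
#' @return An [sl_params()] object (polymer limit, `molar_mass = Inf`).
#' @examples
#' sl_polymer("PHBV8")
#' @export
sl_polymer <- function(label) {
  if (!label %in% names(.PHBV_TABLE)) {
    abort(sprintf(
      "Unknown polymer label '%s'; available: %s.",
      label, paste(names(.PHBV_TABLE), collapse = ", ")
    ))
  }
  v <- .PHBV_TABLE[[label]]
  sl_params(v[1], v[2], v[3], molar_mass = Inf, species = label)
}

#' Peng-Robinson critical constants for one gas
#'
#' @param Tc Critical temperature, K.
#' @param Pc Critical pressure, MPa.
#' @param omega Acentric factor.
#' @param species Species label.
#' @return An object of class `pr_component`.
#' @seealso [pr_gas()], [pr_fugacity()]
#' @export
pr_component <- function(Tc, Pc, omega, species = NULL) {
  if (Tc <= 0 || Pc <= 0) abort("`Tc` and `Pc` must be positive.")
  structure(
    list(Tc = Tc, Pc = Pc, omega = omega, species = species %||% NA_character_),
    class = "pr_component"
  )
}

#' Default Peng-Robinson constants for CO2 and CH4
#'
#' Textbook critical constants: CO2 (304.13 K, 7.377 MPa, omega 0.224),
#' CH4 (190.56 K, 4.599 MPa, omega 0.011).
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @return A [pr_component()] object.
#' @export
pr_gas <- function(gas = c("CO2", "CH4")) {
  gas <- match.arg(gas)
  switch(gas,
    CO2 = pr_component(304.13, 7.377, 0.224, species = "CO2"),
    CH4 = pr_component(190.56, 4.599, 0.011, species = "CH4")
  )
}
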