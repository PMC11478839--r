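#' Define a polymer-gas sorption system
#'
#' Collects everything needed to solve sorption equilibria at one
#' temperature: the polymer (lattice-fluid polymer limit), one or more
#' penetrant gases, the gas-polymer binary interaction coefficients, the
#' gas-gas coefficient acting between dissolved penetrants, and the
#' Peng-Robinson constants used to convert the external gas phase to
#' fugacities.
#'
#' The equilibrium condition equates each penetrant's lattice-fluid chemical
#' potential in the polymer mixture to its external-phase value, with the
#' external phase represented through its Peng-Robinson fugacity (binary
#' coefficient `k_pr`, default 0.09 for CO2/CH4) anchored to the ideal-gas
#' reference of the lattice fluid.
#'
#' @param polymer [sl_params()] of the polymer (infinite chain).
#' @param gases List of penetrant [sl_params()] (default CO2 and CH4 from
#'   [sl_gas()]); a single object is accepted.
#' @param kij_gas_polymer Gas-polymer interaction coefficient, one per gas
#'   (recycled if scalar). Must satisfy |kij| <= 0.2.
#' @param kij_gas_gas Interaction coefficient between dissolved gases
#'   (default -0.03, the CO2/CH4 value).
#' @param temperature Temperature, K (default 308.15).
#' @param pr_components List of [pr_component()] matched to `gases`;
#'   defaults are looked up by species label via [pr_gas()].
#' @param k_pr Peng-Robinson binary coefficient for the external gas
#'   mixture (default 0.09).
#' @return An object of class `sorption_system`.
#' @examples
#' sys <- sorption_system(sl_polymer("PHBV8"),
#'   kij_gas_polymer = c(-0.002, -0.069)
#' )
#' solve_sorption(sys, p_total = 0.1, y = c(1, 0))
#' @export
sorption_system <- function(polymer,
                            gases = list(sl_gas("CO2"), sl_gas("CH4")),
                            kij_gas_polymer = 0,
                            kij_gas_gas = -0.03,
                            temperature = 308.15,
                            pr_components = NULL,
                            k_pr = 0.09) {
  stopifnot(inherits(polymer, "sl_params"))
  if (inherits(gases, "sl_params")) gases <- list(gases)
  if (length(gases) == 0L || !all(vapply(gases, inherits, TRUE, "sl_params"))) {
    abort("`gases` must be one or more sl_params objects.")
  }
  if (!is.infinite(polymer$molar_mass)) {
    abort("`polymer` must be in the polymer limit (molar_mass = Inf).")
  }
  ng <- length(gases)
  kgp <- rep_len(kij_gas_polymer, ng)
  if (any(abs(c(kgp, kij_gas_gas)) > 0.2)) {
    abort("Interaction coefficients must satisfy |kij| <= 0.2.")
  }
  if (is.null(pr_components)) {
    pr_components <- lapply(gases, function(g) {
      if (g$species %in% c("CO2", "CH4")) {
        pr_gas(g$species)
      } else {
        abort(sprintf(
          "No default Peng-Robinson constants for '%s'; supply `pr_components`.",
          g$species
        ))
      }
    })
  }
  if (length(pr_components) != ng) {
    abort("`pr_components` must match `gases` in length.")
  }
  # kij matrix over (gases..., polymer)
  kij <- matrix(0, ng + 1L, ng + 1L)
  if (ng > 1L) {
    kij[seq_len(ng), seq_len(ng)][upper.tri(matrix(0, ng, ng))] <- kij_gas_gas
    kij[seq_len(ng), seq_len(ng)] <-
      kij[seq_len(ng), seq_len(ng)] + t(kij[seq_len(ng), seq_len(ng)])
  }
  kij[ng + 1L, seq_len(ng)] <- kgp
  kij[seq_len(ng), ng + 1L] <- kgp
  structure(
    list(
      polymer = polymer, gases = gases, kij = kij,
      kij_gas_polymer = kgp, kij_gas_gas = kij_gas_gas,
      temperature = temperature,
      pr_components = pr_components, k_pr = k_pr,
      rho_polymer_ref = sl_density(polymer, temperature, 0.1, phase = "liquid")
    ),
    class = "sorption_system"
  )
}

#' @export
print.sorption_system <- function(x, ...) {
  gl <- vapply(x$gases, function(g) g$species, "")
  cat(sprintf(
    "<sorption_system> %s + {%s} at %.2f K\n  kij gas-polymer: %s; gas-gas: %g; PR k: %g\n",
    x$polymer$species, paste(gl, collapse = ", "), x$temperature,
    paste(sprintf("%g", x$kij_gas_polymer), collapse = ", "), x$kij_gas_gas,
    x$k_pr
  ))
  invisible(x)
}

# Ideal-gas-anchored lattice-fluid chemical potential of a pure gas at a
# reference pressure low enough that the fluid is ideal; adding log(f/p_ref)
# then gives the external-phase potential at fugacity f.
.mu_gas_reference <- function(gas, T, p_ref = 1e-4) {
  mx <- .mix_struct(list(gas), 1, matrix(0, 1L, 1L))
  roots <- .sl_roots(T / mx$Tstar, p_ref / mx$pstar, mx$rinv_bar)
  rt <- min(roots)
  .mu_over_RT(mx, rt, T, p_ref)[1L]
}

# External-phase chemical-potential targets for every gas at (p_total, y):
# Peng-Robinson mixture fugacities mapped into the lattice-fluid ideal-gas
# reference frame.
.mu_targets <- function(system, p_total, y) {
  fug <- pr_fugacity(system$temperature, p_total,
    components = system$pr_components, y = y, k = system$k_pr
  )
  f <- fug$fugacity_MPa
  mu <- vapply(seq_along(system$gases), function(i) {
    if (y[i] == 0) {
      return(-Inf)
    }
    .mu_gas_reference(system$gases[[i]], system$temperature) + log(f[i] / 1e-4)
  }, numeric(1))
  list(mu = mu, fugacity_MPa = f)
}

# Chemical potentials of the dissolved gases at polymer-phase gas mass
# fractions w (length = number of gases).
.mu_polymer_phase <- function(system, w, p_total) {
  comps <- c(system$gases, list(system$polymer))
  mx <- .mix_struct(comps, c(w, 1 - sum(w)), system$kij)
  rt <- {
    roots <- .sl_roots(
      system$temperature / mx$Tstar, p_total / mx$pstar, mx$rinv_bar
    )
    if (length(roots) == 0L) {
      abort(sprintf(
        "No polymer-phase density root at p = %g MPa, w = (%s).",
        p_total, paste(sprintf("%.3g", w), collapse = ", ")
      ))
    }
    max(roots)
  }
  list(
    mu = .mu_over_RT(mx, rt, system$temperature, p_total)[seq_along(w)],
    rhotilde = rt, rhostar = mx$rhostar
  )
}

# Damped Newton iteration in log mass-fraction space for the active gases.
.solve_equilibrium <- function(system, p_total, y, w_start = NULL,
                               tol = 1e-10, maxit = 200L) {
  active <- which(y > 0)
  tg <- .mu_targets(system, p_total, y)
  ng <- length(system$gases)
  resid_fn <- function(lw_active) {
    w <- numeric(ng)
    w[active] <- exp(lw_active)
    .mu_polymer_phase(system, w, p_total)$mu[active] - tg$mu[active]
  }
  lw <- log(if (is.null(w_start)) rep(1e-4, length(active)) else
            pmax(w_start[active], 1e-12))
  f0 <- resid_fn(lw)
  for (it in seq_len(maxit)) {
    if (max(abs(f0)) < tol) break
    jac <- matrix(0, length(active), length(active))
    h <- 1e-7
    for (j in seq_along(active)) {
      lp <- lw
      lp[j] <- lp[j] + h
      jac[, j] <- (resid_fn(lp) - f0) / h
    }
    step <- tryCatch(-solve(jac, f0), error = function(e) -f0 / diag(jac))
    step <- pmax(pmin(step, 0.75), -0.75)
    # backtracking damping
    lam <- 1
    repeat {
      lw_new <- pmin(lw + lam * step, log(0.7))
      f_new <- tryCatch(resid_fn(lw_new), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f0)) || lam < 1e-3)) break
      lam <- lam / 2
    }
    lw <- lw_new
    f0 <- f_new
  }
  if (max(abs(f0)) > 1e-8) {
    abort(sprintf(
      "Sorption solver did not converge at p = %g MPa (last residual %.3g, w = %s).",
      p_total, max(abs(f0)),
      paste(sprintf("%.3g", exp(lw)), collapse = ", ")
    ))
  }
  w <- numeric(ng)
  w[active] <- exp(lw)
  list(w = w, fugacity_MPa = tg$fugacity_MPa, mu_residual = max(abs(f0)))
}

# Assemble the per-gas result tibble for solved mass fractions.
.sorption_result <- function(system, p_total, y, sol) {
  ng <- length(system$gases)
  w <- sol$w
  w_pol <- 1 - sum(w)
  comps <- c(system$gases, list(system$polymer))
  mx <- .mix_struct(comps, c(w, w_pol), system$kij)
  rt <- .mix_rhotilde(
    structure(mx, class = "sl_mixture"), system$temperature, p_total, "liquid"
  )
  rho_mix <- rt * mx$rhostar
  rho_ref <- system$rho_polymer_ref
  M <- vapply(system$gases, `[[`, 0, "molar_mass")
  conc <- (w / w_pol) / M * rho_ref * .V_STP
  f_bar <- sol$fugacity_MPa * 10
  S <- ifelse(f_bar > 0, conc / f_bar, NA_real_)
  out <- tibble(
    species = vapply(system$gases, function(g) g$species, ""),
    y = y,
    T_K = system$temperature,
    p_total_MPa = p_total,
    fugacity_bar = f_bar,
    mass_fraction = w,
    concentration_cm3stp_cm3 = conc,
    S_cm3stp_cm3_bar = S,
    mixture_density_g_cm3 = rho_mix,
    polymer_partial_density_g_cm3 = rho_mix * w_pol,
    density_change_pct = 100 * (rho_mix * w_pol - rho_ref) / rho_ref,
    mixture_density_change_pct = 100 * (rho_mix - rho_ref) / rho_ref,
    selectivity = if (ng == 2L && !anyNA(S) && all(S > 0)) S[1] / S[2]
                  else NA_real_,
    mu_residual = sol$mu_residual
  )
  class(out) <- c("sorption_result", class(out))
  out
}

#' Solve a pure- or mixed-gas sorption equilibrium
#'
#' Finds the polymer-phase penetrant mass fractions at which every gas's
#' lattice-fluid chemical potential in the swollen polymer equals its
#' external-phase value at total pressure `p_total` and gas-phase mole
#' fractions `y`, then reports concentrations, solubility coefficients,
#' mixture density and swelling.
#'
#' Concentrations are expressed in cm^3(STP) per cm^3 of unpenetrated
#' polymer at the system temperature and 1 bar. Swelling
#' (`density_change_pct`) is the percent change of the polymer-partial
#' density (mixed-phase density times polymer mass fraction) relative to the
#' unpenetrated polymer density; the mixed-phase mass density and its change
#' are also reported.
#'
#' @param system A [sorption_system()].
#' @param p_total Total pressure, MPa. `0` returns the trivial zero-sorption
#'   state.
#' @param y Gas-phase mole fractions over the system's gases (default: first
#'   gas pure). Zero entries switch a gas off.
#' @param w_start Optional starting mass fractions for the solver.
#' @return A `sorption_result` tibble with one row per gas; see the field
#'   list above. The chemical-potential mismatch at the solution is in
#'   `mu_residual`.
#' @examples
#' sys <- sorption_system(sl_polymer("PHBV8"),
#'   gases = list(sl_gas("CO2")), kij_gas_polymer = -0.002
#' )
#' solve_sorption(sys, 3, y = 1)
#' @export
solve_sorption <- function(system, p_total, y = NULL, w_start = NULL) {
  stopifnot(inherits(system, "sorption_system"))
  ng <- length(system$gases)
  if (is.null(y)) y <- c(1, rep(0, ng - 1L))
  if (length(y) != ng || any(y < 0)) {
    abort("`y` must give a nonnegative mole fraction for every gas.")
  }
  if (p_total < 0) abort("`p_total` must be nonnegative.")
  if (p_total == 0 || sum(y) == 0) {
    sol <- list(
      w = numeric(ng), fugacity_MPa = numeric(ng), mu_residual = 0
    )
    return(.sorption_result(system, p_total, y / max(sum(y), 1), sol))
  }
  y <- y / sum(y)
  sol <- .solve_equilibrium(system, p_total, y, w_start = w_start)
  .sorption_result(system, p_total, y, sol)
}

#' Sorption isotherm over a pressure grid
#'
#' Runs [solve_sorption()] along increasing total pressure with continuation
#' (each solution starts the next) and stacks the per-gas rows.
#'
#' @inheritParams solve_sorption
#' @param pressures Total pressures, MPa.
#' @return A `sorption_result` tibble with `length(pressures)` blocks.
#' @examples
#' sys <- sorption_system(sl_polymer("PHBV8"),
#'   gases = list(sl_gas("CO2")), kij_gas_polymer = -0.002
#' )
#' iso <- sorption_isotherm(sys, pressures = c(0.5, 1, 2, 3))
#' @export
sorption_isotherm <- function(system, pressures, y = NULL) {
  ord <- order(pressures)
  w_prev <- NULL
  blocks <- vector("list", length(pressures))
  for (i in ord) {
    res <- solve_sorption(system, pressures[i], y = y, w_start = w_prev)
    w_prev <- res$mass_fraction
    blocks[[i]] <- res
  }
  out <- bind_rows(blocks)
  class(out) <- c("sorption_result", class(out))
  out
}

#' Plot sorption isotherms
#'
#' Concentration against own fugacity, one curve per gas.
#'
#' @param object A `sorption_result` tibble spanning several pressures.
#' @param ... Unused.
#' @method autoplot sorption_result
#' @export
autoplot.sorption_result <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$y > 0),
    ggplot2::aes(.data$fugacity_bar, .data$concentration_cm3stp_cm3,
      colour = .data$species
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fugacity (bar)", y = "c (cm3 STP / cm3 polymer)",
      colour = NULL, title = "Sorption isotherms"
    )
}

#' Solubility coefficient from a sorption result
#'
#' S = c/f in cm^3(STP) cm^-3 bar^-1 for the requested gas.
#'
#' @param result A `sorption_result` tibble (single state point).
#' @param gas Gas index or species label (default first gas).
#' @return S, a single number.
#' @export
solubility_coefficient <- function(result, gas = 1L) {
  row <- if (is.character(gas)) {
    dplyr::filter(result, .data$species == gas)
  } else {
    result[gas, ]
  }
  if (nrow(row) != 1L) abort("`gas` must select exactly one row.")
  if (!is.finite(row$fugacity_bar) || row$fugacity_bar <= 0) {
    abort("Solubility coefficient undefined at zero fugacity.")
  }
  row$concentration_cm3stp_cm3 / row$fugacity_bar
}

#' Solubility-selectivity between two gases
#'
#' alpha_ij = S_i / S_j on a molar-concentration basis (units cancel).
#' Accepts either a two-gas `sorption_result` or two explicit coefficients.
#'
#' @param result A `sorption_result` (one state point, two or more gases),
#'   or the numerator coefficient S_i.
#' @param s_j Denominator coefficient when two numbers are given.
#' @param i,j Row selectors when a result tibble is given.
#' @return Dimensionless selectivity.
#' @export
solubility_selectivity <- function(result, s_j = NULL, i = 1L, j = 2L) {
  if (is.numeric(result)) {
    if (is.null(s_j) || s_j == 0) abort("Denominator coefficient must be nonzero.")
    return(result / s_j)
  }
  si <- solubility_coefficient(result, i)
  sj <- solubility_coefficient(result, j)
  if (sj == 0) abort("Denominator solubility coefficient is zero.")
  si / sj
}

#' Mixed-gas versus ideal solubility-selectivity
#'
#' Tabulates, over a total-pressure grid at fixed gas-phase composition, the
#' mixed-gas solubility-selectivity and the ideal (pure-gas) selectivity
#' computed from single-gas isotherms at the same total pressure, plus the
#' percent reduction of mixed relative to ideal. In the dilute limit the two
#' coincide.
#'
#' @param system A two-gas [sorption_system()].
#' @param pressures Total pressures, MPa.
#' @param y_first Gas-phase mole fraction of the first gas (e.g. CO2).
#' @return A tibble with `p_total_MPa`, `alpha_mixed`, `alpha_ideal`,
#'   `pct_below_ideal`.
#' @export
mixed_vs_ideal_selectivity <- function(system, pressures, y_first = 0.2) {
  if (length(system$gases) != 2L) abort("Requires a binary gas system.")
  sp <- vapply(system$gases, function(g) g$species, "")
  mix_iso <- sorption_isotherm(system, pressures, y = c(y_first, 1 - y_first))
  pure1 <- sorption_isotherm(system, pressures, y = c(1, 0))
  pure2 <- sorption_isotherm(system, pressures, y = c(0, 1))
  s_of <- function(iso, sp_name, p) {
    row <- dplyr::filter(iso, .data$p_total_MPa == p, .data$species == !!sp_name)
    row$concentration_cm3stp_cm3 / row$fugacity_bar
  }
  out <- lapply(pressures, function(p) {
    m <- dplyr::filter(mix_iso, .data$p_total_MPa == p)
    a_mixed <- solubility_selectivity(m)
    a_ideal <- s_of(pure1, sp[1], p) / s_of(pure2, sp[2], p)
    tibble(
      p_total_MPa = p, alpha_mixed = a_mixed, alpha_ideal = a_ideal,
      pct_below_ideal = 100 * (1 - a_mixed / a_ideal)
    )
  })
  bind_rows(out)
}

#' Interaction-coefficient sensitivity sweep
#'
#' Recomputes sorption over a grid of gas-polymer interaction coefficients,
#' perturbing one gas at a time while the others stay at zero, and reports
#' per-gas concentrations together with percent deviations from the all-zero
#' reference at every pressure.
#'
#' @param system A [sorption_system()] (its `kij_gas_polymer` is ignored;
#'   the sweep sets the values).
#' @param kij_values Coefficients to scan (default 0, +-0.01, +-0.05).
#' @param pressures Total pressures, MPa.
#' @param y Gas-phase mole fractions.
#' @return A tibble with `varied_gas`, `kij`, `p_total_MPa`, `species`,
#'   `concentration_cm3stp_cm3`, `deviation_pct` (vs the kij = 0 reference;
#'   exactly zero on the reference rows).
#' @export
kij_sensitivity <- function(system, kij_values = c(-0.05, -0.01, 0, 0.01, 0.05),
                            pressures, y = NULL) {
  ng <- length(system$gases)
  if (is.null(y)) y <- rep(1 / ng, ng)
  base_sys <- sorption_system(
    system$polymer, system$gases,
    kij_gas_polymer = rep(0, ng), kij_gas_gas = system$kij_gas_gas,
    temperature = system$temperature, pr_components = system$pr_components,
    k_pr = system$k_pr
  )
  ref <- sorption_isotherm(base_sys, pressures, y = y)
  ref_key <- ref[c("p_total_MPa", "species", "concentration_cm3stp_cm3")]
  names(ref_key)[3] <- "conc_ref"
  out <- list()
  for (g in seq_len(ng)) {
    for (k in kij_values) {
      kgp <- rep(0, ng)
      kgp[g] <- k
      sys_k <- sorption_system(
        system$polymer, system$gases, kij_gas_polymer = kgp,
        kij_gas_gas = system$kij_gas_gas, temperature = system$temperature,
        pr_components = system$pr_components, k_pr = system$k_pr
      )
      iso <- sorption_isotherm(sys_k, pressures, y = y)
      iso$varied_gas <- system$gases[[g]]$species
      iso$kij <- k
      out[[length(out) + 1L]] <- iso
    }
  }
  res <- bind_rows(out) |>
    left_join(ref_key, by = c("p_total_MPa", "species")) |>
    mutate(deviation_pct = 100 *
      (.data$concentration_cm3stp_cm3 - .data$conc_ref) / .data$conc_ref)
  res[c(
    "varied_gas", "kij", "p_total_MPa", "species",
    "concentration_cm3stp_cm3", "deviation_pct"
  )]
}

#' Rescale a semicrystalline solubility to the amorphous phase
#'
#' Sorption is negligible in polymer crystallites, so a solubility measured
#' on a semicrystalline sample maps to the amorphous-phase value as
#' S_am = S_sc / (1 - x_c).
#'
#' @param s_semicrystalline Solubility coefficient(s) of the semicrystalline
#'   sample.
#' @param crystallinity Crystalline mass fraction x_c in `[0, 1)`.
#' @return Amorphous-phase solubility, same shape as the input.
#' @examples
#' amorphous_rescale(0.4, 0.6) # 1.0
#' @export
amorphous_rescale <- function(s_semicrystalline, crystallinity) {
  if (any(crystallinity < 0 | crystallinity >= 1)) {
    abort("`crystallinity` must lie in [0, 1).")
  }
  s_semicrystalline / (1 - crystallinity)
}

#' Fit a gas-polymer interaction coefficient to solubility data
#'
#' One-dimensional bounded minimisation of the summed squared relative error
#' between predicted and observed pure-gas solubility coefficients, giving
#' the gas-polymer kij. Deterministic (golden-section [optimize()]).
#'
#' @param polymer Polymer [sl_params()].
#' @param gas Penetrant [sl_params()].
#' @param observations Data frame with columns `p_MPa` and
#'   `S_cm3stp_cm3_bar` (observed pure-gas solubility coefficients).
#' @param temperature Temperature, K.
#' @param bounds Search interval for kij (default c(-0.2, 0.2)).
#' @param pr_component Peng-Robinson constants for the gas (default looked
#'   up by species).
#' @return A list with `kij`, `objective` (residual sum at the optimum) and
#'   `converged`.
#' @export
fit_gas_polymer_kij <- function(polymer, gas, observations,
                                temperature = 308.15,
                                bounds = c(-0.2, 0.2),
                                pr_component = NULL) {
  need <- c("p_MPa", "S_cm3stp_cm3_bar")
  if (!all(need %in% names(observations)) || nrow(observations) < 1L) {
    abort("`observations` needs columns p_MPa and S_cm3stp_cm3_bar (>= 1 row).")
  }
  objective <- function(k) {
    sys <- sorption_system(polymer,
      gases = list(gas), kij_gas_polymer = k,
      temperature = temperature,
      pr_components = if (is.null(pr_component)) NULL else list(pr_component)
    )
    pred <- vapply(observations$p_MPa, function(p) {
      solubility_coefficient(solve_sorption(sys, p, y = 1), 1L)
    }, numeric(1))
    sum(((pred - observations$S_cm3stp_cm3_bar) /
           observations$S_cm3stp_cm3_bar)^2)
  }
  opt <- optimize(objective, interval = bounds, tol = 1e-7)
  list(kij = opt$minimum, objective = opt$objective, converged = TRUE)
}
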