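#' Mean absolute percentage error
#'
#' MAPE = 100/N sum |obs_i - pred_i| / |obs_i|, the objective minimised when
#' fitting characteristic parameters to PVT data.
#'
#' @param observed,predicted Numeric vectors of equal nonzero length;
#'   `observed` must contain no zeros.
#' @return MAPE in percent.
#' @examples
#' mape(c(1, 2), c(1.1, 1.8)) # 10
#' @export
mape <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal nonzero length.")
  }
  if (any(observed == 0)) abort("`observed` must contain no zero values.")
  100 * mean(abs(observed - predicted) / abs(observed))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with the total sum of squares taken about the
#' observed mean.
#'
#' @param observed,predicted Numeric vectors, at least two points,
#'   nonconstant `observed`.
#' @return R^2 (dimensionless, at most 1).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) < 2L || length(observed) != length(predicted)) {
    abort("Need at least two paired points.")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("`observed` must not be constant.")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Validate a PVT data frame and return it with canonical column order.
.check_pvt <- function(data) {
  need <- c("T_K", "p_MPa", "rho_g_cm3", "replicate")
  if (!all(need %in% names(data))) {
    abort(sprintf(
      "PVT data must contain columns %s.", paste(need, collapse = ", ")
    ))
  }
  num <- c("T_K", "p_MPa", "rho_g_cm3")
  if (any(!vapply(data[num], is.numeric, TRUE))) {
    abort("T_K, p_MPa and rho_g_cm3 must be numeric.")
  }
  if (any(as.matrix(data[num]) <= 0)) {
    abort("All temperatures, pressures and densities must be positive.")
  }
  if (nrow(unique(data[c("T_K", "p_MPa")])) < 4L) {
    abort("At least 4 distinct (T, p) states are required.")
  }
  as_tibble(data)[c(need, setdiff(names(data), need))]
}

#' Fit Sanchez-Lacombe characteristic parameters to PVT data
#'
#' Minimises the MAPE between observed densities and the lattice-fluid
#' liquid-root densities over (T*, p*, rho*) with a bounded Nelder-Mead
#' simplex. The fit is deterministic given the data, the start and the
#' optimiser settings. By default every replicate point enters the objective
#' individually; `replicate_mode = "means"` fits the per-state replicate
#' means instead.
#'
#' @param data Data frame with columns `T_K`, `p_MPa`, `rho_g_cm3`,
#'   `replicate` (the CSV dialect of [read_pvt()]).
#' @param initial Starting [sl_params()] (default 800 K, 550 MPa,
#'   1.2 g/cm^3).
#' @param lower,upper Parameter box as length-3 vectors (T*, p*, rho*);
#'   defaults (300, 100, 0.8) and (1500, 1200, 1.6).
#' @param replicate_mode `"points"` (default) or `"means"`.
#' @param reltol Convergence tolerance on the objective (default 1e-10).
#' @param maxit Maximum simplex iterations (default 5000).
#' @return An object of class `sl_fit`: a list with elements `params`
#'   ([sl_params()]), `mape`, `r_squared`, `n_points`, `converged`,
#'   `iterations` and the fitted `data`. [tidy()] and [glance()] methods
#'   give tibble summaries; [autoplot()] overlays fit and data.
#' @examples
#' pvt <- generate_pvt(sl_polymer("PHBV0"), noise_sigma = 0, replicates = 1)
#' fit <- fit_sl_params(pvt)
#' glance(fit)
#' @export
fit_sl_params <- function(data,
                          initial = sl_params(800, 550, 1.2),
                          lower = c(300, 100, 0.8),
                          upper = c(1500, 1200, 1.6),
                          replicate_mode = c("points", "means"),
                          reltol = 1e-10, maxit = 5000L) {
  data <- .check_pvt(data)
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(inherits(initial, "sl_params"))
  fitdat <- if (replicate_mode == "means") {
    data |>
      group_by(.data$T_K, .data$p_MPa) |>
      summarise(rho_g_cm3 = mean(.data$rho_g_cm3), .groups = "drop")
  } else {
    data
  }
  obs <- fitdat$rho_g_cm3

  predict_rho <- function(par) {
    tryCatch(
      par[3] * .liquid_root_vec(fitdat$T_K / par[1], fitdat$p_MPa / par[2], 0),
      error = function(e) rep(NA_real_, nrow(fitdat))
    )
  }
  objective <- function(par) {
    if (any(par < lower) || any(par > upper)) {
      return(1e6 + sum(pmax(lower - par, 0) + pmax(par - upper, 0)))
    }
    pred <- predict_rho(par)
    if (anyNA(pred)) return(1e6)
    mape(obs, pred)
  }

  start <- c(initial$Tstar, initial$pstar, initial$rhostar)
  opt <- optim(start, objective,
    method = "Nelder-Mead",
    control = list(reltol = reltol, maxit = maxit,
                   parscale = c(100, 100, 0.1))
  )
  converged <- opt$convergence == 0L
  if (!converged) {
    warn(sprintf("Optimiser did not converge (code %d).", opt$convergence))
  }
  params <- sl_params(opt$par[1], opt$par[2], opt$par[3], molar_mass = Inf,
                      species = attr(data, "polymer_id", exact = TRUE))
  pred_all <- vapply(seq_len(nrow(data)), function(i) {
    sl_density(params, data$T_K[i], data$p_MPa[i], phase = "liquid")
  }, numeric(1))
  structure(
    list(
      params = params,
      mape = mape(data$rho_g_cm3, pred_all),
      r_squared = r_squared(data$rho_g_cm3, pred_all),
      n_points = nrow(data),
      converged = converged,
      iterations = opt$counts[["function"]],
      replicate_mode = replicate_mode,
      data = mutate(data, rho_fit = pred_all)
    ),
    class = "sl_fit"
  )
}

#' @export
print.sl_fit <- function(x, ...) {
  cat(sprintf(
    "<sl_fit> T* = %.1f K, p* = %.1f MPa, rho* = %.4f g/cm3\n  MAPE = %.4g %%, R2 = %.4f, n = %d, converged: %s\n",
    x$params$Tstar, x$params$pstar, x$params$rhostar,
    x$mape, x$r_squared, x$n_points, x$converged
  ))
  invisible(x)
}

#' @rdname fit_sl_params
#' @param x,object An `sl_fit` object.
#' @param ... Unused.
#' @method tidy sl_fit
#' @export
tidy.sl_fit <- function(x, ...) {
  tibble(
    term = c("Tstar", "pstar", "rhostar"),
    estimate = c(x$params$Tstar, x$params$pstar, x$params$rhostar),
    unit = c("K", "MPa", "g/cm3")
  )
}

#' @rdname fit_sl_params
#' @method glance sl_fit
#' @export
glance.sl_fit <- function(x, ...) {
  tibble(
    mape = x$mape, r_squared = x$r_squared, n_points = x$n_points,
    converged = x$converged, iterations = x$iterations
  )
}

#' @rdname fit_sl_params
#' @method autoplot sl_fit
#' @export
autoplot.sl_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$T_K, .data$rho_g_cm3,
    colour = factor(.data$p_MPa)
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rho_fit)) +
    ggplot2::labs(
      x = "T (K)", y = "density (g/cm3)", colour = "p (MPa)",
      title = "PVT data and fitted lattice-fluid isobars"
    )
}

#' Read and write PVT tables
#'
#' The on-disk dialect is a comma-delimited UTF-8 file with header columns
#' `T_K,p_MPa,rho_g_cm3,replicate` in any order; unknown columns are
#' rejected by name. Values round-trip at full double precision.
#'
#' @param path File path.
#' @return `read_pvt()` returns a tibble; `write_pvt()` returns `path`
#'   invisibly.
#' @export
read_pvt <- function(path) {
  if (!file.exists(path)) abort(sprintf("PVT file '%s' does not exist.", path))
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) abort(sprintf("PVT file '%s' is empty.", path))
  need <- c("T_K", "p_MPa", "rho_g_cm3", "replicate")
  unknown <- setdiff(names(raw), need)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "PVT file '%s' has unknown column(s): %s.",
      path, paste(unknown, collapse = ", ")
    ))
  }
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf(
      "PVT file '%s' is missing column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  num <- c("T_K", "p_MPa", "rho_g_cm3")
  for (cn in num) {
    if (!is.numeric(raw[[cn]])) {
      abort(sprintf("Column '%s' in '%s' is not numeric.", cn, path))
    }
  }
  as_tibble(raw)[need]
}

#' @rdname read_pvt
#' @param data PVT tibble (columns as above).
#' @export
write_pvt <- function(data, path) {
  data <- .check_pvt(data)
  dat <- data[c("T_K", "p_MPa", "rho_g_cm3", "replicate")]
  # full double precision so that write -> read is the identity
  dat$T_K <- format(dat$T_K, digits = 17, trim = TRUE, scientific = FALSE)
  dat$p_MPa <- format(dat$p_MPa, digits = 17, trim = TRUE, scientific = FALSE)
  dat$rho_g_cm3 <- format(dat$rho_g_cm3, digits = 17, trim = TRUE,
                          scientific = FALSE)
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
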