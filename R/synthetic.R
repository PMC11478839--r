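#' Generate a synthetic molecular-dynamics-like PVT dataset
#'
#' Produces replicated (T, p, rho) observations from known characteristic
#' parameters, emulating the statistics of NPT molecular-dynamics density
#' averages on the standard grid: pressures 0.1/50/100 MPa, ten temperatures
#' from 275 to 600 K, three independent replicates, and multiplicative
#' Gaussian density scatter well below 1 percent. The noiseless backbone is
#' the lattice-fluid liquid-root density; only the replicate noise depends
#' on the seed, so the same seed reproduces the dataset exactly.
#'
#' @param params [sl_params()] of the polymer.
#' @param pressures Pressure grid, MPa.
#' @param temperatures Temperature grid, K.
#' @param replicates Number of independent replicates per state (>= 1).
#' @param noise_sigma Relative standard deviation of the multiplicative
#'   Gaussian density noise (default 0.005, i.e. 0.5 %).
#' @param seed Integer seed for the noise stream.
#' @param polymer_id Optional label attached to the result.
#' @return A tibble with columns `T_K`, `p_MPa`, `rho_g_cm3`, `replicate`,
#'   in the dialect accepted by [fit_sl_params()] and [write_pvt()].
#' @examples
#' pvt <- generate_pvt(sl_polymer("PHBV0"), seed = 1)
#' nrow(pvt) # 90
#' @export
generate_pvt <- function(params,
                         pressures = c(0.1, 50, 100),
                         temperatures = c(275, 300, 325, 350, 375, 400,
                                          450, 500, 550, 600),
                         replicates = 3L,
                         noise_sigma = 0.005,
                         seed = 1L,
                         polymer_id = NULL) {
  stopifnot(inherits(params, "sl_params"))
  if (length(pressures) == 0L || length(temperatures) == 0L) {
    abort("Pressure and temperature grids must be nonempty.")
  }
  if (replicates < 1L) abort("`replicates` must be at least 1.")
  if (noise_sigma < 0) abort("`noise_sigma` must be nonnegative.")
  grid <- tidyr::expand_grid(T_K = temperatures, p_MPa = pressures)
  rho0 <- sl_density(params, grid$T_K, grid$p_MPa, phase = "liquid")
  out <- tidyr::expand_grid(grid, replicate = seq_len(replicates))
  rho0_rep <- rep(rho0, each = replicates)
  noise <- withr_seed(seed, rnorm(nrow(out), mean = 0, sd = 1))
  out$rho_g_cm3 <- rho0_rep * (1 + noise_sigma * noise)
  out <- out[c("T_K", "p_MPa", "rho_g_cm3", "replicate")]
  attr(out, "polymer_id") <- polymer_id
  out
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
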