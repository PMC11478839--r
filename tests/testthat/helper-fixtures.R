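# Shared fixtures: characteristic parameter sets and small helper builders.

phbv0 <- sl_polymer("PHBV0")
phbv8 <- sl_polymer("PHBV8")
phbv25 <- sl_polymer("PHBV25")
phbv100 <- sl_polymer("PHBV100")
co2 <- sl_gas("CO2")
ch4 <- sl_gas("CH4")

# Single-gas sorption system at 35 degC.
pure_gas_system <- function(polymer, gas, kij = 0) {
  sorption_system(polymer, gases = list(gas), kij_gas_polymer = kij)
}

# Pure-gas solubility coefficient at total pressure p (MPa).
pure_S <- function(polymer, gas, kij, p) {
  solubility_coefficient(
    solve_sorption(pure_gas_system(polymer, gas, kij), p, y = 1), 1L
  )
}

# Independent bracketed-bisection root of the lattice-fluid EoS, written
# against the residual definition only (no package solver code).
bisect_root <- function(Tt, Pt, rinv, lo, hi, iter = 200L) {
  f <- function(x) x^2 + Pt + Tt * (log(1 - x) + (1 - rinv) * x)
  stopifnot(f(lo) * f(hi) < 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
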