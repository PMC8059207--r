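# Independent oracles used across the suite. These re-derive quantities
# from their definitions by brute force (dense grids, finite
# differences, direct re-typed formulas) and never call the code paths
# they are used to check.

# Dense grid-search minimizer of the single-chain free energy over alpha.
grid_alpha_oracle <- function(chain, solvent, step = 1e-4, alpha_max = 1.5) {
  grid <- seq(step, alpha_max, by = step)
  fe <- free_energy_intensive(rep(0.5, length(grid)), grid, chain, solvent)
  grid[which.min(fe)]
}

# Extensive free energy Delta G / kT as a function of molecule numbers,
# for finite-difference chemical potentials. Built directly from the
# mixing + internal terms, with phi = nD * N / (nD * N + nS).
extensive_G <- function(n_dna, n_solvent, alpha, chain, solvent) {
  N <- chain$segment_number_N
  phi <- n_dna * N / (n_dna * N + n_solvent)
  (n_dna * N + n_solvent) * free_energy_intensive(phi, alpha, chain, solvent)
}

# Central finite differences with Richardson extrapolation.
fd_mu <- function(f, x, h) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Direct re-typing of the per-lattice-site free energy, term by term,
# independent of the package implementation.
free_energy_retyped <- function(phi, alpha, N, omega, chi, B2, B3) {
  internal <- N * ((chi - 1) +
                     B2 * omega / (2^(3 / 2) * alpha^3) +
                     B3 * omega^2 / (2 * 3^(5 / 2) * alpha^6)) +
    (3 / 2) * (alpha^2 - 1) - log(alpha^3)
  (1 - phi) * log(1 - phi) + (phi / N) * log(phi) +
    chi * phi * (1 - phi) + (phi / N) * internal
}

# Adjusted Rand index between two labelings (closed-form pair counting).
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
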