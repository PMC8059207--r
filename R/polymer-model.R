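# Post-Zimm extension of Flory-Huggins theory for DNA solutions:
# length-dependent coil-globule collapse of single chains and two-phase
# coexistence (binodal) computed from chemical-potential equality.

.AVOGADRO <- 6.02214076e23

#' Third virial coefficient of the DNA lattice model
#'
#' Default parameterization of the three-body (triple-contact) virial
#' coefficient entering the internal free energy of a collapsing chain,
#' \deqn{B_3 = 1 + \chi^2/(2q) - \chi^3/(6q^2),}
#' with `q` the lattice coordination number. This grouping keeps
#' \eqn{B_3 > 0} for all solvent qualities of interest so that the
#' single-chain free energy is bounded below (the globule is stabilized
#' by three-body repulsion).
#'
#' An alternative series grouping, \eqn{B_3 = 1 + \chi^2 q/2 - \chi^3
#' q^2/6}, is provided as [virial_B3_series()]; it turns negative for
#' \eqn{\chi \gtrsim 0.52} at \eqn{q = 10}, which removes the globule
#' minimum (free energy diverges to \eqn{-\infty} as \eqn{\alpha \to 0})
#' and is therefore not the default.
#'
#' @param chi Flory interaction parameter (dimensionless).
#' @param q Lattice coordination number.
#' @return Dimensionless third virial coefficient.
#' @seealso [solvent_condition()]
#' @export
virial_B3_regularized <- function(chi, q) {
  1 + chi^2 / (2 * q) - chi^3 / (6 * q^2)
}

#' @rdname virial_B3_regularized
#' @export
virial_B3_series <- function(chi, q) {
  1 + chi^2 * q / 2 - chi^3 * q^2 / 6
}

#' Construct a DNA chain for the Post-Zimm model
#'
#' Derives the model parameters of a DNA species of given length:
#' molecular weight \eqn{M}, lattice segment number \eqn{N} (ratio of the
#' DNA molecular volume to the solvent molecular volume), unperturbed
#' mean-square end-to-end length \eqn{\langle h_0^2\rangle}, and the
#' dimensionless flexibility measure \eqn{\omega}.
#'
#' The parameterization follows the classic Post-Zimm treatment of DNA
#' as a Gaussian chain:
#' \deqn{M = 650\,\mathrm{bp},\quad
#'       \langle h_0^2\rangle = 4\times10^{-15} M^{8/7}\ \mathrm{cm}^2,\quad
#'       N = M/4000,\quad
#'       \omega = 9\pi\,M / (N_A\,\rho\,\langle h_0^2\rangle^{3/2}),}
#' with \eqn{M} in g/mol and \eqn{\rho} the DNA density in g/cm^3.
#' \eqn{\omega} is, up to the numeric prefactor, the volume fraction a
#' chain's own segments occupy inside its unperturbed Gaussian coil; it
#' decreases with length as \eqn{M^{-5/7}} while \eqn{N\omega}, which
#' controls how easily a chain collapses, grows as \eqn{M^{2/7}} --
#' longer DNA collapses in better solvents.
#'
#' @param length_bp DNA length in base pairs (positive).
#' @param mass_per_bp Average mass per base pair, g/mol.
#' @param solvent_reference_mass Molar mass assigned to one lattice
#'   (solvent) site, g/mol; sets the segment number `N = M / this`.
#' @param h0sq_prefactor,h0sq_exponent Prefactor (cm^2) and exponent of
#'   the unperturbed end-to-end scaling law
#'   \eqn{\langle h_0^2\rangle = \mathrm{pref}\cdot M^{\mathrm{exp}}}.
#' @param rho_dna DNA density in g/cm^3 used in \eqn{\omega}.
#' @return An object of class `dna_chain` with fields `length_bp`,
#'   `molecular_weight`, `segment_number_N`, `omega`, `h0_squared`.
#' @examples
#' dna_chain(48500)  # phage lambda DNA
#' @export
dna_chain <- function(length_bp,
                      mass_per_bp = 650,
                      solvent_reference_mass = 4000,
                      h0sq_prefactor = 4e-15,
                      h0sq_exponent = 8 / 7,
                      rho_dna = 1.8) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L ||
      !is.finite(length_bp) || length_bp < 1) {
    stop("`length_bp` must be a single positive number (base pairs)")
  }
  length_bp <- as.numeric(unname(length_bp))
  M <- length_bp * mass_per_bp
  h0sq <- h0sq_prefactor * M^h0sq_exponent
  structure(
    list(
      length_bp        = length_bp,
      molecular_weight = M,
      segment_number_N = M / solvent_reference_mass,
      h0_squared       = h0sq,
      omega            = 9 * pi * M / (.AVOGADRO * rho_dna * h0sq^1.5),
      rho_dna          = rho_dna
    ),
    class = "dna_chain"
  )
}

#' @export
print.dna_chain <- function(x, ...) {
  cat(sprintf(
    "<dna_chain> %g bp | M = %.4g g/mol | N = %.4g | omega = %.4g | <h0^2> = %.4g cm^2\n",
    x$length_bp, x$molecular_weight, x$segment_number_N, x$omega, x$h0_squared
  ))
  invisible(x)
}

#' Solvent condition and virial coefficients
#'
#' Bundles the interaction parameter \eqn{\chi} with the lattice
#' coordination number `q`, the DNA density used for volume-fraction to
#' concentration conversion, and the derived virial coefficients
#' \eqn{B_2 = 1/2 - \chi} and \eqn{B_3 =} `B3_fun(chi, q)`.
#'
#' @param chi Interaction parameter; `0.5` is a theta solvent, larger
#'   values a poorer solvent.
#' @param q Lattice coordination number.
#' @param rho_dna DNA density, g/cm^3 (g/mL); converts volume fractions
#'   to mass concentrations, `c = phi * rho_dna`.
#' @param B3_fun Function of `(chi, q)` returning the third virial
#'   coefficient. Defaults to [virial_B3_regularized()].
#' @return An object of class `solvent_condition` with fields `chi`,
#'   `q`, `rho_dna`, `B2`, `B3`.
#' @export
solvent_condition <- function(chi, q = 10, rho_dna = 1.8,
                              B3_fun = virial_B3_regularized) {
  if (!is.numeric(chi) || length(chi) != 1L || !is.finite(chi)) {
    stop("`chi` must be a single finite number")
  }
  structure(
    list(chi = chi, q = q, rho_dna = rho_dna,
         B2 = 0.5 - chi, B3 = B3_fun(chi, q), B3_fun = B3_fun),
    class = "solvent_condition"
  )
}

#' @export
print.solvent_condition <- function(x, ...) {
  cat(sprintf("<solvent_condition> chi = %g | q = %g | B2 = %g | B3 = %.5g | rho = %g g/cm^3\n",
              x$chi, x$q, x$B2, x$B3, x$rho_dna))
  invisible(x)
}

.as_solvent <- function(solvent) {
  if (inherits(solvent, "solvent_condition")) solvent
  else solvent_condition(solvent)
}

# Internal ("single-chain") free energy per DNA molecule, in units of kT:
#   N[(chi - 1) + B2 w / (2^{3/2} a^3) + B3 w^2 / (2 * 3^{5/2} a^6)]
#     + (3/2)(a^2 - 1) - 3 ln a
.internal_per_chain <- function(alpha, chain, solvent) {
  N <- chain$segment_number_N
  w <- chain$omega
  N * ((solvent$chi - 1) +
         solvent$B2 * w / (2^1.5 * alpha^3) +
         solvent$B3 * w^2 / (2 * 3^2.5 * alpha^6)) +
    1.5 * (alpha^2 - 1) - 3 * log(alpha)
}

#' Intensive Flory-Huggins/Post-Zimm free energy
#'
#' Free energy of mixing per lattice site, \eqn{\Delta G V_s/(V kT)}, for
#' a DNA solution at volume fraction `phi_dna` with chain expansion
#' factor `alpha`:
#' \deqn{(1-\phi)\ln(1-\phi) + (\phi/N)\ln\phi + \chi\phi(1-\phi)
#'   + (\phi/N)\,A(\alpha),}
#' where \eqn{A(\alpha)} is the internal (single-chain) free energy
#' combining two- and three-body intersegment contacts with the elastic
#' entropy of chain deformation. The solvent site volume \eqn{V_s} never
#' needs an absolute value: it cancels in all coexistence conditions.
#'
#' @param phi_dna DNA volume fraction(s), in `[0, 1)`.
#' @param alpha Chain expansion factor(s), `> 0`.
#' @param chain A [dna_chain()].
#' @param solvent A [solvent_condition()] (or a bare `chi` value).
#' @return Dimensionless free energy per lattice site (vectorized over
#'   `phi_dna`/`alpha`).
#' @export
free_energy_intensive <- function(phi_dna, alpha, chain, solvent) {
  solvent <- .as_solvent(solvent)
  if (any(phi_dna < 0 | phi_dna >= 1)) stop("`phi_dna` must lie in [0, 1)")
  if (any(alpha <= 0)) stop("`alpha` must be positive")
  N <- chain$segment_number_N
  mix <- (1 - phi_dna) * log1p(-phi_dna) +
    ifelse(phi_dna > 0, phi_dna / N * log(phi_dna), 0) +
    solvent$chi * phi_dna * (1 - phi_dna)
  mix + phi_dna / N * .internal_per_chain(alpha, chain, solvent)
}

#' Stationarity residual of the expansion factor
#'
#' Residual of the condition \eqn{\partial \Delta G/\partial\alpha = 0}
#' for a single chain,
#' \deqn{3\alpha^8 - 3\alpha^6 - N\left(\frac{3 B_2 \omega
#'   \alpha^3}{2^{3/2}} + \frac{B_3\omega^2}{3^{3/2}}\right),}
#' whose positive roots are the stationary points of the internal free
#' energy over \eqn{\alpha}.
#'
#' @inheritParams free_energy_intensive
#' @return Residual value(s), vectorized over `alpha`.
#' @export
alpha_stationarity_residual <- function(alpha, chain, solvent) {
  solvent <- .as_solvent(solvent)
  if (any(alpha <= 0)) stop("`alpha` must be positive")
  N <- chain$segment_number_N
  w <- chain$omega
  3 * alpha^8 - 3 * alpha^6 -
    N * (3 * solvent$B2 * w * alpha^3 / 2^1.5 + solvent$B3 * w^2 / 3^1.5)
}

#' Equilibrium expansion factor of a dilute chain
#'
#' Finds the global minimum of the single-chain free energy over
#' \eqn{\alpha \in (0, \alpha_{max}]}. Stationary points are obtained as
#' the positive real roots of the degree-8 stationarity polynomial (see
#' [alpha_stationarity_residual()]); the free energy is evaluated at all
#' roots and at the upper interval boundary, and the smallest value wins.
#' For \eqn{\chi > 0.5} the minimizer is non-increasing in \eqn{\chi}:
#' the chain first contracts smoothly, then drops discontinuously into a
#' compact globule at the collapse transition.
#'
#' @inheritParams free_energy_intensive
#' @param alpha_max Upper bound of the search interval.
#' @return The minimizing `alpha` (a single number in `(0, alpha_max]`).
#' @export
expansion_alpha <- function(chain, solvent, alpha_max = 1.5) {
  solvent <- .as_solvent(solvent)
  N <- chain$segment_number_N
  w <- chain$omega
  # 3 a^8 - 3 a^6 - c1 a^3 - c0 = 0, ascending coefficients
  c1 <- 3 * N * solvent$B2 * w / 2^1.5
  c0 <- N * solvent$B3 * w^2 / 3^1.5
  rts <- polyroot(c(-c0, 0, 0, -c1, 0, 0, -3, 0, 3))
  re <- Re(rts)[abs(Im(rts)) < 1e-8 * pmax(1, abs(Re(rts)))]
  cand <- unique(c(re[re > 0 & re <= alpha_max], alpha_max))
  if (solvent$B3 <= 0) {
    warning("B3 <= 0: single-chain free energy is unbounded below as alpha -> 0; ",
            "returning the best candidate on a truncated interval")
    cand <- c(cand, 1e-6)
  }
  vals <- vapply(cand, .internal_per_chain, numeric(1),
                 chain = chain, solvent = solvent)
  if (!any(is.finite(vals))) {
    stop("expansion_alpha: no finite free-energy candidate found (N=",
         format(N), ", chi=", format(solvent$chi), ")")
  }
  cand[which.min(vals)]
}

#' Chemical potentials of DNA and solvent
#'
#' Exchange chemical potentials relative to the pure phases, in units of
#' kT, obtained by differentiating the extensive free energy with
#' respect to molecule numbers:
#' \deqn{\frac{\mu_{DNA}-\mu^0_{DNA}}{kT} = \ln\phi - (N-1)(1-\phi)
#'   + \chi N (1-\phi)^2 + A(\alpha)}
#' \deqn{\frac{\mu_{s}-\mu^0_{s}}{kT} = \ln(1-\phi) + (1-1/N)\phi
#'   + \chi\phi^2.}
#' The solvent potential does not involve \eqn{\alpha}.
#'
#' @inheritParams free_energy_intensive
#' @param phi_dna DNA volume fraction(s), strictly inside `(0, 1)`.
#' @return A list with components `mu_dna` and `mu_solvent` (vectorized).
#' @export
chemical_potentials <- function(phi_dna, alpha, chain, solvent) {
  solvent <- .as_solvent(solvent)
  if (any(phi_dna <= 0 | phi_dna >= 1)) {
    stop("`phi_dna` must lie strictly inside (0, 1)")
  }
  N <- chain$segment_number_N
  list(
    mu_dna = log(phi_dna) - (N - 1) * (1 - phi_dna) +
      solvent$chi * N * (1 - phi_dna)^2 +
      .internal_per_chain(alpha, chain, solvent),
    mu_solvent = .mu_solvent(phi_dna, N, solvent$chi)
  )
}

.mu_solvent <- function(phi, N, chi) {
  log1p(-phi) + (1 - 1 / N) * phi + chi * phi^2
}

# mu_dna as a function of u = log(phi); exact for arbitrarily negative u
# (phi underflow to 0 leaves the remaining terms at their phi -> 0 limit).
.mu_dna_log <- function(u, alpha, chain, solvent) {
  N <- chain$segment_number_N
  phi <- exp(u)
  u - (N - 1) * (1 - phi) + solvent$chi * N * (1 - phi)^2 +
    .internal_per_chain(alpha, chain, solvent)
}

#' Convert volume fraction to mass concentration (and back)
#'
#' `c = phi * rho` with `rho` the DNA density in g/cm^3, giving g/mL.
#'
#' @param phi DNA volume fraction.
#' @param concentration Mass concentration in g/mL.
#' @param rho_dna DNA density, g/cm^3.
#' @return Concentration in g/mL, or volume fraction.
#' @export
phi_to_concentration <- function(phi, rho_dna = 1.8) phi * rho_dna

#' @rdname phi_to_concentration
#' @export
concentration_to_phi <- function(concentration, rho_dna = 1.8) {
  concentration / rho_dna
}

# Spinodal-like extrema of mu_solvent(phi): roots of
#   2 chi phi^2 - (2 chi - 1 + 1/N) phi + 1/N = 0.
# Between them mu_solvent is increasing; coexistence needs them real.
.mu_solvent_extrema <- function(N, chi) {
  b <- 2 * chi - 1 + 1 / N
  disc <- b^2 - 8 * chi / N
  if (disc <= 0) return(NULL)
  s <- sqrt(disc)
  c(lo = (b - s) / (4 * chi), hi = (b + s) / (4 * chi))
}

#' Coexisting phases of a DNA solution (binodal point)
#'
#' Solves for the dilute and dense volume fractions at which DNA and
#' solvent chemical potentials are simultaneously equal between the two
#' phases. The dilute-phase expansion factor is the collapse solution
#' [expansion_alpha()] at the given `chi`; the dense phase uses the
#' unperturbed (theta-solvent, `chi = 0.5`) expansion factor, because
#' intermolecular contacts in the condensate substitute for the
#' intramolecular contacts that drive single-chain collapse
#' (`alpha_dense = "theta"`; set `"unity"` to pin it at exactly 1).
#'
#' Numerically, the dilute branch is parameterized by \eqn{u = \ln\phi_1}
#' (so chromosome-scale chains whose dilute fraction underflows double
#' precision are still solved exactly); for each \eqn{u} the dense
#' \eqn{\phi_2} matching the solvent potential is found on the monotone
#' branch above the upper extremum of \eqn{\mu_s}, and the outer root of
#' the DNA-potential mismatch is bracketed and polished with
#' [stats::uniroot()].
#'
#' @param chain A [dna_chain()].
#' @param chi Interaction parameter, or a [solvent_condition()].
#' @param alpha_dense `"theta"` (default) or `"unity"`.
#' @param tol Convergence tolerance on the chemical-potential residuals
#'   (the DNA residual is assessed per segment, `|d mu_DNA| / max(1, N)`).
#' @return An object of class `binodal_point`: a list with `chi`,
#'   `coexists`, `phi_dilute`, `phi_dense`, `c_dilute`, `c_dense`
#'   (g/mL), `log10_c_dilute` (exact even when `c_dilute` underflows),
#'   `alpha_dilute`, `alpha_dense`, `residual_mu_dna`,
#'   `residual_mu_solvent`. Below the critical point `coexists` is
#'   `FALSE` and the phase fields are `NA` (no error is thrown).
#' @examples
#' binodal_point(dna_chain(200), 0.7)   # ~0.16 g/mL dilute branch
#' @export
binodal_point <- function(chain, chi, alpha_dense = c("theta", "unity"),
                          tol = 1e-8) {
  solvent <- .as_solvent(chi)
  alpha_dense <- match.arg(alpha_dense)
  chi <- solvent$chi
  N <- chain$segment_number_N
  rho <- solvent$rho_dna

  no_coex <- structure(
    list(chi = chi, coexists = FALSE, phi_dilute = NA_real_,
         phi_dense = NA_real_, c_dilute = NA_real_, c_dense = NA_real_,
         log10_c_dilute = NA_real_, alpha_dilute = NA_real_,
         alpha_dense = NA_real_, residual_mu_dna = NA_real_,
         residual_mu_solvent = NA_real_),
    class = "binodal_point")

  ext <- .mu_solvent_extrema(N, chi)
  if (is.null(ext) || chi <= 0.5) return(no_coex)
  pha <- ext[["lo"]]; phb <- ext[["hi"]]

  a1 <- expansion_alpha(chain, solvent)
  ad <- if (alpha_dense == "unity") 1 else {
    expansion_alpha(chain, solvent_condition(0.5, q = solvent$q,
                                             rho_dna = rho,
                                             B3_fun = solvent$B3_fun))
  }

  msb <- .mu_solvent(phb, N, chi)
  dense_phi <- function(t) {
    # mu_solvent is strictly decreasing on [phb, 1): unique match if t < msb
    if (!(t < msb)) return(NA_real_)
    uniroot(function(p) .mu_solvent(p, N, chi) - t,
            c(phb, 1 - 1e-12), tol = 1e-15)$root
  }
  mismatch <- function(u) {
    t <- .mu_solvent(exp(u), N, chi)
    p2 <- dense_phi(t)
    if (is.na(p2)) return(NA_real_)
    .mu_dna_log(u, a1, chain, solvent) -
      .mu_dna_log(log(p2), ad, chain, solvent)
  }

  uhi <- log(pha) - 1e-10
  hhi <- mismatch(uhi)
  if (is.na(hhi) || hhi < 0) return(no_coex)
  if (msb < 0) {
    # dilute window is bounded below: phi_c solves mu_s(phi_c) = mu_s(phb)
    phc <- uniroot(function(p) .mu_solvent(p, N, chi) - msb,
                   c(pha * 1e-10, pha), tol = 1e-15)$root
    ulo <- log(phc)
    hlo <- NA_real_
    for (eps in c(1e-11, 1e-8, 1e-6, 1e-4)) {
      hlo <- mismatch(ulo + eps)
      if (!is.na(hlo)) { ulo <- ulo + eps; break }
    }
  } else {
    ulo <- uhi - 1
    for (k in 1:80) {
      hlo <- mismatch(ulo)
      if (!is.na(hlo) && hlo < 0) break
      ulo <- uhi - 2^k
    }
  }
  if (is.na(hlo) || hlo * hhi > 0) return(no_coex)

  root <- uniroot(mismatch, c(ulo, uhi), tol = 1e-13)
  u <- root$root
  p1 <- exp(u)
  p2 <- dense_phi(.mu_solvent(p1, N, chi))
  res_s <- .mu_solvent(p1, N, chi) - .mu_solvent(p2, N, chi)
  res_d <- (.mu_dna_log(u, a1, chain, solvent) -
              .mu_dna_log(log(p2), ad, chain, solvent)) / max(1, N)
  if (abs(res_s) > tol || abs(res_d) > tol) {
    stop(sprintf("binodal solver did not reach tolerance (residuals %.3g / %.3g)",
                 res_s, res_d))
  }
  structure(
    list(chi = chi, coexists = TRUE,
         phi_dilute = p1, phi_dense = p2,
         c_dilute = p1 * rho, c_dense = p2 * rho,
         log10_c_dilute = (u + log(rho)) / log(10),
         alpha_dilute = a1, alpha_dense = ad,
         residual_mu_dna = res_d, residual_mu_solvent = res_s),
    class = "binodal_point")
}

#' @export
print.binodal_point <- function(x, ...) {
  if (!x$coexists) {
    cat(sprintf("<binodal_point> chi = %g: no coexistence (below critical point)\n", x$chi))
  } else {
    cat(sprintf(
      "<binodal_point> chi = %g | c_dilute = %.4g g/mL | c_dense = %.4g g/mL | alpha_dilute = %.4g\n",
      x$chi, x$c_dilute, x$c_dense, x$alpha_dilute))
  }
  invisible(x)
}

#' Phase diagram of a DNA chain over a chi grid
#'
#' Computes the binodal branch at every grid `chi` where two phases
#' coexist, together with the dilute-solution collapse boundary. The
#' collapse transition is located as the smallest grid `chi` at which
#' the equilibrium expansion factor either drops below
#' `collapse_threshold` or jumps down by more than `collapse_jump`
#' between adjacent grid points, whichever happens first.
#'
#' @param chain A [dna_chain()].
#' @param chi_grid Increasing vector of interaction parameters.
#' @param collapse_threshold Expansion factor below which a chain counts
#'   as collapsed.
#' @param collapse_jump Discontinuity in `alpha` between adjacent grid
#'   points that also flags the collapse transition.
#' @param ... Passed to [binodal_point()].
#' @return An object of class `phase_diagram`: list with `chain`,
#'   `collapse_chi` (NA if no collapse on the grid) and `table`, a
#'   data.frame with one row per `chi` (columns `chi`, `alpha_dilute`,
#'   `phi_dilute`, `phi_dense`, `c_dilute_g_per_mL`, `c_dense_g_per_mL`,
#'   `log10_c_dilute`, `coexists`).
#' @export
phase_diagram <- function(chain, chi_grid, collapse_threshold = 0.5,
                          collapse_jump = 0.2, ...) {
  if (length(chi_grid) == 0) stop("`chi_grid` must be non-empty")
  if (is.unsorted(chi_grid, strictly = TRUE)) {
    stop("`chi_grid` must be sorted in increasing order")
  }
  pts <- lapply(chi_grid, function(chi) binodal_point(chain, chi, ...))
  alpha <- vapply(chi_grid, function(chi) {
    expansion_alpha(chain, solvent_condition(chi))
  }, numeric(1))

  collapsed <- alpha < collapse_threshold
  jumped <- c(FALSE, -diff(alpha) > collapse_jump)
  hit <- which(collapsed | jumped)
  collapse_chi <- if (length(hit)) chi_grid[min(hit)] else NA_real_

  tab <- data.frame(
    chi = chi_grid,
    alpha_dilute = alpha,
    phi_dilute = vapply(pts, `[[`, numeric(1), "phi_dilute"),
    phi_dense = vapply(pts, `[[`, numeric(1), "phi_dense"),
    c_dilute_g_per_mL = vapply(pts, `[[`, numeric(1), "c_dilute"),
    c_dense_g_per_mL = vapply(pts, `[[`, numeric(1), "c_dense"),
    log10_c_dilute = vapply(pts, `[[`, numeric(1), "log10_c_dilute"),
    coexists = vapply(pts, `[[`, logical(1), "coexists")
  )
  structure(list(chain = chain, table = tab, collapse_chi = collapse_chi,
                 collapse_threshold = collapse_threshold),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %g bp chain | %d chi values | collapse chi: %s\n",
              x$chain$length_bp, nrow(x$table),
              if (is.na(x$collapse_chi)) "none on grid" else format(x$collapse_chi)))
  invisible(x)
}
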