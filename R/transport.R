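#' Quantum of conductance, 2 e^2 / h, in siemens
#'
#' The conductance of one fully transmitting spin-degenerate channel
#' (7.748092e-5 S); zero-bias conductance is `G0 * T_eff` at the Fermi
#' energy.
#' @export
G0_SIEMENS <- 2 * 1.602176634e-19^2 / 6.62607015e-34

#' Contact specification for two-terminal transport with decoherence probes
#'
#' Declares which atoms touch the left and right electrodes and the
#' energy-independent coupling strengths: `gamma_contact` is the electrode
#' broadening applied to every orbital of a contact atom (default 0.600 eV),
#' `gamma_probe` the Buettiker-probe broadening on every non-contact atom
#' (default 0.010 eV). The electrodes themselves are represented by these
#' broadening matrices only; no metal or linker atoms are modeled.
#'
#' @param left_atoms,right_atoms Disjoint, nonempty vectors of `atom_id`s.
#' @param gamma_contact Left/right electrode coupling, eV (> 0).
#' @param gamma_probe Probe coupling, eV (>= 0; 0 gives coherent transport).
#' @param temperature Kelvin; recorded for provenance, unused by the
#'   zero-bias linearization (default 300).
#' @param mu_left,mu_right Electrode chemical potentials (eV). Only their
#'   difference enters the linear-response quantities.
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(left_atoms, right_atoms,
                         gamma_contact = 0.600, gamma_probe = 0.010,
                         temperature = 300, mu_left = 0.5, mu_right = -0.5) {
  if (length(left_atoms) == 0L || length(right_atoms) == 0L)
    stop("spec error: both contact atom sets must be nonempty", call. = FALSE)
  if (length(intersect(left_atoms, right_atoms)))
    stop("spec error: atoms ",
         paste(intersect(left_atoms, right_atoms), collapse = ", "),
         " appear in both contacts", call. = FALSE)
  if (gamma_contact <= 0)
    stop("spec error: gamma_contact must be > 0", call. = FALSE)
  if (gamma_probe < 0)
    stop("spec error: gamma_probe must be >= 0", call. = FALSE)
  structure(
    list(left_atoms = left_atoms, right_atoms = right_atoms,
         gamma_contact = gamma_contact, gamma_probe = gamma_probe,
         temperature = temperature, mu_left = mu_left, mu_right = mu_right),
    class = "contact_spec")
}

#' Build contact and probe self-energies
#'
#' The left/right contact self-energies carry `-i * gamma_contact / 2` on
#' every orbital of their atoms; every remaining atom receives its own
#' Buettiker probe with `-i * gamma_probe / 2` on its orbitals. All
#' off-diagonal elements are zero, and each broadening matrix is
#' `Gamma_i = i (Sigma_i - Sigma_i^dagger)`, i.e. `+Gamma` on the coupled
#' orbitals.
#'
#' @param spec A [contact_spec()].
#' @param atoms Atom annotation table of the system.
#' @return An object of class `self_energies`: full matrices `sigma_left`,
#'   `sigma_right`, `sigma_probe`, `sigma_total`, broadenings `gamma_left`,
#'   `gamma_right`, per-terminal diagonal columns `gamma_cols` (orbitals x
#'   terminals, order `L`, `R`, `probe_<atom_id>`...), probe bookkeeping
#'   (`probe_atoms`, `n_probes`), and the originating `spec`.
#' @export
build_self_energies <- function(spec, atoms) {
  n <- sum(atoms$orbital_count)
  orb_l <- atom_orbitals(atoms, spec$left_atoms)
  orb_r <- atom_orbitals(atoms, spec$right_atoms)
  probe_atoms <- setdiff(atoms$atom_id, c(spec$left_atoms, spec$right_atoms))
  gamma_cols <- matrix(0, n, 2L + length(probe_atoms))
  colnames(gamma_cols) <- c("L", "R",
                            if (length(probe_atoms)) paste0("probe_", probe_atoms))
  gamma_cols[orb_l, 1L] <- spec$gamma_contact
  gamma_cols[orb_r, 2L] <- spec$gamma_contact
  for (k in seq_along(probe_atoms))
    gamma_cols[atom_orbitals(atoms, probe_atoms[k]), 2L + k] <- spec$gamma_probe
  diag_mat <- function(v) diag(v, nrow = n)
  sigma_left <- diag_mat(-0.5i * gamma_cols[, 1L])
  sigma_right <- diag_mat(-0.5i * gamma_cols[, 2L])
  probe_diag <- if (length(probe_atoms))
    rowSums(gamma_cols[, -(1:2), drop = FALSE]) else numeric(n)
  sigma_probe <- diag_mat(-0.5i * probe_diag)
  structure(
    list(sigma_left = sigma_left, sigma_right = sigma_right,
         sigma_probe = sigma_probe,
         sigma_total = sigma_left + sigma_right + sigma_probe,
         gamma_left = diag_mat(gamma_cols[, 1L]),
         gamma_right = diag_mat(gamma_cols[, 2L]),
         gamma_cols = gamma_cols,
         probe_atoms = probe_atoms, n_probes = length(probe_atoms),
         spec = spec, n_orb = n),
    class = "self_energies")
}

#' Retarded Green's function
#'
#' Solves `((E + i*eta) I - H - Sigma) G^r = I`. The advanced function is
#' the conjugate transpose of the returned matrix. `eta` is a numerical
#' safety floor only; physical broadening enters through `Sigma`.
#'
#' @param E Energy, eV.
#' @param H Hermitian Hamiltonian (eV), typically the atom-block matrix.
#' @param sigma_total Total self-energy matrix (complex).
#' @param eta Small positive imaginary part, eV (default `1e-6`).
#' @return Complex `n x n` matrix `G^r(E)`.
#' @export
retarded_green <- function(E, H, sigma_total = NULL, eta = 1e-6) {
  n <- nrow(H)
  a <- diag(complex(real = E, imaginary = eta), n) - H
  if (!is.null(sigma_total)) a <- a - sigma_total
  g <- tryCatch(solve(a),
                error = function(e)
                  stop(sprintf(paste0(
                    "near-singularity at E = %.6f eV: %s; use a nonzero eta ",
                    "or broadening"), E, conditionMessage(e)), call. = FALSE))
  g
}

#' Pairwise terminal-to-terminal transmissions at one energy
#'
#' Evaluates `T_ij = trace(Gamma_i G^r Gamma_j G^a)` for every pair of
#' terminals. With the diagonal couplings used throughout, this reduces to
#' `sum_{a in i, b in j} Gamma_i[a] Gamma_j[b] |G^r_ab|^2`, which is how it
#' is computed. The reflection at each probe follows from flux conservation,
#' `R_ii = 1 - sum_{j != i} T_ij`, and `W` is the probe-block matrix
#' `(1 - R_ii) delta_ij - T_ij (1 - delta_ij)` used to float the probe
#' potentials.
#'
#' @param G Retarded Green's function at the evaluation energy.
#' @param broadenings Either a `self_energies` object or a named list of
#'   diagonal broadening matrices; by convention the first two entries are
#'   the left and right electrodes and the remainder are probes.
#' @param energy Energy label stored in the result (eV).
#' @return An object of class `transmission_set` with fields `energy`,
#'   `tmat` (terminals x terminals), `reflections` (per probe), `W`
#'   (probes x probes), `terminals`, `mu_probes` (filled by
#'   [probe_potentials()]).
#' @export
pairwise_transmission <- function(G, broadenings, energy = NA_real_) {
  if (inherits(broadenings, "self_energies")) {
    gamma_cols <- broadenings$gamma_cols
  } else {
    gamma_cols <- do.call(cbind, lapply(broadenings, function(g) {
      g <- as.matrix(g)
      if (max(abs(g - diag(diag(g), nrow(g)))) > 0)
        stop("not supported: non-diagonal broadening matrices", call. = FALSE)
      d <- Re(diag(g))
      if (any(d < 0))
        stop("broadening matrices must be nonnegative", call. = FALSE)
      d
    }))
    if (is.null(colnames(gamma_cols)))
      colnames(gamma_cols) <- c("L", "R",
        if (ncol(gamma_cols) > 2) paste0("probe_", seq_len(ncol(gamma_cols) - 2L)))
  }
  a2 <- abs(G)^2
  tmat <- t(gamma_cols) %*% a2 %*% gamma_cols
  dimnames(tmat) <- list(colnames(gamma_cols), colnames(gamma_cols))
  transmission_set(tmat, energy)
}

transmission_set <- function(tmat, energy = NA_real_) {
  terminals <- colnames(tmat)
  probes <- terminals[-(1:2)]
  np <- length(probes)
  # flux-conservation reflection and the Buettiker W matrix (probe block)
  offdiag_sums <- rowSums(tmat) - diag(tmat)
  reflections <- 1 - offdiag_sums[probes]
  if (np) {
    W <- -tmat[probes, probes, drop = FALSE]
    diag(W) <- offdiag_sums[probes]
  } else {
    W <- matrix(0, 0, 0)
  }
  structure(
    list(energy = energy, tmat = tmat, reflections = reflections, W = W,
         terminals = terminals, probes = probes, mu_probes = NULL),
    class = "transmission_set")
}

W_RCOND_LIMIT <- 1e-12  # condition number > 1e12 is treated as singular
W_DECOUPLED <- 1e-30    # a probe with W_ii below this carries no flux at all

#' Floating probe chemical potentials (zero-current condition)
#'
#' Solves `W x = b`, `b_i = T_iL mu_L + T_iR mu_R`, so that the net
#' linear-response current into every probe vanishes. Probes that are
#' completely decoupled (zero row in `W`, e.g. when `gamma_probe = 0`) carry
#' no current at any potential and are reported at potential 0.
#'
#' @param ts A `transmission_set`.
#' @param mu_left,mu_right Electrode chemical potentials (eV).
#' @return The `transmission_set` with `mu_probes` filled (named numeric).
#' @export
probe_potentials <- function(ts, mu_left, mu_right) {
  np <- length(ts$probes)
  if (np == 0L) {
    ts$mu_probes <- numeric(0)
    return(ts)
  }
  b <- ts$tmat[ts$probes, "L"] * mu_left + ts$tmat[ts$probes, "R"] * mu_right
  mu <- stats::setNames(numeric(np), ts$probes)
  active <- diag(ts$W) > W_DECOUPLED
  if (any(active)) {
    Wa <- ts$W[active, active, drop = FALSE]
    rc <- rcond(Wa)
    if (rc < W_RCOND_LIMIT)
      stop(sprintf(paste0(
        "ill-conditioned probe system at E = %s eV (rcond %.2e): ",
        "a probe is effectively decoupled from the contacts"),
        format(ts$energy), rc), call. = FALSE)
    mu[active] <- solve(Wa, b[active])
  }
  ts$mu_probes <- mu
  ts
}

#' Net linear-response current at every terminal
#'
#' `I_i = sum_j T_ij (mu_i - mu_j)` over all terminals, in units of
#' `(2e/h) * eV`. After [probe_potentials()], every probe current is zero
#' and the total over all terminals vanishes.
#'
#' @param ts A `transmission_set` with `mu_probes` filled.
#' @param mu_left,mu_right Electrode chemical potentials (eV).
#' @return Named numeric vector over `L`, `R` and the probes.
#' @export
terminal_currents <- function(ts, mu_left, mu_right) {
  if (is.null(ts$mu_probes))
    stop("call probe_potentials() first", call. = FALSE)
  mu <- c(L = mu_left, R = mu_right, ts$mu_probes)[ts$terminals]
  tm <- ts$tmat
  vapply(seq_along(mu), function(i)
    sum(tm[i, -i] * (mu[i] - mu[-i])), numeric(1)) |>
    stats::setNames(ts$terminals)
}

#' Effective (decoherent) transmission
#'
#' `T_eff = T_LR + sum_{ij in probes} T_Li (W^{-1})_ij T_jR`: the direct
#' left-right transmission plus the probe-mediated decoherent contribution.
#' `W` is an M-matrix, so the correction is nonnegative and decoherence
#' never reduces the transmission below the coherent value.
#'
#' @param ts A `transmission_set`.
#' @return Scalar `T_eff`.
#' @export
effective_transmission <- function(ts) {
  t_lr <- ts$tmat["L", "R"]
  np <- length(ts$probes)
  if (np == 0L) return(t_lr)
  active <- diag(ts$W) > W_DECOUPLED
  if (!any(active)) return(t_lr)
  Wa <- ts$W[active, active, drop = FALSE]
  rc <- rcond(Wa)
  if (rc < W_RCOND_LIMIT)
    stop(sprintf(
      "ill-conditioned probe system at E = %s eV (rcond %.2e)",
      format(ts$energy), rc), call. = FALSE)
  t_l <- ts$tmat[ts$probes, "L"][active]
  t_r <- ts$tmat[ts$probes, "R"][active]
  t_lr + drop(t_l %*% solve(Wa, t_r))
}

teff_at_energy <- function(H, se, E, eta = 1e-6) {
  G <- retarded_green(E, H, se$sigma_total, eta = eta)
  ts <- pairwise_transmission(G, se, energy = E)
  list(t_direct = ts$tmat["L", "R"], t_eff = effective_transmission(ts),
       ts = ts)
}

#' Transmission spectrum and zero-bias conductance
#'
#' Runs the per-energy pipeline retarded Green's function -> pairwise
#' transmissions -> effective transmission over an energy grid, and reports
#' the zero-bias conductance `G = G0 * T_eff(E_F)`. The Fermi energy
#' defaults to the HOMO (plus `fermi_offset`), following the convention of
#' aligning transport curves at the HOMO.
#'
#' @param system `electronic_system` or `atom_block_hamiltonian`.
#' @param spec A [contact_spec()].
#' @param grid Energy grid (eV), sorted; default spans HOMO - 3 eV to
#'   LUMO + 1 eV with `npoints` points.
#' @param fermi `"homo"` or a numeric energy (eV); must lie inside the grid.
#' @param fermi_offset Offset added to the Fermi energy, eV.
#' @param eta Numerical broadening floor for the Green's function.
#' @param npoints Number of grid points when `grid` is `NULL`.
#' @return Object of class `transport_result`: `energies`, `t_direct`,
#'   `t_eff`, `conductance` (siemens, at `fermi_energy`), `fermi_energy`,
#'   `fermi_t_eff`, `contact`, `flagged_energies` (grid points where the
#'   probe system was ill-conditioned; their `t_eff` is `NA`).
#' @export
transmission_spectrum <- function(system, spec, grid = NULL, fermi = "homo",
                                  fermi_offset = 0, eta = 1e-6,
                                  npoints = 400) {
  abh <- as_atom_blocks(system)
  se <- build_self_energies(spec, abh$atoms)
  H <- abh$matrix
  need_levels <- is.null(grid) ||
    (is.character(fermi) && identical(fermi, "homo"))
  lev <- if (need_levels) spectrum_analysis(abh) else NULL
  if (is.null(grid))
    grid <- seq(lev$homo - 3, lev$lumo + 1, length.out = npoints)
  if (is.unsorted(grid)) stop("grid must be sorted", call. = FALSE)
  fermi_e <- if (is.character(fermi)) lev$homo + fermi_offset
             else fermi + fermi_offset
  if (fermi_e < min(grid) || fermi_e > max(grid))
    stop(sprintf(
      "interpolation-range error: fermi energy %.4f eV outside grid [%.4f, %.4f]",
      fermi_e, min(grid), max(grid)), call. = FALSE)
  eval_one <- function(E) {
    tryCatch({
      r <- teff_at_energy(H, se, E, eta = eta)
      c(r$t_direct, r$t_eff)
    }, error = function(e) c(NA_real_, NA_real_))
  }
  res <- vapply(grid, eval_one, numeric(2))
  fermi_point <- teff_at_energy(H, se, fermi_e, eta = eta)
  structure(
    list(energies = grid, t_direct = res[1L, ], t_eff = res[2L, ],
         fermi_energy = fermi_e, fermi_t_eff = fermi_point$t_eff,
         conductance = G0_SIEMENS * fermi_point$t_eff,
         homo = if (need_levels) lev$homo else NA_real_,
         contact = spec,
         flagged_energies = grid[is.na(res[2L, ])]),
    class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<transport_result> %d energies [%.3f, %.3f] eV\n",
    "  E_F = %.4f eV, T_eff(E_F) = %.4e, G = %.4e S\n"),
    length(x$energies), min(x$energies), max(x$energies),
    x$fermi_energy, x$fermi_t_eff, x$conductance))
  if (length(x$flagged_energies))
    cat("  flagged (ill-conditioned) energies:",
        length(x$flagged_energies), "\n")
  invisible(x)
}
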