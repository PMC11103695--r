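#' Enumerate terminal-base electrode placements
#'
#' Electrodes contact only terminal-base atoms. For a single duplex the one
#' scheme is `ds_end_to_end`; for a two-helix origami the catalog holds the
#' five placements `helix_1_to_1`, `helix_2_to_2`, `helix_1_to_2`,
#' `helix_2_to_1` and `both` (the union of the two same-helix schemes on
#' each side). Each helix end is identified from the annotations:
#' `region == "terminal"` base atoms at the minimum (`A`) or maximum (`B`)
#' helix coordinate `hpos`.
#'
#' @param system An `electronic_system` whose atom table carries `hpos`.
#' @param contact `"base_pair"` (default: both bases of the terminal pair)
#'   or `"single_base"` (only the leading strand's terminal base).
#' @return Object of class `scheme_catalog`: named list of
#'   `list(left, right)` atom-id sets, plus `helices` and `contact` fields.
#' @export
enumerate_schemes <- function(system, contact = c("base_pair", "single_base")) {
  contact <- match.arg(contact)
  at <- system$atoms
  if (!"hpos" %in% names(at))
    stop("catalog error: atom table lacks the helix coordinate column hpos",
         call. = FALSE)
  helices <- sort(unique(at$helix_id))
  term <- at[at$region == "terminal" & at$base_label != "backbone", ,
             drop = FALSE]
  missing <- setdiff(helices, unique(term$helix_id))
  if (length(missing))
    stop("catalog error: no terminal base atoms annotated for helix ",
         paste(missing, collapse = ", "), call. = FALSE)
  end_atoms <- function(helix, end) {
    th <- term[term$helix_id == helix, , drop = FALSE]
    h <- if (end == "A") min(th$hpos) else max(th$hpos)
    sel <- th[th$hpos == h, , drop = FALSE]
    if (contact == "single_base") {
      lead <- min(sel$strand_id)  # leading strand: lowest roman label
      sel <- sel[sel$strand_id == lead, , drop = FALSE]
    }
    sel$atom_id
  }
  schemes <-
    if (length(helices) == 1L) {
      list(ds_end_to_end = list(left = end_atoms(helices, "A"),
                                right = end_atoms(helices, "B")))
    } else if (length(helices) == 2L) {
      h1 <- helices[1L]; h2 <- helices[2L]
      s11 <- list(left = end_atoms(h1, "A"), right = end_atoms(h1, "B"))
      s22 <- list(left = end_atoms(h2, "A"), right = end_atoms(h2, "B"))
      list(helix_1_to_1 = s11,
           helix_2_to_2 = s22,
           helix_1_to_2 = list(left = s11$left, right = s22$right),
           helix_2_to_1 = list(left = s22$left, right = s11$right),
           both = list(left = c(s11$left, s22$left),
                       right = c(s11$right, s22$right)))
    } else {
      stop("catalog error: expected 1 or 2 helices, found ", length(helices),
           call. = FALSE)
    }
  for (nm in names(schemes))
    if (length(intersect(schemes[[nm]]$left, schemes[[nm]]$right)))
      stop("catalog error: scheme ", nm, " has overlapping sides",
           call. = FALSE)
  structure(c(schemes, list(.helices = helices, .contact = contact)),
            class = "scheme_catalog")
}

scheme_names <- function(catalog) setdiff(names(catalog), c(".helices", ".contact"))

#' @export
print.scheme_catalog <- function(x, ...) {
  nms <- scheme_names(x)
  cat(sprintf("<scheme_catalog> %d scheme(s), contact = %s\n",
              length(nms), x$.contact))
  for (nm in nms)
    cat(sprintf("  %-14s left {%s} right {%s}\n", nm,
                paste(x[[nm]]$left, collapse = ","),
                paste(x[[nm]]$right, collapse = ",")))
  invisible(x)
}

#' Conductance sweep over contact schemes and Fermi offsets
#'
#' For every scheme and every offset, evaluates the effective transmission
#' at `E_F = HOMO + offset` (each system's own HOMO, i.e. on the
#' HOMO-aligned axis) and reports `G = G0 * T_eff` together with the ratio
#' to a reference: the companion duplex's `ds_end_to_end` conductance at the
#' same offset when `reference_system` is given, otherwise a reference
#' scheme of this system (default `helix_1_to_1`, or the catalog's first
#' scheme).
#'
#' @param system An `electronic_system` or `atom_block_hamiltonian`.
#' @param catalog Optional [enumerate_schemes()] catalog (built from
#'   `system` when `NULL`; then `system` must be an `electronic_system`).
#' @param fermi_offsets Offsets above the HOMO, eV (default
#'   `c(0, 0.1, 0.2, 0.3)`).
#' @param gamma_contact,gamma_probe Couplings passed to [contact_spec()].
#' @param reference_system Optional companion duplex used as the ratio
#'   reference.
#' @param reference_scheme Scheme name used as reference when no companion
#'   system is given.
#' @param eta Green's-function broadening floor.
#' @return Data frame of class `comparison_table`: `scheme`, `fermi_offset`,
#'   `t_eff`, `conductance` (S), `ratio` (to the reference at the same
#'   offset); reference identity in attributes `reference` /
#'   `reference_conductance`.
#' @export
conductance_sweep <- function(system, catalog = NULL,
                              fermi_offsets = c(0, 0.1, 0.2, 0.3),
                              gamma_contact = 0.600, gamma_probe = 0.010,
                              reference_system = NULL,
                              reference_scheme = NULL, eta = 1e-6) {
  stopifnot(all(is.finite(fermi_offsets)))
  if (is.null(catalog)) catalog <- enumerate_schemes(system)
  abh <- as_atom_blocks(system)
  homo <- spectrum_analysis(abh)$homo
  nms <- scheme_names(catalog)
  teff_for <- function(abh_i, scheme, homo_i) {
    se <- build_self_energies(
      contact_spec(scheme$left, scheme$right,
                   gamma_contact = gamma_contact, gamma_probe = gamma_probe),
      abh_i$atoms)
    vapply(fermi_offsets, function(off)
      teff_at_energy(abh_i$matrix, se, homo_i + off, eta = eta)$t_eff,
      numeric(1))
  }
  teff <- vapply(nms, function(nm) teff_for(abh, catalog[[nm]], homo),
                 numeric(length(fermi_offsets)))
  teff <- matrix(teff, nrow = length(fermi_offsets),
                 dimnames = list(NULL, nms))
  if (!is.null(reference_system)) {
    ref_cat <- enumerate_schemes(reference_system,
                                 contact = catalog$.contact)
    if (!"ds_end_to_end" %in% scheme_names(ref_cat))
      stop("configuration error: reference system is not a single duplex",
           call. = FALSE)
    ref_abh <- as_atom_blocks(reference_system)
    ref_homo <- spectrum_analysis(ref_abh)$homo
    ref_teff <- teff_for(ref_abh, ref_cat$ds_end_to_end, ref_homo)
    ref_label <- "ds_end_to_end (companion duplex)"
  } else {
    if (is.null(reference_scheme))
      reference_scheme <- if ("helix_1_to_1" %in% nms) "helix_1_to_1"
                          else nms[1L]
    if (!reference_scheme %in% nms)
      stop("configuration error: reference scheme ", reference_scheme,
           " is not in the catalog", call. = FALSE)
    ref_teff <- teff[, reference_scheme]
    ref_label <- reference_scheme
  }
  out <- do.call(rbind, lapply(nms, function(nm)
    data.frame(scheme = nm, fermi_offset = fermi_offsets,
               t_eff = teff[, nm],
               conductance = G0_SIEMENS * teff[, nm],
               ratio = teff[, nm] / ref_teff)))
  rownames(out) <- NULL
  attr(out, "reference") <- ref_label
  attr(out, "reference_conductance") <- G0_SIEMENS * ref_teff
  attr(out, "fermi_offsets") <- fermi_offsets
  class(out) <- c("comparison_table", class(out))
  out
}

#' Crossover barrier diagnostics
#'
#' Quantifies the two signatures of the crossover acting as an energy
#' barrier: (a) the fraction of the density of states carried by
#' crossover-region atoms in the window `[HOMO - window, HOMO]`, and (b)
#' the conductance ratio of cross-helix to same-helix contact schemes at
#' `E_F = HOMO`. The structure is flagged `barrier_like` when the DOS
#' fraction is below `fraction_limit` (default 0.05) and the conductance
#' ratio is below 1.
#'
#' @param system An `electronic_system`.
#' @param gamma_contact,gamma_probe Transport couplings, eV.
#' @param window Width of the DOS window below the HOMO, eV (default 0.3).
#' @param fraction_limit DOS-fraction threshold for the flag.
#' @param n_grid DOS grid points inside the window.
#' @param eta Green's-function broadening floor.
#' @return List of class `crossover_report`: `has_crossover`,
#'   `dos_fraction`, `conductance_ratio`, `barrier_like`, `window`,
#'   and the per-scheme conductances used. For a system without crossover
#'   atoms the report is empty (`has_crossover = FALSE`).
#' @export
crossover_barrier_report <- function(system, gamma_contact = 0.600,
                                     gamma_probe = 0.010, window = 0.3,
                                     fraction_limit = 0.05, n_grid = 61,
                                     eta = 1e-6) {
  xo <- system$atoms$atom_id[system$atoms$region == "crossover"]
  if (length(xo) == 0L) {
    return(structure(list(has_crossover = FALSE, dos_fraction = NA_real_,
                          conductance_ratio = NA_real_, barrier_like = NA,
                          window = window),
                     class = "crossover_report"))
  }
  abh <- as_atom_blocks(system)
  homo <- spectrum_analysis(abh)$homo
  catalog <- enumerate_schemes(system)
  # DOS of the fully contacted device (`both` scheme)
  spec <- contact_spec(catalog$both$left, catalog$both$right,
                       gamma_contact = gamma_contact,
                       gamma_probe = gamma_probe)
  grid <- seq(homo - window, homo, length.out = n_grid)
  field <- per_atom_dos(abh, spec, grid, eta = eta)
  frac <- dos_window_fraction(field, c(homo - window, homo), atom_ids = xo)
  sweep <- conductance_sweep(system, catalog, fermi_offsets = 0,
                             gamma_contact = gamma_contact,
                             gamma_probe = gamma_probe, eta = eta)
  g <- stats::setNames(sweep$conductance, sweep$scheme)
  cross <- mean(g[c("helix_1_to_2", "helix_2_to_1")])
  same <- mean(g[c("helix_1_to_1", "helix_2_to_2")])
  ratio <- cross / same
  structure(
    list(has_crossover = TRUE, dos_fraction = frac,
         conductance_ratio = ratio,
         barrier_like = (frac < fraction_limit) && (ratio < 1),
         window = window, conductance = g, homo = homo),
    class = "crossover_report")
}

#' @export
print.crossover_report <- function(x, ...) {
  if (!x$has_crossover) {
    cat("<crossover_report> no crossover atoms in this system\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<crossover_report> DOS fraction on crossover atoms in [HOMO-%.2f, HOMO]: ",
    "%.4f\n  cross-helix / same-helix conductance at E_F = HOMO: %.4f\n",
    "  barrier-like: %s\n"),
    x$window, x$dos_fraction, x$conductance_ratio, x$barrier_like))
  invisible(x)
}
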