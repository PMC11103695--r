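#' Per-atom density of states
#'
#' `D_m(E) = -(1/pi) * sum_{a in atom m} Im G^r_aa(E)`, evaluated with the
#' same Green's function as the transport calculation (contact and probe
#' self-energies included), so DOS and transmission describe the same open
#' system. A bare mode with only the numerical broadening `eta` is available
#' for spectral checks against the closed-system eigenvalues.
#'
#' @param system `electronic_system` or `atom_block_hamiltonian`.
#' @param spec A [contact_spec()] (ignored in `mode = "bare"`).
#' @param grid Sorted, nonempty energy grid (eV).
#' @param eta Numerical broadening floor, eV.
#' @param mode `"transport"` (default) or `"bare"`.
#' @return Object of class `dos_field`: `energies`, `dos` (atoms x
#'   energies, states/eV, rows named by `atom_id`), `atoms`.
#' @export
per_atom_dos <- function(system, spec = NULL, grid, eta = 1e-6,
                         mode = c("transport", "bare")) {
  mode <- match.arg(mode)
  if (length(grid) == 0L) stop("argument error: empty energy grid", call. = FALSE)
  if (is.unsorted(grid)) stop("argument error: grid must be sorted", call. = FALSE)
  abh <- as_atom_blocks(system)
  H <- abh$matrix
  atoms <- abh$atoms
  sigma <- if (mode == "transport") {
    if (is.null(spec)) stop("a contact_spec is required in transport mode",
                            call. = FALSE)
    build_self_energies(spec, atoms)$sigma_total
  } else NULL
  n_at <- nrow(atoms)
  orb_of <- lapply(seq_len(n_at), function(i)
    seq.int(atoms$orbital_offset[i] + 1L, length.out = atoms$orbital_count[i]))
  dos <- matrix(0, n_at, length(grid),
                dimnames = list(as.character(atoms$atom_id), NULL))
  for (k in seq_along(grid)) {
    g <- retarded_green(grid[k], H, sigma, eta = eta)
    d_orb <- -Im(diag(g)) / pi
    dos[, k] <- vapply(orb_of, function(ix) sum(d_orb[ix]), numeric(1))
  }
  structure(list(energies = grid, dos = dos, atoms = atoms, by = "atom"),
            class = "dos_field")
}

#' Aggregate a per-atom DOS field to coarser resolution
#'
#' Each output row is the exact sum of its member atoms' rows; summing the
#' aggregated rows always reproduces the total DOS regardless of grouping.
#'
#' @param field A `dos_field` at atom resolution.
#' @param by One of `"base"`, `"strand"`, `"helix"`, `"region"`.
#' @return A `dos_field` whose rows are named by the grouping values.
#' @export
aggregate_dos <- function(field, by = c("base", "strand", "helix", "region")) {
  by <- match.arg(by)
  col <- switch(by, base = "base_id", strand = "strand_id",
                helix = "helix_id", region = "region")
  if (!col %in% names(field$atoms))
    stop("annotation error: atom table lacks column ", col, call. = FALSE)
  key <- field$atoms[[col]][match(rownames(field$dos),
                                  as.character(field$atoms$atom_id))]
  agg <- rowsum(field$dos, group = key)
  structure(list(energies = field$energies, dos = agg, atoms = field$atoms,
                 by = by),
            class = "dos_field")
}

#' @export
print.dos_field <- function(x, ...) {
  cat(sprintf("<dos_field> %d %s rows x %d energies [%.3f, %.3f] eV\n",
              nrow(x$dos), x$by, length(x$energies),
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Integrate DOS rows over an energy window
#'
#' Trapezoidal integration of each row of a `dos_field` over
#' `[window[1], window[2]]` (grid points inside the window are used).
#'
#' @param field A `dos_field`.
#' @param window Length-2 numeric, eV; default the full grid.
#' @return Named numeric vector of states per row.
#' @export
integrate_dos <- function(field, window = range(field$energies)) {
  keep <- field$energies >= window[1] & field$energies <= window[2]
  if (sum(keep) < 2L)
    stop("argument error: window contains fewer than 2 grid points",
         call. = FALSE)
  e <- field$energies[keep]
  apply(field$dos[, keep, drop = FALSE], 1L, function(r) pracma::trapz(e, r))
}

#' Fraction of windowed DOS residing on a set of atoms or a region
#'
#' @param field A `dos_field` at atom resolution.
#' @param window Length-2 energy window, eV.
#' @param atom_ids Atoms of interest; alternatively give `region`.
#' @param region Region tag (e.g. `"crossover"`) selecting atoms.
#' @return Scalar in `[0, 1]`: windowed DOS on the selection / total.
#' @export
dos_window_fraction <- function(field, window, atom_ids = NULL, region = NULL) {
  if (is.null(atom_ids)) {
    if (is.null(region)) stop("give atom_ids or region", call. = FALSE)
    atom_ids <- field$atoms$atom_id[field$atoms$region == region]
  }
  totals <- integrate_dos(field, window)
  sel <- as.character(atom_ids)
  sum(totals[rownames(field$dos) %in% sel]) / sum(totals)
}

#' Spatial localization of selected molecular orbitals
#'
#' For each requested global eigenvector (of the orthogonalized
#' Hamiltonian), reports the weight fraction `sum_{a in g} |c_a|^2` on each
#' group `g` (strand, helix or region). In the orthogonal basis these
#' squared components are the natural (Loewdin) populations and sum to one.
#'
#' @param system `electronic_system` or `atom_block_hamiltonian`.
#' @param orbitals Integer indices into the ascending-energy orbital list
#'   (e.g. `homo_index` from [spectrum_analysis()]).
#' @param by `"strand"`, `"helix"`, `"region"` or `"base_label"`.
#' @return Data frame with columns `orbital`, `energy` and one fraction
#'   column per group; fractions sum to 1 per orbital.
#' @export
orbital_localization <- function(system, orbitals,
                                 by = c("strand", "helix", "region",
                                        "base_label")) {
  by <- match.arg(by)
  col <- switch(by, strand = "strand_id", helix = "helix_id",
                region = "region", base_label = "base_label")
  abh <- as_atom_blocks(system)
  e <- eigen(abh$matrix, symmetric = TRUE)
  ord <- rev(seq_along(e$values))  # ascending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (any(orbitals < 1L | orbitals > length(vals)))
    stop("orbital index out of range [1, ", length(vals), "]", call. = FALSE)
  atoms <- abh$atoms
  groups <- sort(unique(as.character(atoms[[col]])))
  orb_group <- character(nrow(vecs))
  for (i in seq_len(nrow(atoms))) {
    ix <- seq.int(atoms$orbital_offset[i] + 1L,
                  length.out = atoms$orbital_count[i])
    orb_group[ix] <- as.character(atoms[[col]][i])
  }
  out <- data.frame(orbital = orbitals, energy = vals[orbitals])
  for (g in groups)
    out[[g]] <- vapply(orbitals, function(k)
      sum(abs(vecs[orb_group == g, k])^2), numeric(1))
  out
}
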