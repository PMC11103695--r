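#' Loewdin symmetric orthogonalization
#'
#' Transforms the Fock matrix `H0` of a non-orthogonal basis into the
#' orthogonal-basis Hamiltonian `H_orth = S0^{-1/2} H0 S0^{-1/2}`, which
#' preserves the generalized spectrum of `(H0, S0)`. `S0^{-1/2}` is computed
#' by eigendecomposition of the overlap with an explicit eigenvalue floor, so
#' near-singular overlaps are rejected rather than silently regularized.
#'
#' @param system An `electronic_system` (or a list with `hamiltonian` and
#'   `overlap` matrices).
#' @param tol Minimum admissible overlap eigenvalue (default `1e-8`).
#' @return A list with `matrix` (the orthogonalized Hamiltonian, eV),
#'   `transform` (`S^{-1/2}`), `inverse_transform` (`S^{1/2}`), and
#'   `overlap_eigenvalues`.
#' @export
lowdin_orthogonalize <- function(system, tol = 1e-8) {
  h <- system$hamiltonian
  s <- system$overlap
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  if (min(lam) <= tol)
    stop(sprintf(
      "near-singular overlap: min eigenvalue %.3e <= tolerance %.3e",
      min(lam), tol), call. = FALSE)
  v <- es$vectors
  s_half_inv <- v %*% (t(v) / sqrt(lam))
  s_half <- v %*% (t(v) * sqrt(lam))
  m <- s_half_inv %*% h %*% s_half_inv
  m <- (m + Conj(t(m))) / 2  # remove roundoff asymmetry
  list(matrix = m, transform = s_half_inv, inverse_transform = s_half,
       overlap_eigenvalues = lam)
}

block_eigen <- function(block, degeneracy_tol = 1e-10) {
  # ascending eigenvalues; deterministic column signs (largest-magnitude
  # component made positive); degenerate levels keep original orbital order
  e <- eigen(block, symmetric = TRUE)
  ord <- rev(seq_along(e$values))       # eigen() returns descending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (Re(vecs[i, k]) < 0) vecs[, k] <- -vecs[, k]
  }
  if (ncol(vecs) > 1L) {
    d <- diff(vals)
    if (any(abs(d) < degeneracy_tol)) {
      # within a degenerate cluster, order columns by their dominant
      # original-orbital index
      cl <- cumsum(c(TRUE, abs(d) >= degeneracy_tol))
      for (g in unique(cl)) {
        cols <- which(cl == g)
        if (length(cols) > 1L) {
          dom <- vapply(cols, function(k) which.max(abs(vecs[, k])), integer(1))
          vecs[, cols] <- vecs[, cols[order(dom)], drop = FALSE]
        }
      }
    }
  }
  list(values = vals, vectors = vecs)
}

#' Partition an orthogonalized Hamiltonian into atoms and diagonalize
#'
#' Block-diagonalizes within each atom: each atom's diagonal block is
#' rotated to its own eigenbasis (atomic molecular orbitals), so diagonal
#' elements hold the per-atom eigenvalues while off-diagonal blocks hold the
#' inter-atomic hopping parameters. The transform is block-diagonal unitary,
#' hence the global spectrum is untouched.
#'
#' @param orth Orthogonalized Hermitian matrix (eV), e.g.
#'   `lowdin_orthogonalize(sys)$matrix`.
#' @param atoms Atom annotation table covering all orbitals.
#' @param n_occupied Optional occupation count carried along for
#'   spectrum/transport convenience.
#' @return An object of class `atom_block_hamiltonian` with fields `matrix`,
#'   `block_transforms` (named by `atom_id`), `atom_eigenvalues`, `atoms`,
#'   `n_occupied`.
#' @export
atom_block_transform <- function(orth, atoms, n_occupied = NULL) {
  asym <- max(abs(orth - Conj(t(orth))))
  if (asym > 1e-10)
    stop(sprintf(
      "validation error: input is not Hermitian (max asymmetry %.3e eV)",
      asym), call. = FALSE)
  n <- nrow(orth)
  at <- atoms[order(atoms$orbital_offset), , drop = FALSE]
  if (sum(at$orbital_count) != n)
    stop("annotation error: atom table does not cover all orbitals",
         call. = FALSE)
  u <- matrix(0, n, n)
  transforms <- vector("list", nrow(at))
  eigenvalues <- vector("list", nrow(at))
  names(transforms) <- names(eigenvalues) <- as.character(at$atom_id)
  for (i in seq_len(nrow(at))) {
    idx <- seq.int(at$orbital_offset[i] + 1L, length.out = at$orbital_count[i])
    be <- block_eigen(orth[idx, idx, drop = FALSE])
    u[idx, idx] <- be$vectors
    transforms[[i]] <- be$vectors
    eigenvalues[[i]] <- be$values
  }
  m <- Conj(t(u)) %*% orth %*% u
  m <- (m + Conj(t(m))) / 2
  structure(
    list(matrix = m, block_transforms = transforms,
         atom_eigenvalues = eigenvalues, atoms = at,
         n_occupied = if (is.null(n_occupied)) NA_integer_
                      else as.integer(n_occupied)),
    class = "atom_block_hamiltonian")
}

#' One-shot orthogonalize + atom-block partition
#'
#' Convenience wrapper taking an `electronic_system` through
#' [lowdin_orthogonalize()] and [atom_block_transform()].
#'
#' @param system An `electronic_system`.
#' @param tol Overlap eigenvalue floor passed to [lowdin_orthogonalize()].
#' @return An `atom_block_hamiltonian`.
#' @export
as_atom_blocks <- function(system, tol = 1e-8) {
  if (inherits(system, "atom_block_hamiltonian")) return(system)
  orth <- lowdin_orthogonalize(system, tol = tol)
  atom_block_transform(orth$matrix, system$atoms, system$n_occupied)
}

#' @export
print.atom_block_hamiltonian <- function(x, ...) {
  cat(sprintf("<atom_block_hamiltonian> %d orbitals over %d atoms\n",
              nrow(x$matrix), nrow(x$atoms)))
  invisible(x)
}

system_eigenvalues <- function(x, tol = 1e-8) {
  if (inherits(x, "electronic_system"))
    sort(eigen(lowdin_orthogonalize(x, tol = tol)$matrix,
               symmetric = TRUE, only.values = TRUE)$values)
  else if (inherits(x, "atom_block_hamiltonian"))
    sort(eigen(x$matrix, symmetric = TRUE, only.values = TRUE)$values)
  else sort(eigen(as.matrix(x), symmetric = TRUE, only.values = TRUE)$values)
}

#' Frontier-orbital spectrum analysis
#'
#' Computes the full orbital spectrum (generalized eigenvalues for an
#' `electronic_system`, plain eigenvalues for an already orthogonalized
#' `atom_block_hamiltonian` or matrix) and reports the band-diagram
#' quantities: HOMO, LUMO, gap and the consecutive occupied-level
#' separations near the HOMO (first entry = HOMO minus HOMO-1).
#'
#' @param x `electronic_system`, `atom_block_hamiltonian`, or Hermitian
#'   matrix.
#' @param n_levels_occ,n_levels_unocc How many occupied/unoccupied levels to
#'   retain in the reported window (defaults 20 and 10).
#' @param n_occupied Occupation count; required when `x` does not carry one.
#' @return An object of class `energy_levels` with fields `levels`
#'   (ascending, eV), `homo_index` (1-based, equals `n_occupied`), `homo`,
#'   `lumo`, `gap`, `separations`, `occ_levels`, `unocc_levels`.
#' @export
spectrum_analysis <- function(x, n_levels_occ = 20, n_levels_unocc = 10,
                              n_occupied = NULL) {
  if (is.null(n_occupied)) {
    n_occupied <- if (inherits(x, "electronic_system")) x$n_occupied
                  else if (inherits(x, "atom_block_hamiltonian")) x$n_occupied
                  else NA_integer_
  }
  if (is.null(n_occupied) || is.na(n_occupied))
    stop("configuration error: n_occupied is not set", call. = FALSE)
  levels <- system_eigenvalues(x)
  n <- length(levels)
  if (n_occupied <= 0 || n_occupied >= n)
    stop("configuration error: n_occupied outside (0, n_orb)", call. = FALSE)
  n_levels_occ <- min(n_levels_occ, n_occupied)
  n_levels_unocc <- min(n_levels_unocc, n - n_occupied)
  hi <- n_occupied
  occ <- levels[seq.int(hi - n_levels_occ + 1L, hi)]
  unocc <- levels[seq.int(hi + 1L, hi + n_levels_unocc)]
  separations <- if (n_levels_occ > 1) -diff(rev(occ)) else numeric(0)
  structure(
    list(levels = levels, homo_index = hi,
         homo = levels[hi], lumo = levels[hi + 1L],
         gap = levels[hi + 1L] - levels[hi],
         separations = separations,
         occ_levels = occ, unocc_levels = unocc),
    class = "energy_levels")
}

#' @export
print.energy_levels <- function(x, ...) {
  cat(sprintf("<energy_levels> HOMO %.4f eV, LUMO %.4f eV, gap %.4f eV\n",
              x$homo, x$lumo, x$gap))
  if (length(x$separations))
    cat(sprintf("  HOMO - HOMO-1 separation: %.1f meV\n",
                1000 * x$separations[1]))
  invisible(x)
}

#' Shift energies so the HOMO sits at zero
#'
#' Used to put systems with different absolute level positions on a common
#' axis before comparing transmission or DOS curves.
#'
#' @param x Numeric energy vector/grid or an `energy_levels` object.
#' @param homo Reference HOMO energy in eV; defaults to `x$homo` for
#'   `energy_levels` input.
#' @return Shifted copy of `x` (energies minus `homo`).
#' @export
align_to_homo <- function(x, homo = NULL) {
  if (inherits(x, "energy_levels")) {
    if (is.null(homo)) homo <- x$homo
    stopifnot(is.finite(homo))
    x$levels <- x$levels - homo
    x$homo <- x$homo - homo
    x$lumo <- x$lumo - homo
    x$occ_levels <- x$occ_levels - homo
    x$unocc_levels <- x$unocc_levels - homo
    return(x)
  }
  if (is.null(homo))
    stop("homo reference energy is required for plain energy vectors",
         call. = FALSE)
  stopifnot(is.finite(homo))
  x - homo
}
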