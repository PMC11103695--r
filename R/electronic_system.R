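#' Annotated electronic system
#'
#' Bundles a one-electron Hamiltonian (Fock) matrix `H0` and the overlap
#' matrix `S0` of its (generally non-orthogonal) basis with an atom table
#' that maps orbitals to atoms, bases, strands, helices and region tags.
#' This is the universal input of the transport pipeline: real DFT matrices
#' and the synthetic tight-binding systems built by [build_duplex()] /
#' [build_origami()] flow through the same container.
#'
#' @param hamiltonian Hermitian matrix in eV (`n_orb x n_orb`).
#' @param overlap Symmetric positive-definite overlap matrix (dimensionless).
#'   Positive definiteness is checked lazily, at first use in
#'   [lowdin_orthogonalize()].
#' @param atoms Data frame with one row per atom and columns `atom_id`,
#'   `element`, `orbital_offset` (0-based), `orbital_count`, `base_id`,
#'   `base_label` (one of `A,C,G,T,backbone`), `strand_id` (roman numeral
#'   labels `I`, `II`, ...), `helix_id`, `region` (one of
#'   `base, backbone, crossover, terminal`). Orbital ranges must be
#'   disjoint, contiguous and cover exactly `[0, n_orb)`.
#' @param n_occupied Number of doubly occupied orbitals, `0 < n_occupied <
#'   n_orb`. Taken from the electronic-structure calculation (or defined by
#'   the synthetic builders as one occupied level per base and backbone
#'   site); never guessed.
#' @param metadata Free-form named list of provenance information.
#' @param validate Run invariant checks (default `TRUE`).
#'
#' @return An object of class `electronic_system`.
#' @seealso [load_system()], [save_system()], [lowdin_orthogonalize()]
#' @export
electronic_system <- function(hamiltonian, overlap, atoms, n_occupied,
                              metadata = list(), validate = TRUE) {
  hamiltonian <- as.matrix(hamiltonian)
  overlap <- as.matrix(overlap)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  sys <- structure(
    list(hamiltonian = hamiltonian, overlap = overlap, atoms = atoms,
         n_occupied = as.integer(n_occupied), metadata = metadata),
    class = "electronic_system")
  if (validate) validate_electronic_system(sys)
  sys
}

ATOM_COLUMNS <- c("atom_id", "element", "orbital_offset", "orbital_count",
                  "base_id", "base_label", "strand_id", "helix_id", "region")

#' Validate the invariants of an electronic system
#'
#' Checks matrix shapes, Hermiticity (to 1e-10), the orbital coverage of the
#' atom table (disjoint, contiguous, covering `[0, n_orb)`), and the
#' occupation bounds. Overlap positive definiteness is deliberately not
#' checked here (it is checked where `S^{-1/2}` is needed).
#'
#' @param sys An `electronic_system`.
#' @param tol Hermiticity tolerance in eV.
#' @return `sys`, invisibly; errors describe the violated invariant.
#' @export
validate_electronic_system <- function(sys, tol = 1e-10) {
  h <- sys$hamiltonian
  s <- sys$overlap
  n <- nrow(h)
  if (ncol(h) != n) stop("hamiltonian must be square", call. = FALSE)
  if (nrow(s) != n || ncol(s) != n)
    stop("overlap dimensions do not match the hamiltonian", call. = FALSE)
  asym <- max(abs(h - Conj(t(h))))
  if (asym > tol)
    stop(sprintf(
      "validation error: hamiltonian is not Hermitian (max asymmetry %.3e eV)",
      asym), call. = FALSE)
  sasym <- max(abs(s - Conj(t(s))))
  if (sasym > tol)
    stop(sprintf(
      "validation error: overlap is not symmetric (max asymmetry %.3e)",
      sasym), call. = FALSE)

  missing_cols <- setdiff(ATOM_COLUMNS, names(sys$atoms))
  if (length(missing_cols))
    stop("annotation error: atom table lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  at <- sys$atoms[order(sys$atoms$orbital_offset), ]
  expected_offset <- c(0L, cumsum(at$orbital_count))
  if (any(at$orbital_offset != expected_offset[-length(expected_offset)]) ||
      expected_offset[length(expected_offset)] != n)
    stop(sprintf(paste0(
      "annotation error: atom orbital ranges must be disjoint, contiguous ",
      "and cover [0, %d)"), n), call. = FALSE)
  if (anyDuplicated(sys$atoms$atom_id))
    stop("annotation error: duplicated atom_id", call. = FALSE)

  nocc <- sys$n_occupied
  if (is.na(nocc) || nocc <= 0L || nocc >= n)
    stop(sprintf(
      "validation error: n_occupied must satisfy 0 < n_occupied < %d, got %s",
      n, nocc), call. = FALSE)
  invisible(sys)
}

#' Orbital indices (1-based) belonging to a set of atoms
#'
#' @param atoms Atom annotation table.
#' @param atom_ids Atom ids to resolve; all ids must exist.
#' @return Integer vector of orbital indices into the matrix.
#' @export
atom_orbitals <- function(atoms, atom_ids) {
  idx <- match(atom_ids, atoms$atom_id)
  if (anyNA(idx))
    stop("annotation error: unknown atom_id ",
         paste(atom_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  unlist(lapply(idx, function(i) {
    seq.int(atoms$orbital_offset[i] + 1L,
            length.out = atoms$orbital_count[i])
  }), use.names = FALSE)
}

#' @export
print.electronic_system <- function(x, ...) {
  n <- nrow(x$hamiltonian)
  cat(sprintf("<electronic_system> %d orbitals over %d atoms, n_occupied = %d\n",
              n, nrow(x$atoms), x$n_occupied))
  cat(sprintf("  strands: %s | helices: %s\n",
              paste(unique(x$atoms$strand_id), collapse = ", "),
              paste(unique(x$atoms$helix_id), collapse = ", ")))
  reg <- table(x$atoms$region)
  cat("  regions:", paste(sprintf("%s=%d", names(reg), reg), collapse = " "), "\n")
  if (!is.null(x$metadata$kind))
    cat("  kind:", x$metadata$kind, "\n")
  invisible(x)
}

# -- bundle I/O ---------------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

lower_triangle_df <- function(m, drop_zero = TRUE) {
  idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  v <- m[idx]
  if (drop_zero) {
    keep <- v != 0
    idx <- idx[keep, , drop = FALSE]
    v <- v[keep]
  }
  data.frame(i = idx[, 1L], j = idx[, 2L], value = v)
}

matrix_from_lower <- function(df, n, what) {
  if (!all(c("i", "j", "value") %in% names(df)))
    stop(sprintf("format error: %s table lacks columns i, j, value", what),
         call. = FALSE)
  if (any(df$i < df$j))
    stop(sprintf("format error: %s entries must be lower-triangular (i >= j)",
                 what), call. = FALSE)
  if (any(df$i > n | df$j < 1))
    stop(sprintf("format error: %s indices outside [1, %d]", what, n),
         call. = FALSE)
  m <- matrix(0, n, n)
  m[cbind(df$i, df$j)] <- df$value
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Save an electronic system as a bundle
#'
#' Two on-disk layouts carry the same content:
#' \describe{
#'   \item{`tsv`}{A directory of plain-text TSV files (`meta.tsv`,
#'     `hamiltonian_lower.tsv`, `overlap_lower.tsv`, `atoms.tsv`). Matrices
#'     are stored as their nonzero lower triangle at full double precision
#'     (`%.17g`, exactly round-tripping IEEE doubles).}
#'   \item{`h5`}{A single HDF5 file with datasets `/hamiltonian/lower` and
#'     `/overlap/lower` (packed row-major lower triangle, 64-bit float),
#'     root attributes `n_orb`, `n_occupied`, `energy_unit = "eV"`,
#'     `format_version`, and the atom columns under group `/atoms`.
#'     Requires the `rhdf5` package.}
#' }
#' Only real-valued matrices are serialized; energies are in eV end-to-end.
#'
#' @param sys An `electronic_system`.
#' @param path Destination directory (`tsv`) or `.h5` file path.
#' @param format `"tsv"` or `"h5"`; default guessed from `path` extension.
#' @return `path`, invisibly.
#' @export
save_system <- function(sys, path, format = NULL) {
  validate_electronic_system(sys)
  if (is.complex(sys$hamiltonian) || is.complex(sys$overlap))
    stop("bundle format stores real matrices only", call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.h5$", path, ignore.case = TRUE)) "h5" else "tsv"
  format <- match.arg(format, c("tsv", "h5"))
  if (format == "tsv") save_system_tsv(sys, path) else save_system_h5(sys, path)
  invisible(path)
}

save_system_tsv <- function(sys, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(sys$hamiltonian)
  meta <- data.frame(
    key = c("format_version", "energy_unit", "n_orb", "n_occupied"),
    value = c("1", "eV", as.character(n), as.character(sys$n_occupied)))
  if (length(sys$metadata)) {
    md <- sys$metadata[vapply(sys$metadata, function(v)
      is.atomic(v) && length(v) == 1L, logical(1))]
    if (length(md))
      meta <- rbind(meta, data.frame(
        key = paste0("meta_", names(md)),
        value = vapply(md, as.character, character(1))))
  }
  utils::write.table(meta, file.path(path, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in c("hamiltonian", "overlap")) {
    df <- lower_triangle_df(sys[[nm]])
    df$value <- fmt_num(df$value)
    utils::write.table(df, file.path(path, paste0(nm, "_lower.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sys$atoms, file.path(path, "atoms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

pack_lower <- function(m) {
  # row-major packed lower triangle: rows i, columns 1..i
  unlist(lapply(seq_len(nrow(m)), function(i) m[i, seq_len(i)]),
         use.names = FALSE)
}

unpack_lower <- function(v, n) {
  m <- matrix(0, n, n)
  pos <- 0L
  for (i in seq_len(n)) {
    m[i, seq_len(i)] <- v[pos + seq_len(i)]
    pos <- pos + i
  }
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

save_system_h5 <- function(sys, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the 'rhdf5' package is required for HDF5 bundles", call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "hamiltonian")
  rhdf5::h5createGroup(path, "overlap")
  rhdf5::h5createGroup(path, "atoms")
  rhdf5::h5write(pack_lower(sys$hamiltonian), path, "hamiltonian/lower")
  rhdf5::h5write(pack_lower(sys$overlap), path, "overlap/lower")
  for (col in names(sys$atoms))
    rhdf5::h5write(sys$atoms[[col]], path, paste0("atoms/", col))
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.integer(nrow(sys$hamiltonian)), fid, "n_orb")
  rhdf5::h5writeAttribute(as.integer(sys$n_occupied), fid, "n_occupied")
  rhdf5::h5writeAttribute("eV", fid, "energy_unit")
  rhdf5::h5writeAttribute("1", fid, "format_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load an electronic system bundle
#'
#' Accepts a TSV directory bundle or an HDF5 file (see [save_system()] for
#' the layouts). Symmetric matrices are reconstructed from the stored lower
#' triangle and all `electronic_system` invariants are verified.
#'
#' @param path Bundle directory or `.h5` file.
#' @return An `electronic_system`.
#' @export
load_system <- function(path) {
  if (!file.exists(path))
    stop("format error: no such bundle: ", path, call. = FALSE)
  if (dir.exists(path)) load_system_tsv(path) else load_system_h5(path)
}

load_system_tsv <- function(path) {
  need <- c("meta.tsv", "hamiltonian_lower.tsv", "overlap_lower.tsv", "atoms.tsv")
  have <- file.exists(file.path(path, need))
  if (!all(have))
    stop("format error: bundle is missing ",
         paste(need[!have], collapse = ", "), call. = FALSE)
  meta <- utils::read.table(file.path(path, "meta.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
  kv <- stats::setNames(meta$value, meta$key)
  for (f in c("n_orb", "n_occupied"))
    if (is.na(kv[f]))
      stop("format error: meta.tsv lacks field ", f, call. = FALSE)
  n <- as.integer(kv[["n_orb"]])
  read_m <- function(file, what) {
    df <- utils::read.table(file.path(path, file), sep = "\t", header = TRUE,
                            colClasses = c("integer", "integer", "character"))
    df$value <- as.numeric(df$value)
    matrix_from_lower(df, n, what)
  }
  atoms <- utils::read.table(file.path(path, "atoms.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  md_keys <- grep("^meta_", meta$key, value = TRUE)
  metadata <- as.list(stats::setNames(kv[md_keys], sub("^meta_", "", md_keys)))
  electronic_system(read_m("hamiltonian_lower.tsv", "hamiltonian"),
                    read_m("overlap_lower.tsv", "overlap"),
                    atoms, as.integer(kv[["n_occupied"]]), metadata)
}

load_system_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the 'rhdf5' package is required for HDF5 bundles", call. = FALSE)
  content <- rhdf5::h5ls(path)$name
  for (d in c("hamiltonian", "overlap", "atoms"))
    if (!d %in% content)
      stop("format error: HDF5 bundle is missing dataset group ", d,
           call. = FALSE)
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (f in c("n_orb", "n_occupied"))
    if (is.null(attrs[[f]]))
      stop("format error: HDF5 bundle lacks attribute ", f, call. = FALSE)
  n <- as.integer(attrs$n_orb)
  h <- unpack_lower(as.numeric(rhdf5::h5read(path, "hamiltonian/lower")), n)
  s <- unpack_lower(as.numeric(rhdf5::h5read(path, "overlap/lower")), n)
  cols <- rhdf5::h5read(path, "atoms")
  atoms <- as.data.frame(lapply(cols, as.vector), stringsAsFactors = FALSE)
  first <- intersect(c(ATOM_COLUMNS, "pos", "hpos"), names(atoms))
  atoms <- atoms[, c(first, setdiff(names(atoms), first)), drop = FALSE]
  atoms <- atoms[order(atoms$orbital_offset), , drop = FALSE]
  rownames(atoms) <- NULL
  electronic_system(h, s, atoms, as.integer(attrs$n_occupied))
}
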