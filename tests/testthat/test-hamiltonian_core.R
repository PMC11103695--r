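test_that("bundle round trip preserves the system field by field", {
  sys <- build_duplex("GATTACAG", model_params(seed = 1L))

  td <- withr::local_tempdir()
  save_system(sys, file.path(td, "duplex_bundle"))
  back <- load_system(file.path(td, "duplex_bundle"))
  expect_identical(back$hamiltonian, sys$hamiltonian)
  expect_identical(back$overlap, sys$overlap)
  expect_identical(back$n_occupied, sys$n_occupied)
  expect_equal(back$atoms, sys$atoms)
  expect_identical(back$metadata$kind, "duplex")

  h5 <- file.path(td, "duplex.h5")
  save_system(sys, h5)
  back5 <- load_system(h5)
  expect_identical(back5$hamiltonian, sys$hamiltonian)
  expect_identical(back5$overlap, sys$overlap)
  expect_identical(back5$n_occupied, sys$n_occupied)
  expect_equal(back5$atoms, sys$atoms)
})

test_that("malformed bundles and annotations are rejected with named causes", {
  # overlapping orbital ranges [0,4) and [3,7)
  atoms <- data.frame(
    atom_id = 1:2, element = "C", orbital_offset = c(0L, 3L),
    orbital_count = c(4L, 4L), base_id = 1:2, base_label = "G",
    strand_id = "I", helix_id = 1L, region = "base")
  expect_error(
    electronic_system(diag(7), diag(7), atoms, n_occupied = 3),
    "annotation error")

  expect_error(load_system(file.path(tempdir(), "no-such-bundle")),
               "format error")

  sys <- build_duplex("GC")
  td <- withr::local_tempdir()
  save_system(sys, file.path(td, "b"))
  file.remove(file.path(td, "b", "overlap_lower.tsv"))
  expect_error(load_system(file.path(td, "b")), "overlap_lower")

  h <- diag(2); h[1, 2] <- 0.5  # asymmetric beyond tolerance
  expect_error(
    electronic_system(h, diag(2), rand_atoms(2, 1), n_occupied = 1),
    "max asymmetry")

  expect_error(
    electronic_system(diag(3), diag(3), rand_atoms(3, 1), n_occupied = 3),
    "n_occupied")
})

test_that("orbital bookkeeping is consistent with an independent recount", {
  sys <- build_duplex(random_sequence(8, 1), model_params(seed = 1L))
  n_orb <- 0L
  for (i in seq_len(nrow(sys$atoms))) n_orb <- n_orb + sys$atoms$orbital_count[i]
  expect_identical(nrow(sys$hamiltonian), n_orb)
  covered <- sort(atom_orbitals(sys$atoms, sys$atoms$atom_id))
  expect_identical(covered, seq_len(n_orb))
})

test_that("Loewdin orthogonalization matches closed forms and the generalized oracle", {
  # identity overlap: H unchanged
  sys <- rand_system(8, 42)
  sys$overlap <- diag(8)
  lw <- lowdin_orthogonalize(sys)
  expect_equal(lw$matrix, sys$hamiltonian, tolerance = 1e-12)

  # diagonal overlap closed form D^{-1/2} H D^{-1/2}:
  # h11 / 4, h12 / 2, h22 unchanged for D = diag(4, 1)
  h <- matrix(c(-1, -0.2, -0.2, -2), 2)
  sys2 <- electronic_system(h, diag(c(4, 1)), rand_atoms(2, 7), n_occupied = 1)
  lw2 <- lowdin_orthogonalize(sys2)
  expect_equal(lw2$matrix, matrix(c(-0.25, -0.1, -0.1, -2), 2),
               tolerance = 1e-12)

  # 2x2 generalized eigenproblem oracle
  h3 <- matrix(c(-1, -0.1, -0.1, -1), 2)
  s3 <- matrix(c(1, 0.2, 0.2, 1), 2)
  sys3 <- electronic_system(h3, s3, rand_atoms(2, 8), n_occupied = 1)
  got <- sort(eigen(lowdin_orthogonalize(sys3)$matrix, symmetric = TRUE,
                    only.values = TRUE)$values)
  expect_equal(got, gen_eigen_oracle(h3, s3), tolerance = 1e-10)

  # near-singular overlap rejected, reporting the eigenvalue
  sysn <- rand_system(4, 3)
  sysn$overlap <- diag(c(1, 1, 1, 1e-10))
  expect_error(lowdin_orthogonalize(sysn), "near-singular overlap")
})

test_that("Loewdin round trip recovers H0 and preserves Hermiticity", {
  for (seed in c(2, 5, 11)) {
    sys <- rand_system(20, seed)
    lw <- lowdin_orthogonalize(sys)
    expect_lt(max(abs(lw$matrix - t(lw$matrix))), 1e-10)
    back <- lw$inverse_transform %*% lw$matrix %*% lw$inverse_transform
    expect_lt(max(abs(back - sys$hamiltonian)), 1e-9)
  }
})

test_that("atom-block transform diagonalizes blocks and preserves the spectrum", {
  # single atom: full diagonalization
  h <- rand_hermitian(4, 5)
  atoms1 <- data.frame(atom_id = 1L, element = "C", orbital_offset = 0L,
                       orbital_count = 4L, base_id = 1L, base_label = "G",
                       strand_id = "I", helix_id = 1L, region = "base")
  ab <- atom_block_transform(h, atoms1)
  expect_lt(max(abs(ab$matrix - diag(diag(ab$matrix)))), 1e-10)
  expect_equal(sort(diag(Re(ab$matrix))),
               sort(eigen(h, symmetric = TRUE, only.values = TRUE)$values),
               tolerance = 1e-10)

  # already-diagonal blocks: transform is a signed permutation (here identity,
  # since within-atom energies are stored ascending)
  hd <- diag(c(-2, -1, -3, 0))
  atoms2 <- rand_atoms(4, 1)
  atoms2 <- data.frame(atom_id = 1:2, element = "C",
                       orbital_offset = c(0L, 2L), orbital_count = 2L,
                       base_id = 1:2, base_label = "G", strand_id = "I",
                       helix_id = 1L, region = "base")
  ab2 <- atom_block_transform(hd, atoms2)
  for (u in ab2$block_transforms) {
    expect_lt(max(abs(crossprod(u) - diag(ncol(u)))), 1e-10)
    expect_true(all(abs(abs(u) - diag(nrow(u))) < 1e-12 |
                      abs(u) < 1e-12))
  }

  # two atoms x 2 orbitals: global spectrum preserved
  h7 <- rand_hermitian(4, 7)
  ab7 <- atom_block_transform(h7, atoms2)
  expect_equal(sort(eigen(ab7$matrix, symmetric = TRUE,
                          only.values = TRUE)$values),
               sort(eigen(h7, symmetric = TRUE, only.values = TRUE)$values),
               tolerance = 1e-8)
  expect_lt(max(abs(ab7$matrix - t(ab7$matrix))), 1e-10)
  # within-atom diagonal blocks are diagonal
  expect_lt(max(abs(ab7$matrix[1:2, 1:2] - diag(diag(ab7$matrix)[1:2]))),
            1e-10)

  expect_error(atom_block_transform(matrix(c(0, 1, 0, 0), 2), atoms2[1, ]),
               "not Hermitian")
})

test_that("full pipeline spectrum conservation against the generalized oracle", {
  for (seed in c(1, 9, 17)) {
    n <- sample(c(12, 30, 60), 1)
    sys <- rand_system(n, seed)
    abh <- as_atom_blocks(sys)
    expect_lt(max(abs(sort(eigen(abh$matrix, symmetric = TRUE,
                                 only.values = TRUE)$values) -
                        gen_eigen_oracle(sys$hamiltonian, sys$overlap))),
              1e-8)
  }
})

test_that("spectrum analysis reports HOMO/LUMO, gap and separations", {
  # symmetric dimer: HOMO - HOMO-1 = 2|t|
  t <- -0.05
  dimer <- chain_system(c(-8, -8), t, n_occupied = 1L)
  lev <- spectrum_analysis(dimer, n_levels_occ = 2)
  expect_equal(lev$gap, 2 * abs(t), tolerance = 1e-12)
  expect_identical(lev$homo_index, 1L)

  # fixed levels: gap forced by definition
  lev2 <- spectrum_analysis(diag(c(-5, -4, -1, 0)), n_occupied = 2)
  expect_equal(lev2$gap, 3)
  expect_equal(lev2$separations[1], 1)

  # synthetic GC duplex vs brute-force generalized eigenvalues
  gc <- build_duplex("GGGGCCCC", model_params(seed = 1L))
  lev3 <- spectrum_analysis(gc)
  ev <- gen_eigen_oracle(gc$hamiltonian, gc$overlap)
  expect_equal(lev3$homo, ev[gc$n_occupied], tolerance = 1e-8)
  expect_equal(lev3$gap, ev[gc$n_occupied + 1] - ev[gc$n_occupied],
               tolerance = 1e-8)
  expect_identical(lev3$homo_index, gc$n_occupied)

  expect_error(spectrum_analysis(diag(4)), "n_occupied")
})

test_that("HOMO alignment shifts energies as stated", {
  expect_equal(align_to_homo(c(-5, -4), homo = -5), c(0, 1))
  x <- c(-2.5, 0, 1)
  expect_identical(align_to_homo(x, homo = 0), x)

  # comparing two systems at a common aligned offset equals comparing each
  # at its own HOMO + offset
  a <- spectrum_analysis(build_duplex("GGGGCCCC"))
  b <- spectrum_analysis(build_duplex("AAAATTTT"))
  off <- 0.3
  direct <- (a$homo + off) - (b$homo + off)
  aligned <- align_to_homo(a)$homo - align_to_homo(b)$homo
  expect_equal((a$homo + off) - a$homo, (b$homo + off) - b$homo)
  expect_equal(aligned, 0)
  expect_equal(direct, a$homo - b$homo)
})
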