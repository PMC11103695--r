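test_that("self-energy construction places contacts and probes per atom", {
  sys <- chain_system(c(-8, -8, -8), -0.1)
  spec <- contact_spec(1L, 3L, gamma_contact = 0.6, gamma_probe = 0.01)
  se <- build_self_energies(spec, sys$atoms)
  expect_identical(se$n_probes, 1L)
  expect_identical(se$probe_atoms, 2L)
  expect_equal(diag(se$sigma_left), c(-0.3i, 0, 0))
  expect_equal(diag(se$sigma_right), c(0, 0, -0.3i))
  expect_equal(diag(se$sigma_probe), c(0, -0.005i, 0))
  expect_equal(se$gamma_left, diag(c(0.6, 0, 0)))
  expect_true(all(se$sigma_total[upper.tri(se$sigma_total)] == 0))

  se0 <- build_self_energies(contact_spec(1L, 3L, gamma_probe = 0), sys$atoms)
  expect_true(all(se0$sigma_probe == 0))

  # duplex: probe count equals an independent recount of non-contact atoms
  ds <- build_duplex("GGGGCCCC")
  cs <- enumerate_schemes(ds)$ds_end_to_end
  sed <- build_self_energies(contact_spec(cs$left, cs$right), ds$atoms)
  recount <- sum(!ds$atoms$atom_id %in% c(cs$left, cs$right))
  expect_identical(sed$n_probes, recount)

  expect_error(build_self_energies(contact_spec(1L, 99L), sys$atoms),
               "unknown atom_id")
  expect_error(contact_spec(c(1L, 2L), 2L), "both contacts")
})

test_that("retarded Green's function solves its defining equation", {
  # scalar closed form
  eps <- -0.4; gam <- 0.6
  g <- retarded_green(0.1, matrix(eps, 1, 1), matrix(-0.5i * gam, 1, 1),
                      eta = 0)
  expect_equal(g[1, 1], 1 / (0.1 - eps + 0.5i * gam), tolerance = 1e-14)

  # defining equation and adjoint identity on a random dense case
  h <- rand_hermitian(4, 3)
  sig <- diag(c(-0.3i, 0, 0, -0.3i))
  E <- 0.25; eta <- 1e-6
  g4 <- retarded_green(E, h, sig, eta = eta)
  a <- diag(complex(real = E, imaginary = eta), 4) - h - sig
  expect_lt(max(abs(a %*% g4 - diag(4))), 1e-8)
  ga <- Conj(t(g4))
  expect_lt(max(abs(ga %*% Conj(t(a)) - diag(4))), 1e-8)
  # independent dense inversion oracle
  expect_lt(max(abs(g4 - qr.solve(a, diag(4) + 0i))), 1e-10)
})

test_that("pairwise transmission matches Breit-Wigner and the trace formula", {
  # symmetric resonance: T = 1
  gl <- 0.3; gr <- 0.3
  g <- retarded_green(0, matrix(0, 1, 1), matrix(-0.5i * (gl + gr), 1, 1),
                      eta = 0)
  ts <- pairwise_transmission(g, list(L = matrix(gl, 1, 1),
                                      R = matrix(gr, 1, 1)))
  expect_equal(ts$tmat["L", "R"], 1, tolerance = 1e-12)

  # asymmetric couplings at resonance: 4 GL GR / (GL + GR)^2
  gl <- 0.6; gr <- 0.2
  g2 <- retarded_green(0, matrix(0, 1, 1), matrix(-0.5i * (gl + gr), 1, 1),
                       eta = 0)
  ts2 <- pairwise_transmission(g2, list(L = matrix(gl, 1, 1),
                                        R = matrix(gr, 1, 1)))
  expect_equal(ts2$tmat["L", "R"], 4 * 0.6 * 0.2 / 0.8^2, tolerance = 1e-12)

  # 3-site chain with one probe: fast route vs explicit trace products
  sys <- chain_system(c(-8, -8.2, -8), -0.15)
  set.seed(5)
  spec <- contact_spec(1L, 3L, gamma_contact = 0.5, gamma_probe = 0.02)
  se <- build_self_energies(spec, sys$atoms)
  abh <- as_atom_blocks(sys)
  E <- -8 + rnorm(1, 0, 0.1)
  G <- retarded_green(E, abh$matrix, se$sigma_total)
  ts3 <- pairwise_transmission(G, se, energy = E)
  gammas <- list(se$gamma_left, se$gamma_right,
                 diag(c(0, 0.02, 0)))
  Ga <- Conj(t(G))
  for (i in 1:3) for (j in 1:3) {
    tr <- Re(sum(diag(gammas[[i]] %*% G %*% gammas[[j]] %*% Ga)))
    expect_equal(unname(ts3$tmat[i, j]), tr, tolerance = 1e-10)
  }
  # reciprocity for a real-symmetric Hamiltonian
  expect_lt(max(abs(ts3$tmat - t(ts3$tmat))), 1e-9)
  expect_true(all(ts3$tmat >= -1e-12))

  expect_error(
    pairwise_transmission(G, list(matrix(c(0.1, 0.05, 0.05, 0.1), 2))),
    "non-diagonal")
})

test_that("probe potentials satisfy the zero-current condition", {
  # mirror-symmetric chain, single probe: midpoint potential
  sys <- chain_system(c(-8, -8, -8), -0.1)
  abh <- as_atom_blocks(sys)
  spec <- contact_spec(1L, 3L, gamma_probe = 0.05)
  se <- build_self_energies(spec, sys$atoms)
  G <- retarded_green(-7.9, abh$matrix, se$sigma_total)
  ts <- probe_potentials(pairwise_transmission(G, se, energy = -7.9), 0.5, -0.5)
  expect_equal(unname(ts$mu_probes), 0, tolerance = 1e-12)  # (mu_L + mu_R) / 2

  # gamma_probe = 0: no probe current can flow; potential reported at 0
  se0 <- build_self_energies(contact_spec(1L, 3L, gamma_probe = 0), sys$atoms)
  G0 <- retarded_green(-7.9, abh$matrix, se0$sigma_total)
  ts0 <- probe_potentials(pairwise_transmission(G0, se0), 0.7, -0.1)
  expect_equal(unname(ts0$mu_probes), 0)

  # asymmetric 4-site chain with 2 probes vs an independent least-squares
  # solve of the zero-probe-current equations
  sys4 <- chain_system(c(-8, -8.3, -7.9, -8.1), -0.12)
  abh4 <- as_atom_blocks(sys4)
  spec4 <- contact_spec(1L, 4L, gamma_contact = 0.4, gamma_probe = 0.03)
  se4 <- build_self_energies(spec4, sys4$atoms)
  E <- -8.05
  G4 <- retarded_green(E, abh4$matrix, se4$sigma_total)
  ts4 <- probe_potentials(pairwise_transmission(G4, se4, energy = E), 1, 0)
  tm <- ts4$tmat
  p <- ts4$probes
  # zero current at probe i: sum_j T_ij (mu_i - mu_j) = 0, mu_L = 1, mu_R = 0
  A <- matrix(0, length(p), length(p), dimnames = list(p, p))
  b <- numeric(length(p))
  for (i in seq_along(p)) {
    A[i, i] <- sum(tm[p[i], colnames(tm) != p[i]])
    for (j in seq_along(p)) if (j != i) A[i, j] <- -tm[p[i], p[j]]
    b[i] <- tm[p[i], "L"] * 1 + tm[p[i], "R"] * 0
  }
  mu_ls <- qr.solve(A, b)
  expect_equal(unname(ts4$mu_probes), unname(mu_ls), tolerance = 1e-9)

  # conservation: probe currents vanish, total current vanishes
  I <- terminal_currents(ts4, 1, 0)
  expect_lt(max(abs(I[p])), 1e-9)
  expect_lt(abs(sum(I)), 1e-9)
})

test_that("effective transmission has the correct limits", {
  # no probes: T_eff = T_LR exactly
  sys <- chain_system(c(-8, -8), -0.1)
  abh <- as_atom_blocks(sys)
  se <- build_self_energies(contact_spec(1L, 2L), sys$atoms)
  r <- origamiCT:::teff_at_energy(abh$matrix, se, -8.05)
  expect_identical(r$t_eff, r$t_direct)

  # coherent limit: |T_eff - T_LR| decreases monotonically with gamma_probe
  sys3 <- chain_system(c(-8, -8.2, -8), -0.1)
  abh3 <- as_atom_blocks(sys3)
  lev <- spectrum_analysis(sys3)
  gaps <- vapply(c(1e-2, 1e-4, 1e-6), function(gb) {
    se3 <- build_self_energies(contact_spec(1L, 3L, gamma_probe = gb),
                               sys3$atoms)
    r3 <- origamiCT:::teff_at_energy(abh3$matrix, se3, lev$homo)
    r3$t_eff - r3$t_direct
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_true(all(gaps >= 0))

  # single site + single probe: brute-force three-terminal current balance
  eps <- 0; gl <- 0.2; gr <- 0.2; gb <- 0.2
  E <- 0.1
  g11 <- 1 / (E - eps + 0.5i * (gl + gr + gb))
  t_lr <- gl * gr * abs(g11)^2
  t_lb <- gl * gb * abs(g11)^2
  t_rb <- gr * gb * abs(g11)^2
  # probe floats to zero current: mu_b = (T_bL mu_L + T_bR mu_R)/(T_bL + T_bR);
  # I_L = T_LR (mu_L - mu_R) + T_LB (mu_L - mu_B) gives the effective T
  mu_l <- 1; mu_r <- 0
  mu_b <- (t_lb * mu_l + t_rb * mu_r) / (t_lb + t_rb)
  t_eff_brute <- t_lr * (mu_l - mu_r) + t_lb * (mu_l - mu_b)
  G <- matrix(g11, 1, 1)
  ts <- origamiCT:::transmission_set(
    matrix(c(0, t_lr, t_lb, t_lr, 0, t_rb, t_lb, t_rb, 0), 3,
           dimnames = list(c("L", "R", "probe_1"), c("L", "R", "probe_1"))),
    energy = E)
  expect_equal(effective_transmission(ts), t_eff_brute, tolerance = 1e-12)
})

test_that("transmission spectrum is reciprocal and order-independent", {
  ds <- build_duplex("GGGGCCCC")
  cs <- enumerate_schemes(ds)$ds_end_to_end
  spec <- contact_spec(cs$left, cs$right)
  lev <- spectrum_analysis(ds)
  grid <- seq(lev$homo - 0.5, lev$homo + 0.2, length.out = 40)
  tr <- transmission_spectrum(ds, spec, grid = grid)
  expect_equal(tr$conductance, G0_SIEMENS * tr$fermi_t_eff)
  expect_true(all(tr$t_eff >= tr$t_direct - 1e-10))

  # swapping contacts leaves T_eff unchanged (reciprocity)
  swapped <- contact_spec(cs$right, cs$left)
  tr2 <- transmission_spectrum(ds, swapped, grid = grid)
  expect_lt(max(abs(tr$t_eff - tr2$t_eff)), 1e-9)

  # point-by-point re-evaluation with single-energy ops in randomized order
  abh <- as_atom_blocks(ds)
  se <- build_self_energies(spec, abh$atoms)
  set.seed(13)
  perm <- sample(seq_along(grid))
  redo <- numeric(length(grid))
  for (k in perm)
    redo[k] <- origamiCT:::teff_at_energy(abh$matrix, se, grid[k])$t_eff
  expect_equal(redo, tr$t_eff, tolerance = 1e-12)

  expect_error(
    transmission_spectrum(ds, spec, grid = grid, fermi = lev$homo + 5),
    "interpolation-range")
})
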