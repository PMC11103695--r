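# fixture builders used across the suite; everything is generated in code

rand_hermitian <- function(n, seed, scale = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  scale * (m + t(m)) / 2
}

# identity + bounded symmetric part: well-conditioned SPD overlap
rand_spd_overlap <- function(n, seed, spread = 0.3) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  s <- (m + t(m)) / 2
  s <- spread * s / max(abs(eigen(s, symmetric = TRUE,
                                  only.values = TRUE)$values))
  diag(n) + s
}

# random partition of n orbitals into atoms plus minimal valid annotations
rand_atoms <- function(n, seed, max_block = 3) {
  set.seed(seed)
  counts <- integer(0)
  left <- n
  while (left > 0) {
    k <- min(left, sample.int(max_block, 1))
    counts <- c(counts, k)
    left <- left - k
  }
  n_at <- length(counts)
  data.frame(
    atom_id = seq_len(n_at), element = "C",
    orbital_offset = c(0L, cumsum(counts))[seq_len(n_at)],
    orbital_count = counts,
    base_id = seq_len(n_at), base_label = "G",
    strand_id = "I", helix_id = 1L,
    region = ifelse(seq_len(n_at) %in% c(1L, n_at), "terminal", "base"),
    stringsAsFactors = FALSE)
}

rand_system <- function(n, seed, spread = 0.3) {
  electronic_system(rand_hermitian(n, seed),
                    rand_spd_overlap(n, seed + 1000L, spread),
                    rand_atoms(n, seed + 2000L),
                    n_occupied = max(1L, n %/% 2L))
}

# independent generalized-eigenvalue oracle: non-symmetric standard problem
# S^{-1} H, solved by the QZ-free route eigen(solve(S, H))
gen_eigen_oracle <- function(h, s) {
  sort(Re(eigen(solve(s, h), only.values = TRUE)$values))
}

random_sequence <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# a small three-terminal toy: chain of single-orbital atoms with explicit
# couplings, one orbital per atom
chain_system <- function(eps, t, s = 0, n_occupied = NULL) {
  n <- length(eps)
  h <- diag(eps)
  for (i in seq_len(n - 1)) h[i, i + 1] <- h[i + 1, i] <- t
  ov <- diag(1, n)
  for (i in seq_len(n - 1)) ov[i, i + 1] <- ov[i + 1, i] <- s
  atoms <- data.frame(
    atom_id = seq_len(n), element = "C",
    orbital_offset = seq_len(n) - 1L, orbital_count = 1L,
    base_id = seq_len(n), base_label = "G", strand_id = "I", helix_id = 1L,
    region = ifelse(seq_len(n) %in% c(1L, n), "terminal", "base"),
    stringsAsFactors = FALSE)
  electronic_system(h, ov, atoms,
                    n_occupied = if (is.null(n_occupied)) max(1L, n - 1L)
                                 else n_occupied)
}
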