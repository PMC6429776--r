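# Shared fixtures and independent oracles. Everything is generated in
# code; nothing is read from disk except the packaged parameter files.

PARAMS <- load_default_params()

# small duplexes reused across tests (built once)
DUPLEX_GC2 <- generate_aform_duplex("GC", PARAMS)
DUPLEX_6 <- generate_aform_duplex("GGCGCC", PARAMS)

# independent superposition oracle: quaternion method (Horn 1987),
# deliberately distinct from the SVD-based implementation under test
quaternion_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  M <- crossprod(Bc, Ac)
  S <- c(M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
         M[3, 1] - M[1, 3], M[1, 2] - M[2, 1])
  K <- matrix(c(
    S[1], S[2], S[3], S[4],
    S[2], M[1, 1] - M[2, 2] - M[3, 3], M[1, 2] + M[2, 1],
    M[1, 3] + M[3, 1],
    S[3], M[1, 2] + M[2, 1], -M[1, 1] + M[2, 2] - M[3, 3],
    M[2, 3] + M[3, 2],
    S[4], M[1, 3] + M[3, 1], M[2, 3] + M[3, 2],
    -M[1, 1] - M[2, 2] + M[3, 3]), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lmax) / nrow(A)
  sqrt(max(0, msd))
}

# central finite-difference gradient of f at selected flat coordinates
fd_gradient <- function(f, X, idx, h = 1e-5) {
  vapply(idx, function(k) {
    Xp <- X; Xp[k] <- Xp[k] + h
    Xm <- X; Xm[k] <- Xm[k] - h
    (f(Xp) - f(Xm)) / (2 * h)
  }, 0)
}

# relative agreement between analytic and numerical gradients
grad_rel_dev <- function(ana, num) {
  max(abs(ana - num) / pmax(1, abs(num)))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

# tiny hand-built topology for analytic non-bonded checks
two_atom_topology <- function(sigma, epsilon, q1 = 0, q2 = 0) {
  list(n = 2L, types = c("X1", "X2"), charges = c(q1, q2),
       elements = c("C", "C"), sigma = c(sigma, sigma),
       epsilon = c(epsilon, epsilon), gb_radius = c(1.7, 1.7),
       gb_screen = c(0.72, 0.72),
       bonds = matrix(integer(), 0, 2), bond_k = numeric(),
       bond_r0 = numeric(), angles = matrix(integer(), 0, 3),
       angle_k = numeric(), angle_t0 = numeric(),
       torsions = matrix(integer(), 0, 4), torsion_k = numeric(),
       torsion_n = integer(), torsion_g = numeric(),
       pair_i = 1L, pair_j = 2L, pair_class = 0L,
       pair_sigma = sigma, pair_eps = epsilon,
       pair_qq = 332.0636 * q1 * q2,
       nb_i = 1L, nb_j = 2L, nb_sigma = sigma, nb_eps = epsilon,
       nb_qq = 332.0636 * q1 * q2, nb_is14 = FALSE,
       res = c(1L, 2L), atom_names = c("X1", "X2"),
       link_next = NA_integer_)
}
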