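# Energy model: standard bonded and non-bonded molecular-mechanics terms
# plus the four add-on restraint terms (explicit hydrogen bonds, base-pair
# co-planarity, knowledge-based backbone regularization, custom springs).
# Every term returns both the energy (kcal/mol) and its analytic gradient
# with respect to Cartesian coordinates (kcal/mol/A).
#
# Conventions (documented, fixed for reproducibility): harmonic terms are
# written k*delta^2 with no 1/2 factor; torsions are k*(1+cos(n*phi-gamma));
# 1-4 pairs are scaled by 1/1.2 (electrostatics) and 1/2 (LJ).

grad_acc <- function(g, idx, contrib) {
  m <- rowsum(contrib, idx)
  rows <- as.integer(rownames(m))
  g[rows, ] <- g[rows, ] + m
  g
}

# angle theta (radians) and its gradient for triples (i, j, k); vectorized
angle_terms <- function(X, i, j, k) {
  u <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  v <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  nu <- vnorm(u); nv <- vnorm(v)
  cth <- pmin(1, pmax(-1, vdot(u, v) / (nu * nv)))
  sth <- pmax(sqrt(1 - cth^2), 1e-10)
  theta <- acos(cth)
  gi <- (u * (cth / nu) - v / nv) / (nu * sth)
  gk <- (v * (cth / nv) - u / nu) / (nv * sth)
  list(theta = theta, gi = gi, gj = -(gi + gk), gk = gk)
}

# torsion phi (radians) and gradient for quadruples; vectorized
torsion_terms <- function(X, i, j, k, l) {
  b1 <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  b2 <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  b3 <- X[l, , drop = FALSE] - X[k, , drop = FALSE]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- vnorm(b2)
  # IUPAC sign convention (matches dihedral_deg)
  phi <- atan2(vdot(vcross(n1, n2), b2 / nb2), vdot(n1, n2))
  sq1 <- pmax(rowSums(n1^2), 1e-18)
  sq2 <- pmax(rowSums(n2^2), 1e-18)
  gi <- -n1 * (nb2 / sq1)
  gl <- n2 * (nb2 / sq2)
  c12 <- vdot(b1, b2) / nb2^2
  c32 <- vdot(b3, b2) / nb2^2
  gj <- -gi * (1 + c12) + gl * c32
  gk <- gi * c12 - gl * (1 + c32)
  list(phi = phi, gi = gi, gj = gj, gk = gk, gl = gl)
}

#' Bonded energy (bonds, angles, torsions) and gradient
#'
#' Harmonic bonds \code{k (r - r0)^2}, harmonic angles
#' \code{k (theta - theta0)^2} and periodic torsions
#' \code{k (1 + cos(n phi - gamma))}.
#'
#' @param topology An \code{rna_topology}.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param params Parameter set (unused here: parameters are resolved into
#'   the topology; kept for interface symmetry).
#' @return List with \code{bond}, \code{angle}, \code{torsion} energies and
#'   the combined \code{gradient}.
#' @export
bonded_energy <- function(topology, coords, params = NULL) {
  tq <- topology$torsions
  if (NROW(tq) == 0L) tq <- matrix(integer(), 0, 4)
  out <- .bonded_kernel(coords,
                        topology$bonds, topology$bond_k, topology$bond_r0,
                        topology$angles, topology$angle_k,
                        topology$angle_t0,
                        tq, topology$torsion_k,
                        as.integer(topology$torsion_n),
                        topology$torsion_g)
  list(bond = out$bond, angle = out$angle, torsion = out$torsion,
       gradient = out$gradient)
}

#' Non-bonded energy (Lennard-Jones, Coulomb, optional generalized Born)
#'
#' 12-6 Lennard-Jones with Lorentz-Berthelot mixing and Coulomb
#' electrostatics over the exclusion-filtered pair list; 1-4 pairs are
#' scaled. Electrostatics and van der Waals can be switched off
#' independently; the solvent model is vacuum or generalized Born. The
#' system is non-periodic and by default no cutoff is applied.
#'
#' @param topology An \code{rna_topology}.
#' @param coords n x 3 coordinate matrix.
#' @param params Parameter set (coefficients are precomputed in the
#'   topology).
#' @param config Configuration list, see \code{\link{default_config}}.
#' @return List with \code{lj}, \code{electrostatic}, \code{gb_solvation}
#'   energies and combined \code{gradient}.
#' @export
nonbonded_energy <- function(topology, coords, params = NULL,
                             config = default_config()) {
  X <- coords
  do_lj <- cfg_on(config, "vdw")
  do_el <- cfg_on(config, "electrostatics")
  cutoff <- if (is.numeric(config$cutoff)) config$cutoff else -1
  out <- .nb_kernel(X, topology$nb_i, topology$nb_j, topology$nb_sigma,
                    topology$nb_eps, topology$nb_qq / config$epsilon_in,
                    topology$nb_is14, config$scale_14_lj,
                    config$scale_14_elec, cutoff, do_lj, do_el)
  if (out$bad > 0) {
    bad <- out$bad
    stop("zero interatomic distance between atoms ",
         topology$atom_names[topology$nb_i[bad]], " (",
         topology$nb_i[bad], ") and ",
         topology$atom_names[topology$nb_j[bad]], " (",
         topology$nb_j[bad], ")", call. = FALSE)
  }
  g <- out$gradient
  e_gb <- 0
  if (do_el && identical(config$solvent, "gb")) {
    gb <- gb_energy(topology, X, config)
    e_gb <- gb$energy
    g <- g + gb$gradient
  }
  list(lj = out$lj, electrostatic = out$elec, gb_solvation = e_gb,
       gradient = g)
}

#' Explicit hydrogen-bond restraint energy
#'
#' \code{E = sum k1 exp(-(r - r_ideal)^2 / d) exp(cos(theta - theta0))}
#' where \code{r} is the hydrogen-acceptor distance and \code{theta} the
#' donor-hydrogen-acceptor angle. With \code{k1 < 0} the term is attractive
#' and minimized at ideal geometry (\code{r = r_ideal}, \code{theta =
#' theta0}); it is Gaussian in the length deviation and decays to zero for
#' distant donors/acceptors.
#'
#' @param hbonds Data frame with columns \code{d}, \code{h}, \code{a}
#'   (atom indices of donor heavy atom, hydrogen, acceptor) and
#'   \code{ideal} (ideal hydrogen-acceptor length, Angstrom). May have
#'   zero rows.
#' @param coords n x 3 coordinate matrix.
#' @param addons Add-on constants list (\code{k1}, \code{d},
#'   \code{theta0}).
#' @return List with \code{energy} and \code{gradient}.
#' @export
hbond_energy <- function(hbonds, coords, addons) {
  X <- coords
  g <- matrix(0, nrow(X), 3)
  if (is.null(hbonds) || nrow(hbonds) == 0L)
    return(list(energy = 0, gradient = g))
  if (addons$d <= 0) stop("hbond width d must be positive", call. = FALSE)
  hi <- hbonds$h; ai <- hbonds$a; di <- hbonds$d
  dv <- X[hi, , drop = FALSE] - X[ai, , drop = FALSE]
  r <- vnorm(dv)
  delta <- r - hbonds$ideal
  at <- angle_terms(X, di, hi, ai)
  th0 <- deg2rad(addons$theta0)
  co <- cos(at$theta - th0)
  e_i <- addons$k1 * exp(-delta^2 / addons$d) * exp(co)
  energy <- sum(e_i)
  # length part
  w_r <- e_i * (-2 * delta / addons$d)
  f <- dv * (w_r / r)
  g <- grad_acc(g, hi, f)
  g <- grad_acc(g, ai, -f)
  # angle part
  w_t <- e_i * (-sin(at$theta - th0))
  g <- grad_acc(g, di, at$gi * w_t)
  g <- grad_acc(g, hi, at$gj * w_t)
  g <- grad_acc(g, ai, at$gk * w_t)
  list(energy = energy, gradient = g)
}

#' Base-pair co-planarity restraint energy
#'
#' For each group (the base atoms of a Watson-Crick pair) a plane is
#' least-squares fitted to the current coordinates at every evaluation and
#' \code{E = k2 sum r_i0^2} accumulates the squared atom-plane distances.
#' The force on each atom is perpendicular to the fitted plane with
#' magnitude proportional to its distance from it; because the fitted
#' plane is itself the minimizer over plane parameters, this simple force
#' is the exact gradient.
#'
#' @param groups List of integer vectors (atom indices; at least 3
#'   non-collinear atoms each).
#' @param coords n x 3 coordinate matrix.
#' @param addons Add-on constants list (uses \code{k2}).
#' @return List with \code{energy} and \code{gradient}.
#' @export
planarity_energy <- function(groups, coords, addons) {
  X <- coords
  g <- matrix(0, nrow(X), 3)
  energy <- 0
  k2 <- if (is.list(addons)) addons$k2 else addons
  for (idx in groups) {
    if (length(idx) < 3L)
      stop("planarity group needs at least 3 atoms", call. = FALSE)
    Y <- X[idx, , drop = FALSE]
    ctr <- colMeans(Y)
    Yc <- sweep(Y, 2, ctr)
    M <- crossprod(Yc)
    ev <- eigen(M, symmetric = TRUE)
    if (ev$values[2] < 1e-8)
      stop("degenerate (collinear) planarity group", call. = FALSE)
    nrm <- ev$vectors[, 3]
    dist <- drop(Yc %*% nrm)
    energy <- energy + k2 * sum(dist^2)
    g[idx, ] <- g[idx, ] + 2 * k2 * outer(dist, nrm)
  }
  list(energy = energy, gradient = g)
}

#' Knowledge-based backbone regularization energy
#'
#' Each backbone fragment is pulled towards a reference conformer: the
#' reference coordinates are rigid-body superposed (RMSD-optimal) onto the
#' current fragment at every evaluation, then
#' \code{E = k3 sum (r_i - b_i)^2}. The term is invariant under rigid
#' motion of the fragment and equals \code{k3 * n_atoms * RMSD^2}.
#'
#' @param targets List of targets, each \code{list(idx = atom indices,
#'   ref = m x 3 reference coordinates)}.
#' @param coords n x 3 coordinate matrix.
#' @param addons Add-on constants list (uses \code{k3}).
#' @return List with \code{energy} and \code{gradient}.
#' @export
backbone_regul_energy <- function(targets, coords, addons) {
  X <- coords
  g <- matrix(0, nrow(X), 3)
  energy <- 0
  k3 <- if (is.list(addons)) addons$k3 else addons
  for (tg in targets) {
    if (length(tg$idx) != nrow(tg$ref))
      stop("backbone fragment/reference length mismatch", call. = FALSE)
    Y <- X[tg$idx, , drop = FALSE]
    fit <- kabsch_fit(tg$ref, Y)
    diff <- Y - fit$moved
    energy <- energy + k3 * sum(diff^2)
    g[tg$idx, ] <- g[tg$idx, ] + 2 * k3 * diff
  }
  list(energy = energy, gradient = g)
}

#' Custom harmonic spring restraint energy
#'
#' Positional springs \code{k (r - c)^2} towards a fixed anchor point and
#' distance springs \code{k (|r_a - r_b| - rest)^2} between two atoms.
#'
#' @param springs Data frame with columns \code{type} ("posn"/"dist"),
#'   \code{i}, \code{j}, \code{px}, \code{py}, \code{pz}, \code{rest},
#'   \code{k}. May have zero rows.
#' @param coords n x 3 coordinate matrix.
#' @return List with \code{energy} and \code{gradient}.
#' @export
spring_energy <- function(springs, coords) {
  X <- coords
  g <- matrix(0, nrow(X), 3)
  if (is.null(springs) || nrow(springs) == 0L)
    return(list(energy = 0, gradient = g))
  energy <- 0
  pos <- springs$type == "posn"
  if (any(pos)) {
    i <- springs$i[pos]
    d <- X[i, , drop = FALSE] -
      as.matrix(springs[pos, c("px", "py", "pz")])
    energy <- energy + sum(springs$k[pos] * rowSums(d * d))
    g <- grad_acc(g, i, d * (2 * springs$k[pos]))
  }
  dst <- !pos
  if (any(dst)) {
    i <- springs$i[dst]; j <- springs$j[dst]
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- pmax(vnorm(d), 1e-10)
    dev <- r - springs$rest[dst]
    energy <- energy + sum(springs$k[dst] * dev^2)
    f <- d * (2 * springs$k[dst] * dev / r)
    g <- grad_acc(g, i, f)
    g <- grad_acc(g, j, -f)
  }
  list(energy = energy, gradient = g)
}

#' Total energy with per-term breakdown and gradient
#'
#' Sums the enabled terms. With all four add-on terms disabled
#' (\code{hbonds}, \code{planarity}, \code{backbone_regularization},
#' \code{springs} set to "off") the model falls back to the plain force
#' field: those components are exactly zero. Calling this once without
#' minimizing is the single-point scoring mode.
#'
#' @param topology An \code{rna_topology}.
#' @param coords n x 3 coordinate matrix.
#' @param restraints An \code{rna_restraints} set (or NULL for none).
#' @param params Parameter set (supplies the add-on constants).
#' @param config Configuration list.
#' @return An object of class \code{energy_breakdown}: named numeric of
#'   components and \code{total}, with the gradient matrix in attribute
#'   \code{"gradient"}.
#' @export
total_energy <- function(topology, coords, restraints = NULL,
                         params = NULL, config = default_config()) {
  addons <- params$addons
  be <- bonded_energy(topology, coords, params)
  ne <- nonbonded_energy(topology, coords, params, config)
  g <- be$gradient + ne$gradient
  comp <- c(bond = be$bond, angle = be$angle, torsion = be$torsion,
            lj = ne$lj, electrostatic = ne$electrostatic,
            gb_solvation = ne$gb_solvation, hbond = 0, planarity = 0,
            backbone_regul = 0, spring = 0)
  if (!is.null(restraints)) {
    if (cfg_on(config, "hbonds") && NROW(restraints$hbonds) > 0) {
      hb <- hbond_energy(restraints$hbonds, coords, addons)
      comp["hbond"] <- hb$energy
      g <- g + hb$gradient
    }
    if (cfg_on(config, "planarity") && length(restraints$planarity) > 0) {
      pl <- planarity_energy(restraints$planarity, coords, addons)
      comp["planarity"] <- pl$energy
      g <- g + pl$gradient
    }
    if (cfg_on(config, "backbone_regularization") &&
        length(restraints$backbone) > 0) {
      bb <- backbone_regul_energy(restraints$backbone, coords, addons)
      comp["backbone_regul"] <- bb$energy
      g <- g + bb$gradient
    }
    if (cfg_on(config, "springs") && NROW(restraints$springs) > 0) {
      sp <- spring_energy(restraints$springs, coords)
      comp["spring"] <- sp$energy
      g <- g + sp$gradient
    }
  }
  out <- c(comp, total = sum(comp))
  class(out) <- "energy_breakdown"
  attr(out, "gradient") <- g
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kcal/mol):\n")
  v <- unclass(x)
  attr(v, "gradient") <- NULL
  for (nm in names(v))
    cat(sprintf("  %-16s %14.4f\n", nm, v[[nm]]))
  invisible(x)
}
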