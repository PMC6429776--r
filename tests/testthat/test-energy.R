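# Energy model: analytic values for the individual terms, the plain
# force-field fallback, gradient correctness against central finite
# differences, and rigid-motion invariance.

test_that("harmonic bond and angle conventions are k*delta^2", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X <- get_coords(DUPLEX_GC2)
  # put the first bond exactly at rest length, orthogonally to the rest
  t2 <- topo
  t2$angles <- topo$angles[0, , drop = FALSE]
  t2$angle_k <- t2$angle_t0 <- numeric()
  t2$torsions <- topo$torsions[0, , drop = FALSE]
  t2$torsion_k <- numeric(); t2$torsion_n <- integer()
  t2$torsion_g <- numeric()
  b1 <- topo$bonds[1, ]
  t2$bonds <- topo$bonds[1, , drop = FALSE]
  t2$bond_k <- topo$bond_k[1]; t2$bond_r0 <- topo$bond_r0[1]
  dir <- X[b1[2], ] - X[b1[1], ]
  X2 <- X
  X2[b1[2], ] <- X[b1[1], ] + dir / sqrt(sum(dir^2)) * t2$bond_r0
  expect_equal(bonded_energy(t2, X2, PARAMS)$bond, 0, tolerance = 1e-12)
  # displaced by delta: k * delta^2 exactly
  X2[b1[2], ] <- X[b1[1], ] + dir / sqrt(sum(dir^2)) * (t2$bond_r0 + 0.2)
  expect_equal(bonded_energy(t2, X2, PARAMS)$bond, t2$bond_k * 0.04,
               tolerance = 1e-10)
  # angle displaced by delta with constant k -> k * delta^2
  tri <- matrix(c(1, 0, 0, 0, 0, 0, cos(1.9), sin(1.9), 0), 3, 3,
                byrow = TRUE)
  ta <- t2
  ta$bonds <- topo$bonds[0, , drop = FALSE]
  ta$bond_k <- ta$bond_r0 <- numeric()
  ta$angles <- matrix(c(1L, 2L, 3L), 1)
  ta$angle_k <- 63; ta$angle_t0 <- 1.6
  expect_equal(bonded_energy(ta, tri, PARAMS)$angle, 63 * 0.3^2,
               tolerance = 1e-10)
})

test_that("two neutral LJ particles at the minimum give -epsilon", {
  topo <- two_atom_topology(sigma = 3.2, epsilon = 0.5)
  X <- matrix(c(0, 0, 0, 3.2 * 2^(1 / 6), 0, 0), 2, 3, byrow = TRUE)
  cfg <- default_config(); cfg$solvent <- "vacuum"
  nb <- nonbonded_energy(topo, X, PARAMS, cfg)
  expect_equal(nb$lj, -0.5, tolerance = 1e-12)
  expect_equal(nb$electrostatic, 0)
  # gradient vanishes at the minimum
  expect_lt(max(abs(nb$gradient)), 1e-10)
})

test_that("disabled electrostatics and vdW give exactly zero components", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X <- get_coords(DUPLEX_GC2)
  cfg <- default_config()
  cfg$electrostatics <- "off"
  nb <- nonbonded_energy(topo, X, PARAMS, cfg)
  expect_identical(nb$electrostatic, 0)
  expect_identical(nb$gb_solvation, 0)
  cfg <- default_config(); cfg$vdw <- "off"; cfg$solvent <- "vacuum"
  expect_identical(nonbonded_energy(topo, X, PARAMS, cfg)$lj, 0)
})

test_that("coincident atoms raise a singularity error naming the pair", {
  topo <- two_atom_topology(sigma = 3.2, epsilon = 0.5)
  X <- matrix(0, 2, 3)
  expect_error(nonbonded_energy(topo, X, PARAMS, default_config()),
               "zero interatomic distance.*X1.*X2")
})

test_that("GB self-energy of an isolated charge matches the Born formula", {
  topo <- two_atom_topology(sigma = 3.2, epsilon = 0, q1 = 1, q2 = 0)
  topo$n <- 1L
  for (f in c("types", "charges", "elements", "sigma", "epsilon",
              "gb_radius", "gb_screen", "res", "atom_names"))
    topo[[f]] <- topo[[f]][1]
  topo$pair_i <- integer(); topo$pair_j <- integer()
  X <- matrix(0, 1, 3)
  cfg <- default_config()
  e <- rnarefine:::gb_energy(topo, X, cfg)$energy
  rho <- 1.7 - rnarefine:::GB_OFFSET
  born <- -0.5 * 332.0636 * (1 - 1 / 78.5) * 1^2 / rho
  expect_equal(e, born, tolerance = 1e-12)
})

test_that("hydrogen-bond term has the printed analytic values", {
  ad <- PARAMS$addons
  # ideal geometry: linear donor-H-acceptor at the ideal length
  X <- matrix(c(0, 0, 0,    1.01, 0, 0,    1.01 + 1.84, 0, 0),
              3, 3, byrow = TRUE)
  hb <- data.frame(d = 1L, h = 2L, a = 3L, ideal = 1.84)
  e <- hbond_energy(hb, X, ad)$energy
  expect_equal(e, -exp(1), tolerance = 1e-9)   # k1 = -1, cos(0) = 1
  # empty list is zero
  expect_equal(hbond_energy(hb[0, ], X, ad)$energy, 0)
  # Gaussian decay in the length deviation, monotone to zero
  deltas <- seq(0, 6, by = 0.5)
  es <- vapply(deltas, function(dd) {
    X2 <- X; X2[3, 1] <- X[2, 1] + 1.84 + dd
    hbond_energy(hb, X2, ad)$energy
  }, 0)
  expect_true(all(diff(es) > 0))        # increases towards 0
  expect_lt(abs(es[length(es)]), 1e-50)
  # minimized over the angle exactly at theta0 (grid check)
  angs <- seq(120, 240, by = 5)
  ea <- vapply(angs, function(a) {
    th <- a * pi / 180
    X2 <- X
    X2[3, ] <- X[2, ] + 1.84 * c(cos(pi - th), sin(pi - th), 0)
    hbond_energy(hb, X2, ad)$energy
  }, 0)
  expect_equal(angs[which.min(ea)], 180)
  expect_error(hbond_energy(hb, X, list(k1 = -1, d = -1, theta0 = 180)),
               "must be positive")
})

test_that("planarity term matches the symmetric-set oracle", {
  ad <- list(k2 = 1)
  # 4 atoms in the z=0 plane, 2 atoms at +/-1: LS plane stays at z=0
  # the in-plane square is wide enough that the z = 0 mid-plane is the
  # least-squares optimum
  X <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0),
             c(1, 1, 1), c(1, 1, -1))
  pl <- planarity_energy(list(1:6), X, ad)
  expect_equal(pl$energy, 2.0, tolerance = 1e-10)
  # perfectly coplanar group is exactly zero; forces perpendicular
  expect_equal(planarity_energy(list(1:4), X, ad)$energy, 0,
               tolerance = 1e-20)
  expect_equal(abs(pl$gradient[5, ]), c(0, 0, 2), tolerance = 1e-10)
  # collinear group is degenerate
  Xc <- cbind(1:4, 1:4, 1:4)
  expect_error(planarity_energy(list(1:4), Xc, ad), "collinear")
})

test_that("backbone regularization equals k3 * n * RMSD^2 after fitting", {
  set.seed(7)
  ref <- matrix(rnorm(27), 9, 3)
  frag <- ref + 0.3 * matrix(rnorm(27), 9, 3)
  X <- frag
  tg <- list(list(idx = 1:9, ref = ref))
  e <- backbone_regul_energy(tg, X, list(k3 = 10))$energy
  rmsd <- quaternion_rmsd(frag, ref)     # independent RMSD routine
  expect_equal(e, 10 * 9 * rmsd^2, tolerance = 1e-8)
  # identical fragment: zero; rigidly moved fragment: zero
  expect_equal(backbone_regul_energy(list(list(idx = 1:9, ref = frag)),
                                     X, list(k3 = 10))$energy, 0,
               tolerance = 1e-16)
  R <- random_rotation()
  Xr <- sweep(frag %*% R, 2, c(3, -2, 7), `+`)
  expect_lt(backbone_regul_energy(list(list(idx = 1:9, ref = frag)),
                                  Xr, list(k3 = 10))$energy, 1e-8)
  expect_error(backbone_regul_energy(list(list(idx = 1:8, ref = ref)),
                                     X, list(k3 = 10)), "mismatch")
})

test_that("spring restraints follow the harmonic definitions", {
  X <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  posn <- data.frame(type = "posn", i = 1L, j = NA_integer_,
                     px = 2, py = 0, pz = 0, rest = 0, k = 0.5)
  expect_equal(spring_energy(posn, X)$energy, 0.5 * 4)  # |r-c| = 2
  at_anchor <- posn; at_anchor$px <- 0
  expect_equal(spring_energy(at_anchor, X)$energy, 0)
  dist <- data.frame(type = "dist", i = 1L, j = 2L, px = NA_real_,
                     py = NA_real_, pz = NA_real_, rest = 5, k = 3)
  expect_equal(spring_energy(dist, X)$energy, 0)
  dist$rest <- 3
  expect_equal(spring_energy(dist, X)$energy, 3 * 4)
})

test_that("disabling all four add-ons falls back to the plain force field", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X <- get_coords(DUPLEX_GC2)
  cfg <- default_config()
  cfg[c("hbonds", "planarity", "backbone_regularization",
        "springs")] <- "off"
  rset <- build_restraints(DUPLEX_GC2, PARAMS, cfg)
  eb <- total_energy(topo, X, rset, PARAMS, cfg)
  expect_identical(eb[["hbond"]], 0)
  expect_identical(eb[["planarity"]], 0)
  expect_identical(eb[["backbone_regul"]], 0)
  expect_identical(eb[["spring"]], 0)
  plain <- bonded_energy(topo, X, PARAMS)
  nb <- nonbonded_energy(topo, X, PARAMS, cfg)
  expect_equal(eb[["total"]],
               plain$bond + plain$angle + plain$torsion + nb$lj +
                 nb$electrostatic + nb$gb_solvation, tolerance = 1e-12)
})

test_that("the total equals the component sum to 1e-9 relative", {
  topo <- build_topology(DUPLEX_6, PARAMS)
  X <- get_coords(DUPLEX_6)
  rset <- build_restraints(DUPLEX_6, PARAMS, default_config())
  eb <- total_energy(topo, X, rset, PARAMS, default_config())
  v <- unclass(eb)
  expect_equal(v[["total"]], sum(v[names(v) != "total"]),
               tolerance = 1e-9)
})

test_that("every term's gradient matches finite differences on random configurations", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X0 <- get_coords(DUPLEX_GC2)
  cfg <- default_config()
  rset <- build_restraints(DUPLEX_GC2, PARAMS, cfg)
  terms <- list(
    bonded = function(x) {
      b <- bonded_energy(topo, x, PARAMS)
      list(e = b$bond + b$angle + b$torsion, g = b$gradient)
    },
    nonbonded_vacuum = function(x) {
      c2 <- cfg; c2$solvent <- "vacuum"
      b <- nonbonded_energy(topo, x, PARAMS, c2)
      list(e = b$lj + b$electrostatic, g = b$gradient)
    },
    gb = function(x) {
      b <- rnarefine:::gb_energy(topo, x, cfg)
      list(e = b$energy, g = b$gradient)
    },
    hbond = function(x) {
      b <- hbond_energy(rset$hbonds, x, PARAMS$addons)
      list(e = b$energy, g = b$gradient)
    },
    planarity = function(x) {
      b <- planarity_energy(rset$planarity, x, PARAMS$addons)
      list(e = b$energy, g = b$gradient)
    },
    backbone = function(x) {
      tg <- rnarefine:::backbone_targets(DUPLEX_GC2,
                                         build_builtin_library())
      tg <- list(list(idx = 1:9,
                      ref = build_builtin_library()$fragments[[1]]))
      b <- backbone_regul_energy(tg, x, PARAMS$addons)
      list(e = b$energy, g = b$gradient)
    },
    total = function(x) {
      eb <- total_energy(topo, x, rset, PARAMS, cfg)
      list(e = unclass(eb)[["total"]], g = attr(eb, "gradient"))
    })
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    X <- X0 + 0.08 * matrix(rnorm(length(X0)), nrow(X0), 3)
    idx <- sample(length(X), 6)
    for (nm in names(terms)) {
      f <- terms[[nm]]
      ana <- f(X)$g[idx]
      num <- fd_gradient(function(x) f(matrix(x, ncol = 3))$e, X, idx)
      dev <- grad_rel_dev(ana, num)
      worst <- max(worst, dev)
      expect_lt(dev, 1e-4, label = paste(nm, "rep", rep))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("internal terms are invariant under global rigid motion", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X <- get_coords(DUPLEX_GC2)
  cfg <- default_config()
  rset <- build_restraints(DUPLEX_GC2, PARAMS, cfg)
  e0 <- unclass(total_energy(topo, X, rset, PARAMS, cfg))
  set.seed(9)
  for (rep in 1:3) {
    R <- random_rotation()
    Xr <- sweep(X %*% R, 2, rnorm(3, sd = 10), `+`)
    er <- unclass(total_energy(topo, Xr, rset, PARAMS, cfg))
    expect_equal(er[["total"]], e0[["total"]],
                 tolerance = 1e-8 / max(1, abs(e0[["total"]])))
  }
  # positional springs are the documented exception
  sp <- data.frame(type = "posn", i = 1L, j = NA_integer_, px = 0, py = 0,
                   pz = 0, rest = 0, k = 1)
  e1 <- spring_energy(sp, X)$energy
  e2 <- spring_energy(sp, sweep(X, 2, c(5, 0, 0), `+`))$energy
  expect_gt(abs(e2 - e1), 1)
})

test_that("evaluation is deterministic and independent of pair-list order", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  X <- get_coords(DUPLEX_GC2)
  cfg <- default_config()
  e1 <- unclass(total_energy(topo, X, NULL, PARAMS, cfg))
  e2 <- unclass(total_energy(topo, X, NULL, PARAMS, cfg))
  expect_identical(e1, e2)
  # shuffle the non-bonded pair list: same physics, same energy
  set.seed(4)
  perm <- sample(length(topo$nb_i))
  t2 <- topo
  for (f in c("nb_i", "nb_j", "nb_sigma", "nb_eps", "nb_qq", "nb_is14"))
    t2[[f]] <- topo[[f]][perm]
  perm2 <- sample(length(topo$pair_i))
  for (f in c("pair_i", "pair_j", "pair_class", "pair_sigma", "pair_eps",
              "pair_qq"))
    t2[[f]] <- topo[[f]][perm2]
  e3 <- unclass(total_energy(t2, X, NULL, PARAMS, cfg))
  expect_equal(e1[["total"]], e3[["total"]], tolerance = 1e-12)
})
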