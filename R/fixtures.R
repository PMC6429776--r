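# Synthetic-structure generators: ideal A-form duplexes with correct
# Watson-Crick geometry, random decoys at controlled RMSD, and targeted
# backbone perturbations. These stand in for experimental structures in
# tests and in the scaled-down decoy-funnel experiment.
#
# The duplex is built residue-by-residue with a helical screw transform
# derived from standard A-form backbone torsions (alpha -68, beta 178,
# gamma 54, delta 82, epsilon -153, zeta -71 degrees), which yields a
# rise of ~2.81 A and a twist of ~32.7 deg per step; the complementary
# strand is placed by superposing its bases onto ideal Watson-Crick
# pairing positions derived from the packaged pair transforms.

# junction torsions calibrated (once, at design time) so that the helix
# emerging from the template internal geometry has exactly the standard
# A-form parameters: twist 32.7 deg, rise 2.81 A per step. They stay
# within a few degrees of textbook A-form values.
.aform_tors <- list(epsilon = -156.77, zeta = -75.24, alpha = -69.07,
                    beta = 178.0)
.aform_geom <- list(b_o3p = 1.607, a_c3o3p = 119.7,
                    b_po5 = 1.593, a_o3po5 = 104.0,
                    b_o5c5 = 1.440, a_po5c5 = 120.9,
                    b_c5c4 = 1.510, a_o5c5c4 = 111.5)

.complement <- c(A = "U", U = "A", G = "C", C = "G")

tpl_coords <- function(tpl, names) {
  m <- as.matrix(tpl$atoms[match(names, tpl$atoms$name),
                           c("x", "y", "z")])
  if (anyNA(m)) stop("template ", tpl$name, " lacks atoms ",
                     paste(names[is.na(m[, 1])], collapse = ","),
                     call. = FALSE)
  unname(m)
}

# NeRF-extend the backbone anchor (P, O5', C5', C4') of the next residue
# from the (C4', C3', O3') of the current one. The anchor's internal
# geometry (bonds/angles among P, O5', C5', C4') is measured from the
# template being placed, so the subsequent superposition is exact and the
# junction torsions/angles come out at their A-form targets.
next_anchor <- function(c4, c3, o3, tpl, tors = .aform_tors) {
  g <- .aform_geom; t <- tors
  tc <- tpl_coords(tpl, c("P", "O5'", "C5'", "C4'"))
  blen <- function(i, j) sqrt(sum((tc[i, ] - tc[j, ])^2))
  p <- nerf_place(c4, c3, o3, g$b_o3p, g$a_c3o3p, t$epsilon)
  o5 <- nerf_place(c3, o3, p, blen(1, 2), g$a_o3po5, t$zeta)
  c5 <- nerf_place(o3, p, o5, blen(2, 3),
                   angle_deg3(tc[1, ], tc[2, ], tc[3, ]), t$alpha)
  c4n <- nerf_place(p, o5, c5, blen(3, 4),
                    angle_deg3(tc[2, ], tc[3, ], tc[4, ]),
                    dihedral_deg(tc[1, ], tc[2, ], tc[3, ], tc[4, ]))
  rbind(p, o5, c5, c4n)
}

# place a residue template so that its (P, O5', C5', C4') matches anchor
place_on_anchor <- function(tpl, anchor) {
  src <- tpl_coords(tpl, c("P", "O5'", "C5'", "C4'"))
  fit <- kabsch_fit(src, anchor)
  all <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  sweep(all %*% fit$R, 2, fit$t, `+`)
}

build_strand <- function(sequence, params, tors = .aform_tors) {
  tpls <- lapply(sequence, residue_template, params = params)
  # start: first template in its own frame
  placed <- list(as.matrix(tpls[[1]]$atoms[, c("x", "y", "z")]))
  for (k in seq_along(tpls)[-1]) {
    prev <- placed[[k - 1L]]
    pn <- tpls[[k - 1L]]$atoms$name
    anchor <- next_anchor(prev[match("C4'", pn), ],
                          prev[match("C3'", pn), ],
                          prev[match("O3'", pn), ], tpls[[k]], tors)
    placed[[k]] <- place_on_anchor(tpls[[k]], anchor)
  }
  list(tpls = tpls, coords = placed)
}

base_frame <- function(tpl, coords = NULL) {
  fa <- if (tpl$class %in% c("A", "G")) c("N9", "C8", "C4")
        else c("N1", "C6", "C2")
  X <- if (is.null(coords)) as.matrix(tpl$atoms[, c("x", "y", "z")])
       else coords
  i <- match(fa, tpl$atoms$name)
  frame_from_atoms(X[i[1], ], X[i[2], ], X[i[3], ])
}

# target coordinates for the Watson-Crick partner of a placed residue
pair_target <- function(tpl1, coords1, tpl2, params) {
  key <- paste(tpl1$class, tpl2$class)
  pt <- params$addons$pairt[[key]]
  if (is.null(pt)) stop("no pair transform for classes ", key,
                        call. = FALSE)
  f1 <- base_frame(tpl1, coords1)
  f2 <- base_frame(tpl2)
  X2 <- as.matrix(tpl2$atoms[, c("x", "y", "z")])
  loc <- sweep(X2, 2, f2$o) %*% f2$R           # template2 in its own frame
  inf1 <- sweep(loc %*% t(pt$R), 2, pt$t, `+`) # paired, in frame1 coords
  sweep(inf1 %*% t(f1$R), 2, f1$o, `+`)        # to world
}

strand_atoms_df <- function(tpls, coords, chain, drop5p = TRUE) {
  n <- length(tpls)
  rows <- list()
  for (k in seq_len(n)) {
    at <- tpls[[k]]$atoms
    keep <- rep(TRUE, nrow(at))
    if (k == 1L && drop5p) keep[at$name %in% c("P", "OP1", "OP2")] <- FALSE
    else keep[at$name == "HO5'"] <- FALSE
    if (k < n) keep[at$name == "HO3'"] <- FALSE
    X <- coords[[k]]
    rows[[k]] <- data.frame(
      serial = NA_integer_, name = at$name[keep],
      resname = tpls[[k]]$name, chain = chain, resnum = k, icode = " ",
      x = X[keep, 1], y = X[keep, 2], z = X[keep, 3],
      element = at$element[keep], record = "ATOM",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate an ideal A-form double helix
#'
#' Builds a duplex from the given strand sequence (RNA alphabet ACGU);
#' the complementary strand is generated automatically and placed so that
#' every base pair has ideal Watson-Crick geometry. The construction is
#' deterministic, clash-free, and the geometric base-pair detector finds
#' every pair.
#'
#' @param sequence Character string over A/C/G/U (5' to 3' of strand A).
#' @param params Parameter set (default: packaged).
#' @return An \code{rna_structure} with chains A and B.
#' @examples
#' \donttest{
#' dx <- generate_aform_duplex("GGCGCC")
#' dx
#' }
#' @export
generate_aform_duplex <- function(sequence, params = load_default_params()) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 2L)
    stop("sequence must have at least 2 residues", call. = FALSE)
  bad <- setdiff(seq1, names(.complement))
  if (length(bad))
    stop("invalid sequence character(s): ", paste(unique(bad),
                                                  collapse = ", "),
         call. = FALSE)
  seq2 <- rev(unname(.complement[seq1]))
  s1 <- build_strand(seq1, params)
  s2 <- build_strand(seq2, params)
  n <- length(seq1)
  # ideal pairing targets for the strand-2 bases, derived from strand 1
  dst <- list(); sel2 <- list()
  base_heavy <- function(tpl) {
    tpl$atoms$name[tpl$atoms$element != "H" &
                   !(tpl$atoms$name %in% c(.backbone_names, .sugar_names))]
  }
  for (k in seq_len(n)) {
    m <- n + 1L - k                       # strand-2 residue paired with k
    tpl2 <- s2$tpls[[m]]
    target_full <- pair_target(s1$tpls[[k]], s1$coords[[k]], tpl2, params)
    sel2[[m]] <- match(c(base_heavy(tpl2), "C1'"), tpl2$atoms$name)
    dst[[m]] <- target_full[sel2[[m]], , drop = FALSE]
  }
  # place strand 2 by duplex (pseudo-)dyad symmetry: align its helical
  # axis antiparallel to strand 1's, then optimize only the rotation
  # about, and the shift along, the common axis -- so pairing geometry is
  # uniform over all steps
  strand_screw <- function(s) {
    a <- if (length(s$coords) >= 3L) 2L else 1L
    com <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'", "O4'", "C2'")
    pick <- function(k) s$coords[[k]][match(com, s$tpls[[k]]$atoms$name), ,
                                      drop = FALSE]
    fit <- kabsch_fit(pick(a), pick(a + 1L))
    sc <- screw_axis(fit$R, fit$t)
    if (sc$h < 0) { sc$u <- -sc$u; sc$h <- -sc$h }
    sc
  }
  sc1 <- strand_screw(s1)
  sc2 <- strand_screw(s2)
  # rotation taking u2 to -u1
  v <- pracma_cross(sc2$u, -sc1$u)
  sv <- sqrt(sum(v^2))
  Q <- if (sv < 1e-12) {
    if (sum(sc2$u * -sc1$u) > 0) diag(3) else
      rotation_about_axis(ortho_vec(sc2$u), pi)
  } else rotation_about_axis(v / sv,
                             atan2(sv, sum(sc2$u * -sc1$u)))
  pre <- function(X) sweep(sweep(X, 2, sc2$p) %*% t(Q), 2, sc1$p, `+`)
  place <- function(X, phi, z) {
    Rp <- rotation_about_axis(sc1$u, phi)
    sweep(sweep(pre(X), 2, sc1$p) %*% t(Rp), 2,
          sc1$p + z * sc1$u, `+`)
  }
  objective <- function(par) {
    err <- 0
    for (m in seq_len(n)) {
      Y <- place(s2$coords[[m]][sel2[[m]], , drop = FALSE], par[1], par[2])
      err <- err + sum((Y - dst[[m]])^2)
    }
    err
  }
  grid <- expand.grid(phi = seq(0, 2 * pi, length.out = 73)[-73],
                      z = seq(-6, 6, by = 1))
  vals <- mapply(function(phi, z) objective(c(phi, z)), grid$phi, grid$z)
  start <- as.numeric(grid[which.min(vals), ])
  best <- stats::optim(start, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  s2$coords <- lapply(s2$coords, place, phi = best$par[1],
                      z = best$par[2])
  atoms <- rbind(strand_atoms_df(s1$tpls, s1$coords, "A"),
                 strand_atoms_df(s2$tpls, s2$coords, "B"))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate random decoys at controlled RMSD
#'
#' Each decoy displaces all atoms by i.i.d. Gaussian noise, rescaled so
#' that the superposed RMSDs of the decoy set are spread evenly over
#' \code{(0, rmsd_max]}. Deterministic under a fixed seed.
#'
#' @param structure Reference \code{rna_structure}.
#' @param n Number of decoys.
#' @param rmsd_max Largest target RMSD, Angstrom.
#' @param seed Integer seed.
#' @return List of \code{list(structure =, rmsd =)} with the achieved
#'   superposed RMSD.
#' @export
generate_decoys <- function(structure, n, rmsd_max, seed = 1L) {
  stopifnot(n >= 1L, rmsd_max > 0)
  X <- get_coords(structure)
  targets <- rmsd_max * seq_len(n) / n
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      Z <- matrix(stats::rnorm(length(X)), nrow(X), 3)
      s <- targets[k] / sqrt(mean(rowSums(Z^2)))
      for (it in 1:3) {
        ach <- kabsch_rmsd(X, X + s * Z)
        s <- s * targets[k] / ach
      }
      Xp <- X + s * Z
      list(structure = set_coords(structure, Xp),
           rmsd = kabsch_rmsd(X, Xp))
    })
  })
}

#' Randomly perturb only the backbone atoms
#'
#' Adds i.i.d. Gaussian noise of the given amplitude to the phosphate /
#' sugar-backbone atoms (P, OP1, OP2, O5', C5', C4', C3', O3'); base
#' atoms are untouched. Used to create outlying backbone conformers.
#'
#' @param structure An \code{rna_structure}.
#' @param amplitude Gaussian standard deviation per coordinate, Angstrom.
#' @param seed Integer seed.
#' @return Perturbed \code{rna_structure}.
#' @export
perturb_backbone <- function(structure, amplitude, seed = 1L) {
  stopifnot(amplitude > 0)
  X <- get_coords(structure)
  sel <- structure$atoms$name %in% .backbone_names
  with_seed(seed, {
    X[sel, ] <- X[sel, ] + amplitude * matrix(stats::rnorm(3 * sum(sel)),
                                              sum(sel), 3)
  })
  set_coords(structure, X)
}
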