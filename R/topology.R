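# Molecular topology: bond graph, angle/torsion enumeration, exclusion
# sets and the precomputed non-bonded pair list with per-pair Lennard-Jones
# and Coulomb coefficients. Built once per structure; energy evaluations
# then reduce to vectorized arithmetic over index vectors.

COULOMB_KE <- 332.0636  # kcal*A/mol/e^2

.backbone_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
.sugar_names <- c("C1'", "C2'", "O2'", "O4'", "H1'", "H2'", "H2''", "HO2'",
                  "H3'", "H4'", "H5'", "H5''", "HO3'", "HO5'")

# residues i and i+1 of the same chain are linked when O3'(i)..P(i+1) is
# within this distance (Angstrom)
.link_cutoff <- 2.5

residue_link_map <- function(structure) {
  # returns, for each residue r, the index of the next residue it is
  # covalently linked to (O3'-P), or NA
  rt <- residue_table(structure)
  a <- structure$atoms
  nres <- nrow(rt)
  nxt <- rep(NA_integer_, nres)
  if (nres < 2L) return(nxt)
  X <- get_coords(structure)
  for (r in seq_len(nres - 1L)) {
    if (rt$chain[r] != rt$chain[r + 1L]) next
    o3 <- which(a$res == r & a$name == "O3'")
    p <- which(a$res == r + 1L & a$name == "P")
    if (length(o3) == 1L && length(p) == 1L &&
        sqrt(sum((X[o3, ] - X[p, ])^2)) <= .link_cutoff)
      nxt[r] <- r + 1L
  }
  nxt
}

#' Build the molecular topology of a structure
#'
#' Assigns atom types and charges from the residue templates, collects
#' intra-residue bonds from the templates plus the inter-residue
#' O3'(i)-P(i+1) linkage (consecutive residues of a chain within 2.5
#' Angstrom), enumerates angles and torsions from the bond graph, builds
#' the 1-2/1-3/1-4 exclusion classification and precomputes the non-bonded
#' pair list.
#'
#' @param structure An \code{rna_structure}; hydrogens may be absent.
#' @param params An \code{rna_params} parameter set.
#' @return An object of class \code{rna_topology}.
#' @export
build_topology <- function(structure, params) {
  a <- structure$atoms
  n <- nrow(a)
  rt <- residue_table(structure)
  nxt <- residue_link_map(structure)
  typ <- character(n); q <- numeric(n)
  bonds <- list()
  for (r in seq_len(nrow(rt))) {
    tpl <- tryCatch(residue_template(rt$resname[r], params),
                    error = function(e)
                      stop("chain ", rt$chain[r], " residue ", rt$resnum[r],
                           ": ", conditionMessage(e), call. = FALSE))
    rows <- which(a$res == r)
    tname <- tpl$atoms$name
    here <- match(a$name[rows], tname)
    if (anyNA(here))
      stop("chain ", rt$chain[r], " residue ", rt$resnum[r],
           ": atom(s) not in template ", tpl$name, ": ",
           paste(a$name[rows][is.na(here)], collapse = ", "),
           call. = FALSE)
    typ[rows] <- tpl$atoms$type[here]
    q[rows] <- tpl$atoms$charge[here]
    # heavy-atom completeness (5'-terminal phosphate group may be absent)
    heavy <- tname[tpl$atoms$element != "H"]
    first_of_chain <- r == 1L || rt$chain[r] != rt$chain[r - 1L]
    optional <- if (first_of_chain) c("P", "OP1", "OP2") else character()
    miss <- setdiff(setdiff(heavy, optional), a$name[rows])
    if (length(miss))
      stop("chain ", rt$chain[r], " residue ", rt$resnum[r],
           ": missing heavy atom(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if ("HO3'" %in% a$name[rows] && !is.na(nxt[r]))
      stop("chain ", rt$chain[r], " residue ", rt$resnum[r],
           ": has both HO3' and a 3' phosphodiester linkage",
           call. = FALSE)
    idx_of <- function(nm) rows[match(nm, a$name[rows])]
    for (b in seq_len(nrow(tpl$bonds))) {
      i <- idx_of(tpl$bonds[b, 1]); j <- idx_of(tpl$bonds[b, 2])
      if (!is.na(i) && !is.na(j))
        bonds[[length(bonds) + 1L]] <- c(i, j)
    }
    if (!is.na(nxt[r])) {
      o3 <- idx_of("O3'")
      p <- which(a$res == nxt[r] & a$name == "P")
      bonds[[length(bonds) + 1L]] <- c(o3, p)
    }
  }
  bmat <- do.call(rbind, bonds)
  bmat <- t(apply(bmat, 1, sort))
  bmat <- bmat[!duplicated(bmat), , drop = FALSE]
  # order bonds canonically so the topology is independent of input order
  bmat <- bmat[order(bmat[, 1], bmat[, 2]), , drop = FALSE]

  adj <- vector("list", n)
  for (b in seq_len(nrow(bmat))) {
    i <- bmat[b, 1]; j <- bmat[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)

  angles <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    for (c2 in seq_len(ncol(cmb)))
      angles[[length(angles) + 1L]] <- c(cmb[1, c2], j, cmb[2, c2])
  }
  amat <- do.call(rbind, angles)

  torsions <- list()
  for (b in seq_len(nrow(bmat))) {
    j <- bmat[b, 1]; k <- bmat[b, 2]
    for (i in setdiff(adj[[j]], k))
      for (l in setdiff(adj[[k]], j))
        if (i != l)
          torsions[[length(torsions) + 1L]] <- c(i, j, k, l)
  }
  tmat <- do.call(rbind, torsions)

  pkey <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    lo * (n + 1) + hi
  }
  k12 <- pkey(bmat[, 1], bmat[, 2])
  k13 <- setdiff(pkey(amat[, 1], amat[, 3]), k12)
  k14 <- if (!is.null(tmat))
    setdiff(pkey(tmat[, 1], tmat[, 4]), c(k12, k13)) else numeric()

  # resolve bonded parameters
  bp <- resolve_bonds(bmat, typ, params, a)
  ap <- resolve_angles(amat, typ, params, a)
  tp <- resolve_torsions(tmat, typ, params, a)

  # full pair list (i < j), classified
  pi_ <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pj_ <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n),
                use.names = FALSE)
  keyall <- pkey(pi_, pj_)
  cls <- integer(length(keyall))          # 0 normal, 1 = 1-4, 2 = excluded
  cls[keyall %in% c(k12, k13)] <- 2L
  cls[keyall %in% k14] <- 1L

  at <- params$atom_types
  ti <- match(typ, at$type)
  sig <- at$sigma[ti]; eps <- at$epsilon[ti]
  sij <- (sig[pi_] + sig[pj_]) / 2
  eij <- sqrt(eps[pi_] * eps[pj_])
  qq <- COULOMB_KE * q[pi_] * q[pj_]

  topo <- list(
    n = n, types = typ, charges = q,
    elements = a$element,
    sigma = sig, epsilon = eps,
    gb_radius = at$gb_radius[ti], gb_screen = at$gb_screen[ti],
    bonds = bmat, bond_k = bp$k, bond_r0 = bp$r0,
    angles = amat, angle_k = ap$k, angle_t0 = deg2rad(ap$theta0),
    torsions = tp$quads, torsion_k = tp$k, torsion_n = tp$n,
    torsion_g = deg2rad(tp$gamma),
    pair_i = pi_, pair_j = pj_, pair_class = cls,
    pair_sigma = sij, pair_eps = eij, pair_qq = qq,
    nb_i = pi_[cls != 2L], nb_j = pj_[cls != 2L],
    nb_sigma = sij[cls != 2L], nb_eps = eij[cls != 2L],
    nb_qq = qq[cls != 2L], nb_is14 = (cls == 1L)[cls != 2L],
    res = a$res, atom_names = a$name,
    link_next = nxt)
  class(topo) <- "rna_topology"
  topo
}

resolve_bonds <- function(bmat, typ, params, a) {
  k <- numeric(nrow(bmat)); r0 <- numeric(nrow(bmat))
  for (b in seq_len(nrow(bmat))) {
    p <- bond_param(params, typ[bmat[b, 1]], typ[bmat[b, 2]])
    if (is.null(p))
      stop("no bond parameter for ", a$name[bmat[b, 1]], "-",
           a$name[bmat[b, 2]], " (", typ[bmat[b, 1]], "-", typ[bmat[b, 2]],
           ")", call. = FALSE)
    k[b] <- p$k; r0[b] <- p$r0
  }
  list(k = k, r0 = r0)
}

resolve_angles <- function(amat, typ, params, a) {
  k <- numeric(nrow(amat)); t0 <- numeric(nrow(amat))
  for (i in seq_len(nrow(amat))) {
    p <- angle_param(params, typ[amat[i, 1]], typ[amat[i, 2]],
                     typ[amat[i, 3]])
    if (is.null(p))
      stop("no angle parameter for ",
           paste(a$name[amat[i, ]], collapse = "-"), " (",
           paste(typ[amat[i, ]], collapse = "-"), ")", call. = FALSE)
    k[i] <- p$k; t0[i] <- p$theta0
  }
  list(k = k, theta0 = t0)
}

resolve_torsions <- function(tmat, typ, params, a) {
  quads <- list(); k <- numeric(); n <- integer(); g <- numeric()
  for (i in seq_len(NROW(tmat))) {
    p <- torsion_param(params, typ[tmat[i, 1]], typ[tmat[i, 2]],
                       typ[tmat[i, 3]], typ[tmat[i, 4]])
    if (is.null(p))
      stop("no torsion parameter for ",
           paste(typ[tmat[i, ]], collapse = "-"), call. = FALSE)
    for (r in seq_len(nrow(p))) {
      if (p$k[r] == 0) next
      quads[[length(quads) + 1L]] <- tmat[i, ]
      k <- c(k, p$k[r]); n <- c(n, p$n[r]); g <- c(g, p$gamma[r])
    }
  }
  list(quads = do.call(rbind, quads), k = k, n = n, gamma = g)
}

#' @export
print.rna_topology <- function(x, ...) {
  cat("Topology: ", x$n, " atoms, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", NROW(x$torsions), " torsion terms\n",
      sep = "")
  invisible(x)
}

# ---- hydrogen completion ---------------------------------------------------

#' Add missing hydrogens at template-ideal positions
#'
#' For every hydrogen listed in a residue's template but absent from the
#' structure, the local cluster of heavy atoms around its parent is
#' superposed from the template onto the structure and the template
#' hydrogen position is mapped through that transform. Placement is fully
#' deterministic and idempotent; existing hydrogens are never moved.
#' Terminal hydroxyl hydrogens (HO5', HO3') are only generated at chain
#' termini lacking the corresponding phosphodiester link.
#'
#' @param structure An \code{rna_structure} with complete heavy atoms.
#' @param params An \code{rna_params} parameter set.
#' @return A new \code{rna_structure} including hydrogens.
#' @export
add_hydrogens <- function(structure, params) {
  a <- structure$atoms
  rt <- residue_table(structure)
  nxt <- residue_link_map(structure)
  pieces <- list()
  for (r in seq_len(nrow(rt))) {
    tpl <- residue_template(rt$resname[r], params)
    rows <- which(a$res == r)
    block <- a[rows, , drop = FALSE]
    first_of_chain <- r == 1L || rt$chain[r] != rt$chain[r - 1L]
    has_p <- "P" %in% block$name
    wanted <- tpl$atoms$name[tpl$atoms$element == "H"]
    if (!(first_of_chain && !has_p)) wanted <- setdiff(wanted, "HO5'")
    if (!is.na(nxt[r])) wanted <- setdiff(wanted, "HO3'")
    missing_h <- setdiff(wanted, block$name)
    if (length(missing_h)) {
      tx <- as.matrix(tpl$atoms[, c("x", "y", "z")])
      tn <- tpl$atoms$name
      tadj <- template_adjacency(tpl)
      newrows <- list()
      for (h in missing_h) {
        hi <- match(h, tn)
        parent <- tadj[[hi]][1]
        cluster <- unique(c(parent, setdiff(tadj[[parent]], hi)))
        cl_heavy <- cluster[tpl$atoms$element[cluster] != "H"]
        # grow the local cluster until >= 3 heavy atoms are actually
        # present in the structure (terminal variants may lack some)
        repeat {
          here <- match(tn[cl_heavy], block$name)
          if (sum(!is.na(here)) >= 3L) break
          more <- unique(unlist(lapply(cl_heavy, function(i) tadj[[i]])))
          more <- more[tpl$atoms$element[more] != "H"]
          grown <- unique(c(cl_heavy, more))
          if (length(grown) == length(cl_heavy))
            stop("cannot place ", h, " in chain ", rt$chain[r],
                 " residue ", rt$resnum[r],
                 ": local heavy atoms incomplete", call. = FALSE)
          cl_heavy <- grown
        }
        here <- match(tn[cl_heavy], block$name)
        ok <- !is.na(here)
        fit <- kabsch_fit(tx[cl_heavy[ok], , drop = FALSE],
                          as.matrix(block[here[ok], c("x", "y", "z")]))
        pos <- drop(tx[hi, ] %*% fit$R) + fit$t
        newrows[[length(newrows) + 1L]] <-
          data.frame(serial = NA_integer_, name = h,
                     resname = block$resname[1], chain = block$chain[1],
                     resnum = block$resnum[1], icode = block$icode[1],
                     x = pos[1], y = pos[2], z = pos[3], element = "H",
                     record = block$record[1], res = r,
                     stringsAsFactors = FALSE)
      }
      block <- rbind(block, do.call(rbind, newrows))
    }
    pieces[[r]] <- block
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  out$res <- NULL
  new_structure(out, skipped = structure$skipped,
                dropped_solvent = structure$dropped_solvent)
}

template_adjacency <- function(tpl) {
  nx <- nrow(tpl$atoms)
  adj <- vector("list", nx)
  for (b in seq_len(nrow(tpl$bonds))) {
    i <- match(tpl$bonds[b, 1], tpl$atoms$name)
    j <- match(tpl$bonds[b, 2], tpl$atoms$name)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}
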