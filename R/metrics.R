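# Structure-comparison and quality metrics: superposed RMSD (Kabsch),
# Interaction Network Fidelity over residue-residue contacts, and a
# simple internal clash score (van der Waals overlap >= 0.4 A between
# non-bonded atoms, per 1000 atoms). The clash score is a lightweight
# proxy for external validation tools, not a reimplementation of them.

#' Superposed RMSD of two matched coordinate sets
#'
#' RMSD after optimal rigid superposition (proper rotation only; no
#' reflection), computed with the Kabsch algorithm.
#'
#' @param coordsA,coordsB n x 3 matrices (or \code{rna_structure}
#'   objects), matched row order, n >= 3.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coordsA, coordsB) {
  if (inherits(coordsA, "rna_structure")) coordsA <- get_coords(coordsA)
  if (inherits(coordsB, "rna_structure")) coordsB <- get_coords(coordsB)
  if (nrow(coordsA) != nrow(coordsB))
    stop("coordinate sets differ in atom count (", nrow(coordsA), " vs ",
         nrow(coordsB), ")", call. = FALSE)
  if (nrow(coordsA) < 3L)
    stop("need at least 3 atoms for superposition", call. = FALSE)
  kabsch_fit(coordsB, coordsA)$rmsd
}

#' Residue-residue contact set of a structure
#'
#' Watson-Crick pairs from the geometric detector (class "WC") plus all
#' other residue pairs, excluding chain neighbours, with any heavy-atom
#' contact within \code{cutoff} (class "other").
#'
#' @param structure Protonated \code{rna_structure}.
#' @param params Parameter set.
#' @param cutoff Heavy-atom contact distance, Angstrom.
#' @return Data frame with columns \code{i}, \code{j}, \code{class}.
#' @export
contact_set <- function(structure, params, cutoff = 4.0) {
  wc <- detect_base_pairs(structure, params)
  a <- structure$atoms
  X <- get_coords(structure)
  heavy <- a$element != "H"
  res <- a$res[heavy]
  Xh <- X[heavy, , drop = FALSE]
  nres <- max(a$res)
  rt <- residue_table(structure)
  pairs <- list()
  for (ri in seq_len(nres - 1L)) {
    ii <- which(res == ri)
    for (rj in (ri + 1L):nres) {
      if (rj == ri + 1L && rt$chain[ri] == rt$chain[rj]) next
      jj <- which(res == rj)
      d2 <- outer(rowSums(Xh[ii, , drop = FALSE]^2),
                  rowSums(Xh[jj, , drop = FALSE]^2), `+`) -
        2 * Xh[ii, , drop = FALSE] %*% t(Xh[jj, , drop = FALSE])
      if (min(d2) <= cutoff^2)
        pairs[[length(pairs) + 1L]] <- c(ri, rj)
    }
  }
  other <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(), 0, 2)
  df <- data.frame(i = c(wc$i, other[, 1]), j = c(wc$j, other[, 2]),
                   class = c(rep("WC", nrow(wc)),
                             rep("other", nrow(other))))
  df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
}

#' Interaction Network Fidelity between two contact sets
#'
#' \code{INF = sqrt(PPV * TPR)} over residue-residue contacts; the
#' comparison can be restricted to Watson-Crick ("wc") or
#' non-Watson-Crick ("nwc") contacts.
#'
#' @param reference,model Contact data frames (\code{i}, \code{j},
#'   optional \code{class}).
#' @param class "all", "wc" or "nwc".
#' @return INF in [0, 1].
#' @export
inf_score <- function(reference, model, class = c("all", "wc", "nwc")) {
  class <- match.arg(class)
  filt <- function(df) {
    if (class == "wc" && "class" %in% names(df))
      df <- df[df$class == "WC", , drop = FALSE]
    if (class == "nwc" && "class" %in% names(df))
      df <- df[df$class != "WC", , drop = FALSE]
    unique(paste(pmin(df$i, df$j), pmax(df$i, df$j)))
  }
  ref <- filt(reference)
  mod <- filt(model)
  if (!length(ref))
    stop("INF is undefined for an empty reference contact set",
         call. = FALSE)
  tp <- length(intersect(ref, mod))
  if (!length(mod)) return(0)
  ppv <- tp / length(mod)
  tpr <- tp / length(ref)
  sqrt(ppv * tpr)
}

#' Internal clash score
#'
#' Counts non-bonded atom pairs (1-2, 1-3 and 1-4 neighbours excluded)
#' whose van der Waals overlap is at least \code{overlap} Angstrom,
#' reported per 1000 atoms. Contact radii for heavy atoms are derived
#' from the Lennard-Jones zero-crossing (sigma/2, which coincides with
#' standard van der Waals radii); carbon-bound hydrogens use the
#' conventional contact radii (1.1 A aliphatic, 1.0 A aromatic) while
#' polar hydrogens keep their (tiny) LJ-derived radius. Hydrogen-bond
#' pairs are exempt (polar hydrogen vs N/O, and donor-heavy vs acceptor
#' N/O): hydrogen bonds are not steric clashes.
#'
#' @param structure Protonated \code{rna_structure}.
#' @param params Parameter set.
#' @param topology Optional precomputed \code{rna_topology}.
#' @param overlap Overlap threshold, Angstrom (0.4 by convention).
#' @return Clashes per 1000 atoms.
#' @export
clash_score <- function(structure, params, topology = NULL,
                        overlap = 0.4) {
  if (is.null(topology)) topology <- build_topology(structure, params)
  X <- get_coords(structure)
  sel <- topology$pair_class == 0L   # exclude 1-2/1-3/1-4
  i <- topology$pair_i[sel]; j <- topology$pair_j[sel]
  d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  # heavy atoms: LJ zero-crossing radius (numerically the standard vdW
  # radii); carbon-bound hydrogens: conventional contact radii; polar
  # (N/O-bound) hydrogens keep their LJ-derived radius, which is tiny in
  # AMBER-family sets -- their contacts are governed by hydrogen bonding,
  # not a vdW core, so the proxy only counts contacts the energy model
  # itself can resolve
  rad <- topology$sigma / 2
  rad[topology$types %in% c("HC", "H1", "H2")] <- 1.1
  rad[topology$types %in% c("HA", "H4", "H5")] <- 1.0
  polar_h <- topology$types %in% c("H", "HO")
  acceptor <- topology$elements %in% c("N", "O")
  # N/O atoms carrying a polar hydrogen are donors; donor..acceptor
  # heavy-atom pairs sit at hydrogen-bond distance by design
  donor <- logical(topology$n)
  b <- topology$bonds
  hb_bonds <- polar_h[b[, 1]] | polar_h[b[, 2]]
  donor[b[hb_bonds, 1]] <- TRUE
  donor[b[hb_bonds, 2]] <- TRUE
  donor <- donor & acceptor
  hbond_like <- (polar_h[i] & acceptor[j]) | (polar_h[j] & acceptor[i]) |
    (donor[i] & acceptor[j]) | (donor[j] & acceptor[i])
  nclash <- sum(!hbond_like & (rad[i] + rad[j] - r >= overlap))
  1000 * nclash / topology$n
}
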