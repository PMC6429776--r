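# Restraint construction: Watson-Crick base-pair detection (or imposition
# from user secondary structure), explicit hydrogen-bond triples,
# co-planarity groups, backbone conformer targets and custom spring
# restraints. The whole restraint set is frozen at startup; nothing is
# re-detected during minimization.

#' Parse a Vienna dot-bracket string into base pairs
#'
#' Matched brackets become pairs; the bracket tiers \code{()}, \code{[]},
#' \code{{}} and \code{<>} are matched independently, so pseudoknots can
#' be expressed. The string length must equal the residue count of the
#' (single) chain.
#'
#' @param dotbracket Secondary-structure string over \code{".()[]{}<>"}.
#' @param structure An \code{rna_structure} with exactly one chain.
#' @return Data frame with columns \code{i}, \code{j}: paired residue
#'   indices (1-based, \code{i < j}).
#' @export
parse_vienna <- function(dotbracket, structure) {
  rt <- residue_table(structure)
  if (length(unique(rt$chain)) > 1L)
    stop("Vienna input is defined for a single chain; this structure has ",
         length(unique(rt$chain)),
         " chains - provide a contact list instead", call. = FALSE)
  s <- strsplit(dotbracket, "")[[1]]
  if (length(s) != nrow(rt))
    stop("secondary structure length (", length(s),
         ") does not match residue count (", nrow(rt), ")", call. = FALSE)
  tiers <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  allowed <- c(".", unlist(tiers))
  bad <- which(!s %in% allowed)
  if (length(bad))
    stop("invalid secondary-structure character '", s[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  pairs <- list()
  for (tier in tiers) {
    stack <- integer()
    for (pos in seq_along(s)) {
      if (s[pos] == tier[1]) stack <- c(stack, pos)
      else if (s[pos] == tier[2]) {
        if (!length(stack))
          stop("unbalanced brackets: unmatched '", tier[2],
               "' at position ", pos, call. = FALSE)
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], pos)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced brackets: unmatched '", tier[1], "' at position ",
           stack[1], call. = FALSE)
  }
  normalize_pairs(pairs)
}

#' Parse a residue contact list into base pairs
#'
#' One pair per line, either chain-qualified (\code{A:5 B:12}) or plain
#' residue numbers for single-chain structures (\code{5 12}).
#'
#' @param text Contact-list text (string, lines, or file path).
#' @param structure An \code{rna_structure}.
#' @return Data frame with residue-index columns \code{i}, \code{j}.
#' @export
parse_contacts <- function(text, structure) {
  lines <- read_text_lines(text)
  rt <- residue_table(structure)
  one_chain <- length(unique(rt$chain)) == 1L
  pairs <- list()
  for (li in seq_along(lines)) {
    line <- sub("#.*$", "", lines[li])
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(f) || identical(f, "")) next
    if (length(f) != 2L)
      stop("contact list line ", li, ": expected two residue references",
           call. = FALSE)
    res <- vapply(f, function(tok) {
      if (grepl(":", tok, fixed = TRUE)) {
        cr <- strsplit(tok, ":", fixed = TRUE)[[1]]
        hit <- which(rt$chain == cr[1] & rt$resnum == as.integer(cr[2]))
      } else {
        if (!one_chain)
          stop("contact list line ", li,
               ": chain-qualified references (A:5) required for ",
               "multi-chain structures", call. = FALSE)
        hit <- which(rt$resnum == as.integer(tok))
      }
      if (length(hit) != 1L)
        stop("contact list line ", li, ": cannot resolve residue '", tok,
             "'", call. = FALSE)
      hit
    }, 0L)
    pairs[[length(pairs) + 1L]] <- res
  }
  normalize_pairs(pairs)
}

normalize_pairs <- function(pairs) {
  if (!length(pairs))
    return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, pairs)
  df <- data.frame(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]))
  df <- df[order(df$i), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(c(df$i, df$j)))
    stop("a residue appears in more than one pair", call. = FALSE)
  if (any(df$i == df$j))
    stop("a residue cannot pair with itself", call. = FALSE)
  df
}

read_text_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) readLines(text, warn = FALSE)
  else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
  else text
}

# WC hydrogen-bond triples for an ordered residue pair, or NULL when the
# two classes cannot form a canonical pair
pair_hb_rules <- function(ci, cj, params) {
  hb <- params$addons$pairhb
  hit <- hb[(hb$class1 == ci & hb$class2 == cj) |
            (hb$class1 == cj & hb$class2 == ci), , drop = FALSE]
  if (nrow(hit) == 0L) NULL else hit
}

pair_hb_geometry <- function(ri, rj, structure, params) {
  rt <- residue_table(structure)
  ci <- residue_template(rt$resname[ri], params)$class
  cj <- residue_template(rt$resname[rj], params)$class
  rules <- pair_hb_rules(ci, cj, params)
  if (is.null(rules)) return(NULL)
  a <- structure$atoms
  at <- params$atom_types
  rows <- list()
  for (k in seq_len(nrow(rules))) {
    dres <- if (rules$donor_class[k] == ci) ri else rj
    ares <- if (rules$acceptor_class[k] == ci) ri else rj
    d <- which(a$res == dres & a$name == rules$donor[k])
    h <- which(a$res == dres & a$name == rules$hydrogen[k])
    ac <- which(a$res == ares & a$name == rules$acceptor[k])
    if (length(d) != 1L || length(h) != 1L || length(ac) != 1L)
      return(NULL)  # atoms (e.g. hydrogens) missing: no geometry
    key <- paste(a$element[d], a$element[ac])
    ideal <- params$addons$hbideal[[key]]
    if (is.null(ideal))
      stop("no ideal hydrogen-bond length for donor/acceptor elements ",
           key, call. = FALSE)
    rows[[k]] <- data.frame(d = d, h = h, a = ac, ideal = ideal)
  }
  do.call(rbind, rows)
}

#' Detect Watson-Crick base pairs from geometry
#'
#' For every candidate canonical pairing (A-U, G-C and their deoxy
#' analogues) the summed explicit hydrogen-bond energy over the pair's
#' Watson-Crick-edge donor/hydrogen/acceptor triples is evaluated; the
#' pair is accepted when that energy is below the acceptance threshold
#' (default -2 kcal/mol). Each residue joins at most one pair (best energy
#' wins). Detection is geometric and runs once at startup; when user
#' secondary structure is supplied the detector is not called at all.
#'
#' @param structure An \code{rna_structure} with hydrogens present.
#' @param params Parameter set.
#' @return Data frame with columns \code{i}, \code{j} (residue indices),
#'   \code{energy} (kcal/mol) and \code{class} ("WC").
#' @export
detect_base_pairs <- function(structure, params) {
  rt <- residue_table(structure)
  a <- structure$atoms
  X <- get_coords(structure)
  classes <- vapply(rt$resname, function(rn)
    residue_template(rn, params)$class, "")
  c1p <- vapply(seq_len(nrow(rt)), function(r) {
    hit <- which(a$res == r & a$name == "C1'")
    if (length(hit) == 1L) hit else NA_integer_
  }, 0L)
  thr <- params$addons$pair_energy_threshold
  cand <- list()
  for (ri in seq_len(nrow(rt) - 1L)) {
    for (rj in (ri + 1L):nrow(rt)) {
      if (is.na(c1p[ri]) || is.na(c1p[rj])) next
      if (sqrt(sum((X[c1p[ri], ] - X[c1p[rj], ])^2)) > 12.5) next
      if (is.null(pair_hb_rules(classes[ri], classes[rj], params))) next
      hb <- pair_hb_geometry(ri, rj, structure, params)
      if (is.null(hb)) next
      e <- hbond_energy(hb, X, params$addons)$energy
      if (e < thr)
        cand[[length(cand) + 1L]] <- data.frame(i = ri, j = rj, energy = e)
    }
  }
  if (!length(cand))
    return(data.frame(i = integer(), j = integer(), energy = numeric(),
                      class = character()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$energy), , drop = FALSE]
  used <- logical(nrow(rt))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[c(cand$i[k], cand$j[k])] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$i), , drop = FALSE]
  out$class <- "WC"
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond restraint triples for a list of base pairs
#'
#' G-C pairs contribute three donor/hydrogen/acceptor triples, A-U and A-T
#' two, following the Watson-Crick edge annotations of the templates.
#'
#' @param pairs Data frame with residue-index columns \code{i}, \code{j}.
#' @param structure An \code{rna_structure} with hydrogens.
#' @param params Parameter set.
#' @return Data frame of triples (\code{d}, \code{h}, \code{a} atom
#'   indices and \code{ideal} lengths).
#' @export
assign_hbond_restraints <- function(pairs, structure, params) {
  if (NROW(pairs) == 0L)
    return(data.frame(d = integer(), h = integer(), a = integer(),
                      ideal = numeric()))
  rt <- residue_table(structure)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    ri <- pairs$i[k]; rj <- pairs$j[k]
    ci <- residue_template(rt$resname[ri], params)
    cj <- residue_template(rt$resname[rj], params)
    if (!length(ci$wc_edge) || !length(cj$wc_edge))
      stop("residue ", rt$resname[ri], " or ", rt$resname[rj],
           " lacks a Watson-Crick edge annotation", call. = FALSE)
    hb <- pair_hb_geometry(ri, rj, structure, params)
    if (is.null(hb))
      stop("cannot build hydrogen-bond restraints for pair ", rt$chain[ri],
           ":", rt$resnum[ri], " - ", rt$chain[rj], ":", rt$resnum[rj],
           " (not a canonical pairing or atoms missing)", call. = FALSE)
    out[[k]] <- hb
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Co-planarity groups for a list of base pairs
#'
#' One group per pair, containing the heavy base-moiety atoms of both
#' residues.
#'
#' @param pairs Data frame with residue-index columns \code{i}, \code{j}.
#' @param structure An \code{rna_structure}.
#' @return List of integer vectors (atom indices).
#' @export
assign_planarity_groups <- function(pairs, structure) {
  a <- structure$atoms
  base_atoms <- function(r) {
    which(a$res == r & a$element != "H" &
          !(a$name %in% c(.backbone_names, .sugar_names)))
  }
  lapply(seq_len(NROW(pairs)), function(k)
    c(base_atoms(pairs$i[k]), base_atoms(pairs$j[k])))
}

# ---- backbone conformer library --------------------------------------------

.bb_window <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'", "P+")

#' Load the packaged backbone conformer library
#'
#' The packaged library is synthetic: the helical backbone window of an
#' ideal A-form duplex plus a versioned set of perturbed variants. Each
#' fragment spans one suite-like unit: the eight backbone atoms of a
#' residue plus the next residue's phosphorus.
#'
#' @param file Library file; defaults to the packaged one.
#' @return An object of class \code{conformer_library}: list with
#'   \code{schema} (atom names) and \code{fragments} (named list of m x 3
#'   matrices).
#' @export
build_builtin_library <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "conformers", "backbone_library.txt",
                        package = "rnarefine", mustWork = TRUE)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  schema <- NULL; frags <- list(); cur <- NULL; curname <- NULL
  flush <- function() {
    if (!is.null(curname))
      frags[[curname]] <<- do.call(rbind, cur)
  }
  for (line in lines) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (f[1] == "schema") schema <- f[-1]
    else if (f[1] == "fragment") {
      flush()
      curname <- f[2]; cur <- list()
    } else cur[[length(cur) + 1L]] <- as.numeric(f)
  }
  flush()
  if (is.null(schema) || !length(frags))
    stop("malformed conformer library: ", file, call. = FALSE)
  for (nm in names(frags))
    if (nrow(frags[[nm]]) != length(schema))
      stop("conformer library fragment ", nm,
           " does not match the schema", call. = FALSE)
  structure(list(schema = schema, fragments = frags),
            class = "conformer_library")
}

#' Build a conformer library from coordinate structures
#'
#' The documented builder behind the packaged library: extracts every
#' complete backbone window from the given structures. Users can mine
#' their own (e.g. high-resolution) coordinate files and pass the result
#' anywhere a library is accepted.
#'
#' @param structures List of \code{rna_structure} objects.
#' @param labels Optional fragment label prefix per structure.
#' @return A \code{conformer_library}.
#' @export
build_conformer_library <- function(structures,
                                    labels = paste0("s", seq_along(structures))) {
  frags <- list()
  for (si in seq_along(structures)) {
    s <- structures[[si]]
    w <- backbone_windows(s)
    for (k in seq_along(w))
      frags[[paste0(labels[si], "_", k)]] <- w[[k]]$coords
  }
  if (!length(frags)) stop("no complete backbone windows found",
                           call. = FALSE)
  structure(list(schema = .bb_window, fragments = frags),
            class = "conformer_library")
}

backbone_windows <- function(structure) {
  a <- structure$atoms
  X <- get_coords(structure)
  nxt <- residue_link_map(structure)
  out <- list()
  for (r in which(!is.na(nxt))) {
    names8 <- .bb_window[1:8]
    idx <- vapply(names8, function(nm) {
      hit <- which(a$res == r & a$name == nm)
      if (length(hit) == 1L) hit else NA_integer_
    }, 0L)
    pn <- which(a$res == nxt[r] & a$name == "P")
    idx <- c(idx, if (length(pn) == 1L) pn else NA_integer_)
    if (anyNA(idx)) next
    out[[length(out) + 1L]] <- list(res = r, idx = unname(idx),
                                    coords = X[idx, , drop = FALSE])
  }
  out
}

#' Select the closest reference conformer for a backbone fragment
#'
#' Returns the library entry minimizing the superposed RMSD to the
#' fragment; ties are broken by the lowest library index.
#'
#' @param frag m x 3 fragment coordinates matching the library schema.
#' @param library A \code{conformer_library}.
#' @return List with \code{name}, \code{index}, \code{ref} (reference
#'   coordinates) and \code{rmsd}.
#' @export
select_reference_conformer <- function(frag, library) {
  if (nrow(frag) != length(library$schema))
    stop("fragment does not match the library schema (", nrow(frag),
         " atoms vs ", length(library$schema), ")", call. = FALSE)
  best <- NULL
  for (k in seq_along(library$fragments)) {
    rmsd <- kabsch_fit(library$fragments[[k]], frag)$rmsd
    if (is.null(best) || rmsd < best$rmsd - 1e-12)
      best <- list(name = names(library$fragments)[k], index = k,
                   ref = library$fragments[[k]], rmsd = rmsd)
  }
  best
}

backbone_targets <- function(structure, library) {
  w <- backbone_windows(structure)
  lapply(w, function(win) {
    sel <- select_reference_conformer(win$coords, library)
    list(idx = win$idx, ref = sel$ref, conformer = sel$name,
         rmsd = sel$rmsd)
  })
}

# ---- custom spring restraints ----------------------------------------------

#' Parse a custom restraint file
#'
#' Line formats: \code{DIST chain resnum atom chain resnum atom rest k}
#' for distance springs and \code{POSN chain resnum atom x y z k} for
#' positional springs; \code{#} starts a comment.
#'
#' @param text Restraint text (string, lines, or file path).
#' @param structure An \code{rna_structure} used to resolve atoms.
#' @return Data frame of springs (see \code{\link{spring_energy}}).
#' @export
parse_restraint_file <- function(text, structure) {
  lines <- read_text_lines(text)
  out <- list()
  for (li in seq_along(lines)) {
    line <- sub("#.*$", "", lines[li])
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(f) || identical(f, "")) next
    resolve <- function(chain, resnum, name) {
      hit <- atom_index(structure, chain, as.integer(resnum), name)
      if (length(hit) != 1L)
        stop("restraint line ", li, ": cannot resolve atom ", chain, " ",
             resnum, " ", name, call. = FALSE)
      hit
    }
    if (f[1] == "DIST") {
      if (length(f) != 9L)
        stop("restraint line ", li, ": DIST needs 8 fields", call. = FALSE)
      k <- as.numeric(f[9])
      if (is.na(k) || k < 0)
        stop("restraint line ", li, ": negative or invalid force constant",
             call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        type = "dist", i = resolve(f[2], f[3], f[4]),
        j = resolve(f[5], f[6], f[7]), px = NA_real_, py = NA_real_,
        pz = NA_real_, rest = as.numeric(f[8]), k = k)
    } else if (f[1] == "POSN") {
      if (length(f) != 8L)
        stop("restraint line ", li, ": POSN needs 7 fields", call. = FALSE)
      k <- as.numeric(f[8])
      if (is.na(k) || k < 0)
        stop("restraint line ", li, ": negative or invalid force constant",
             call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        type = "posn", i = resolve(f[2], f[3], f[4]), j = NA_integer_,
        px = as.numeric(f[5]), py = as.numeric(f[6]),
        pz = as.numeric(f[7]), rest = 0, k = k)
    } else stop("restraint line ", li, ": unknown record '", f[1], "'",
                call. = FALSE)
  }
  if (!length(out))
    return(data.frame(type = character(), i = integer(), j = integer(),
                      px = numeric(), py = numeric(), pz = numeric(),
                      rest = numeric(), k = numeric()))
  res <- do.call(rbind, out)
  if (any(res$rest < 0)) stop("negative rest length", call. = FALSE)
  res
}

#' Build the complete restraint set for a structure
#'
#' Base pairs come from the geometric detector unless user secondary
#' structure (Vienna string or contact list) is given, in which case the
#' user list is used verbatim and automatic detection is disabled. The
#' restraint set is frozen at startup.
#'
#' @param structure Protonated \code{rna_structure}.
#' @param params Parameter set.
#' @param config Configuration list (term toggles decide which components
#'   are built).
#' @param ss Optional Vienna dot-bracket string.
#' @param contacts Optional contact-list text.
#' @param restraint_text Optional custom-restraint file text.
#' @param library Optional \code{conformer_library} (defaults to the
#'   packaged one).
#' @return An object of class \code{rna_restraints}.
#' @export
build_restraints <- function(structure, params,
                             config = default_config(), ss = NULL,
                             contacts = NULL, restraint_text = NULL,
                             library = NULL) {
  want_pairs <- cfg_on(config, "hbonds") || cfg_on(config, "planarity")
  if (!is.null(ss) && !is.null(contacts))
    stop("give either a Vienna string or a contact list, not both",
         call. = FALSE)
  if (!is.null(ss)) {
    pairs <- parse_vienna(ss, structure)
    pairs$class <- rep("WC", nrow(pairs))
    source <- "user"
  } else if (!is.null(contacts)) {
    pairs <- parse_contacts(contacts, structure)
    pairs$class <- rep("WC", nrow(pairs))
    source <- "user"
  } else if (want_pairs) {
    pairs <- detect_base_pairs(structure, params)
    source <- "auto"
  } else {
    pairs <- data.frame(i = integer(), j = integer())
    source <- "none"
  }
  hb <- if (cfg_on(config, "hbonds") && NROW(pairs) > 0)
    assign_hbond_restraints(pairs, structure, params)
  else data.frame(d = integer(), h = integer(), a = integer(),
                  ideal = numeric())
  pg <- if (cfg_on(config, "planarity") && NROW(pairs) > 0)
    assign_planarity_groups(pairs, structure)
  else list()
  bb <- if (cfg_on(config, "backbone_regularization")) {
    if (is.null(library)) library <- build_builtin_library()
    backbone_targets(structure, library)
  } else list()
  sp <- if (cfg_on(config, "springs") && !is.null(restraint_text))
    parse_restraint_file(restraint_text, structure)
  else data.frame(type = character(), i = integer(), j = integer(),
                  px = numeric(), py = numeric(), pz = numeric(),
                  rest = numeric(), k = numeric())
  out <- list(pairs = pairs, hbonds = hb, planarity = pg,
              backbone = bb, springs = sp, source = source)
  class(out) <- "rna_restraints"
  out
}

#' @export
print.rna_restraints <- function(x, ...) {
  cat("Restraint set (", x$source, " base pairs):\n", sep = "")
  cat("  base pairs: ", NROW(x$pairs), "\n", sep = "")
  cat("  hydrogen-bond triples: ", NROW(x$hbonds), "\n", sep = "")
  cat("  planarity groups: ", length(x$planarity), "\n", sep = "")
  cat("  backbone targets: ", length(x$backbone), "\n", sep = "")
  cat("  custom springs: ", NROW(x$springs), "\n", sep = "")
  invisible(x)
}
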