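# Force-field parameter set: atom types, bonded parameters, residue
# templates and the add-on restraint constants. All values live in plain
# text files under extdata/params so that users can extend the template set
# (e.g. add modified residues) without touching code.

param_dir <- function() {
  system.file("extdata", "params", package = "rnarefine", mustWork = TRUE)
}

stop_load <- function(file, line, msg) {
  stop(sprintf("parameter load error in %s, line %d: %s",
               basename(file), line, msg), call. = FALSE)
}

read_param_lines <- function(file) {
  raw <- readLines(file, warn = FALSE)
  list(raw = raw, keep = which(!grepl("^\\s*(#|$)", raw)))
}

#' Load the packaged force-field parameter set
#'
#' Reads the packaged AMBER-family parameter files: Lennard-Jones atom types
#' (with generalized-Born radii and screening factors), bond / angle /
#' torsion parameters, residue templates for the canonical ribo- and
#' deoxyribonucleotides plus demonstration modified residues (5MU, DU), and
#' the constants of the four add-on energy terms. The set carries the
#' method's tuned rest angles (OP1-P-OP2 119.62 degrees, N9-C1'-O4' 109.00
#' degrees), the explicit hydrogen-bond multiplier k1 = -1 kcal/mol and the
#' base-pair acceptance threshold of -2 kcal/mol.
#'
#' @param dir Directory holding the parameter files; defaults to the
#'   packaged set.
#' @return An object of class \code{rna_params}: a list with elements
#'   \code{atom_types}, \code{bonds}, \code{angles}, \code{torsions},
#'   \code{templates}, \code{addons} and \code{aliases}.
#' @examples
#' p <- load_default_params()
#' p$addons$k1                       # -1 kcal/mol
#' residue_angle_rest(p, "A", c("OP1", "P", "OP2"))
#' @export
load_default_params <- function(dir = param_dir()) {
  at <- parse_atom_types(file.path(dir, "atom_types.tsv"))
  bonded <- parse_bonded(file.path(dir, "bonded.tsv"))
  tdir <- file.path(dir, "templates")
  tfiles <- sort(list.files(tdir, pattern = "\\.tpl$", full.names = TRUE))
  if (length(tfiles) == 0L)
    stop("no residue templates found in ", tdir, call. = FALSE)
  templates <- lapply(tfiles, parse_template)
  names(templates) <- vapply(templates, `[[`, "", "name")
  addons <- parse_addons(file.path(dir, "addons.conf"))
  aliases <- build_alias_table(templates)
  p <- list(atom_types = at, bonds = bonded$bonds, angles = bonded$angles,
            torsions = bonded$torsions, templates = templates,
            addons = addons, aliases = aliases, dir = dir)
  class(p) <- "rna_params"
  validate_params(p)
  p
}

parse_atom_types <- function(file) {
  ln <- read_param_lines(file)
  rows <- lapply(ln$keep, function(i) {
    f <- strsplit(ln$raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 7L)
      stop_load(file, i, "expected 7 tab-separated fields")
    f
  })
  m <- do.call(rbind, rows)
  at <- data.frame(type = m[, 1], sigma = as.numeric(m[, 2]),
                   epsilon = as.numeric(m[, 3]), charge = as.numeric(m[, 4]),
                   element = m[, 5], gb_radius = as.numeric(m[, 6]),
                   gb_screen = as.numeric(m[, 7]),
                   stringsAsFactors = FALSE)
  if (anyNA(at$sigma) || any(at$sigma <= 0))
    stop_load(file, 0L, "non-positive or missing sigma")
  if (any(at$epsilon < 0)) stop_load(file, 0L, "negative epsilon")
  at
}

parse_bonded <- function(file) {
  ln <- read_param_lines(file)
  bonds <- list(); angles <- list(); torsions <- list()
  for (i in ln$keep) {
    f <- strsplit(trimws(ln$raw[i]), "\\s+")[[1]]
    kind <- f[1]
    if (kind == "BOND") {
      if (length(f) != 5L) stop_load(file, i, "BOND needs 4 fields")
      bonds[[length(bonds) + 1L]] <-
        data.frame(t1 = f[2], t2 = f[3], k = as.numeric(f[4]),
                   r0 = as.numeric(f[5]), stringsAsFactors = FALSE)
    } else if (kind == "ANGLE") {
      if (length(f) != 6L) stop_load(file, i, "ANGLE needs 5 fields")
      angles[[length(angles) + 1L]] <-
        data.frame(t1 = f[2], tc = f[3], t2 = f[4], k = as.numeric(f[5]),
                   theta0 = as.numeric(f[6]), stringsAsFactors = FALSE)
    } else if (kind == "TORSION") {
      if (length(f) != 8L) stop_load(file, i, "TORSION needs 7 fields")
      torsions[[length(torsions) + 1L]] <-
        data.frame(t1 = f[2], t2 = f[3], t3 = f[4], t4 = f[5],
                   k = as.numeric(f[6]), n = as.integer(f[7]),
                   gamma = as.numeric(f[8]), stringsAsFactors = FALSE)
    } else stop_load(file, i, paste("unknown record", kind))
  }
  b <- do.call(rbind, bonds); a <- do.call(rbind, angles)
  t <- do.call(rbind, torsions)
  if (any(b$k < 0) || any(a$k < 0))
    stop_load(file, 0L, "negative force constant")
  if (any(a$theta0 <= 0 | a$theta0 >= 180))
    stop_load(file, 0L, "rest angle outside (0, 180)")
  list(bonds = b, angles = a, torsions = t)
}

parse_template <- function(file) {
  ln <- read_param_lines(file)
  tpl <- list(name = NULL, aliases = character(), class = NULL,
              kind = NULL, formal_charge = NA_real_)
  atoms <- list(); bonds <- list(); donors <- list()
  acceptors <- character(); wc_edge <- character()
  section <- "header"
  for (i in ln$keep) {
    f <- strsplit(trimws(ln$raw[i]), "\\s+")[[1]]
    if (f[1] %in% c("atoms", "bonds", "donors", "acceptors", "wc_edge",
                    "end")) {
      section <- f[1]
      next
    }
    if (section == "header") {
      key <- f[1]
      if (key == "residue") tpl$name <- f[2]
      else if (key == "aliases") tpl$aliases <- f[-1]
      else if (key == "class") tpl$class <- f[2]
      else if (key == "kind") tpl$kind <- f[2]
      else if (key == "formal_charge") tpl$formal_charge <- as.numeric(f[2])
      else stop_load(file, i, paste("unknown header key", key))
    } else if (section == "atoms") {
      if (length(f) != 8L) stop_load(file, i, "atom row needs 8 fields")
      atoms[[length(atoms) + 1L]] <-
        data.frame(name = f[1], type = f[2], element = f[3],
                   charge = as.numeric(f[4]), x = as.numeric(f[5]),
                   y = as.numeric(f[6]), z = as.numeric(f[7]),
                   ter = f[8], stringsAsFactors = FALSE)
    } else if (section == "bonds") {
      if (length(f) != 2L) stop_load(file, i, "bond row needs 2 fields")
      bonds[[length(bonds) + 1L]] <- f
    } else if (section == "donors") {
      if (length(f) != 2L) stop_load(file, i, "donor row needs 2 fields")
      donors[[length(donors) + 1L]] <- f
    } else if (section == "acceptors") {
      acceptors <- c(acceptors, f[1])
    } else if (section == "wc_edge") {
      wc_edge <- c(wc_edge, f[1])
    }
  }
  tpl$atoms <- do.call(rbind, atoms)
  tpl$bonds <- do.call(rbind, bonds)
  tpl$donors <- if (length(donors)) do.call(rbind, donors) else
    matrix(character(), 0, 2)
  tpl$acceptors <- acceptors
  tpl$wc_edge <- wc_edge
  if (is.null(tpl$name)) stop_load(file, 0L, "missing residue name")
  if (anyDuplicated(tpl$atoms$name))
    stop_load(file, 0L, "duplicate atom name")
  bad <- setdiff(c(tpl$bonds), tpl$atoms$name)
  if (length(bad))
    stop_load(file, 0L, paste("bond references unknown atom:",
                              paste(bad, collapse = ", ")))
  tpl
}

parse_addons <- function(file) {
  ln <- read_param_lines(file)
  ad <- list(hbideal = list(), pairhb = list(), pairt = list())
  for (i in ln$keep) {
    line <- trimws(ln$raw[i])
    f <- strsplit(line, "\\s+")[[1]]
    if (f[1] == "HBIDEAL") {
      ad$hbideal[[paste(f[2], f[3])]] <- as.numeric(f[4])
    } else if (f[1] == "PAIRHB") {
      ad$pairhb[[length(ad$pairhb) + 1L]] <-
        data.frame(class1 = f[2], class2 = f[3], donor_class = f[4],
                   donor = f[5], hydrogen = f[6], acceptor_class = f[7],
                   acceptor = f[8], stringsAsFactors = FALSE)
    } else if (f[1] == "PAIRT") {
      v <- as.numeric(f[4:15])
      ad$pairt[[paste(f[2], f[3])]] <-
        list(R = matrix(v[1:9], 3, 3, byrow = TRUE), t = v[10:12])
    } else if (grepl("=", line, fixed = TRUE)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      ad[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    } else stop_load(file, i, "unrecognized add-on record")
  }
  ad$pairhb <- do.call(rbind, ad$pairhb)
  for (key in c("k1", "d", "theta0", "k2", "k3", "k4",
                "pair_energy_threshold"))
    if (is.null(ad[[key]])) stop_load(file, 0L, paste("missing", key))
  if (ad$k1 >= 0) stop_load(file, 0L, "k1 must be negative (attractive)")
  if (ad$d <= 0) stop_load(file, 0L, "d must be positive")
  if (any(c(ad$k2, ad$k3, ad$k4) < 0))
    stop_load(file, 0L, "k2..k4 must be non-negative")
  if (ad$pair_energy_threshold >= 0)
    stop_load(file, 0L, "pair threshold must be negative")
  ad
}

validate_params <- function(p) {
  for (tpl in p$templates) {
    miss <- setdiff(unique(tpl$atoms$type), p$atom_types$type)
    if (length(miss))
      stop("template ", tpl$name, " uses unknown atom types: ",
           paste(miss, collapse = ", "), call. = FALSE)
    typ <- stats::setNames(tpl$atoms$type, tpl$atoms$name)
    for (r in seq_len(nrow(tpl$bonds))) {
      bp <- bond_param(p, typ[[tpl$bonds[r, 1]]], typ[[tpl$bonds[r, 2]]])
      if (is.null(bp))
        stop("template ", tpl$name, ": no bond parameter for ",
             tpl$bonds[r, 1], "-", tpl$bonds[r, 2], call. = FALSE)
    }
  }
  invisible(p)
}

# ---- lookups ---------------------------------------------------------------

bond_param <- function(params, t1, t2) {
  b <- params$bonds
  hit <- which((b$t1 == t1 & b$t2 == t2) | (b$t1 == t2 & b$t2 == t1))
  if (!length(hit)) return(NULL)
  b[hit[1], ]
}

angle_param <- function(params, t1, tc, t2) {
  a <- params$angles
  hit <- which(a$tc == tc & ((a$t1 == t1 & a$t2 == t2) |
                             (a$t1 == t2 & a$t2 == t1)))
  if (!length(hit)) return(NULL)
  a[hit[1], ]
}

torsion_param <- function(params, t1, t2, t3, t4) {
  tt <- params$torsions
  exact <- which((tt$t1 == t1 & tt$t2 == t2 & tt$t3 == t3 & tt$t4 == t4) |
                 (tt$t1 == t4 & tt$t2 == t3 & tt$t3 == t2 & tt$t4 == t1))
  if (length(exact)) return(tt[exact, , drop = FALSE])
  wild <- which(tt$t1 == "X" & tt$t4 == "X" &
                ((tt$t2 == t2 & tt$t3 == t3) | (tt$t2 == t3 & tt$t3 == t2)))
  if (length(wild)) return(tt[wild, , drop = FALSE])
  NULL
}

#' Rest value of a named angle inside a residue template
#'
#' Resolves atom names to force-field types through the residue template and
#' returns the rest angle in degrees. Useful to inspect the tuned values,
#' e.g. \code{residue_angle_rest(p, "A", c("OP1", "P", "OP2"))}.
#'
#' @param params An \code{rna_params} object.
#' @param residue Residue name (alias-aware).
#' @param atom_names Character vector of three atom names.
#' @return Rest angle in degrees.
#' @export
residue_angle_rest <- function(params, residue, atom_names) {
  stopifnot(length(atom_names) == 3L)
  tpl <- residue_template(residue, params)
  typ <- stats::setNames(tpl$atoms$type, tpl$atoms$name)
  nm <- vapply(atom_names, normalize_atom_name, "")
  ap <- angle_param(params, typ[[nm[1]]], typ[[nm[2]]], typ[[nm[3]]])
  if (is.null(ap))
    stop("no angle parameter for ", paste(nm, collapse = "-"), call. = FALSE)
  ap$theta0
}

#' Look up a residue template
#'
#' Case-insensitive and alias-aware (e.g. \code{"RA"}, \code{"ADE"} and
#' \code{"a"} all resolve to the adenosine template).
#'
#' @param name Residue name from a PDB file.
#' @param params An \code{rna_params} object.
#' @return The template: a list with the atom table, bond list, donor /
#'   acceptor annotations and the Watson-Crick edge atoms.
#' @export
residue_template <- function(name, params) {
  key <- toupper(trimws(name))
  hit <- params$aliases[[key]]
  if (is.null(hit)) {
    known <- names(params$aliases)
    dist <- utils::adist(key, known)
    near <- known[order(dist)][seq_len(min(3L, length(known)))]
    stop("unknown residue '", name, "'; nearest known names: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  params$templates[[hit]]
}

build_alias_table <- function(templates) {
  tab <- list()
  for (tpl in templates) {
    for (al in toupper(c(tpl$name, tpl$aliases))) {
      if (!is.null(tab[[al]]) && tab[[al]] != tpl$name)
        stop("residue alias clash: ", al, call. = FALSE)
      tab[[al]] <- tpl$name
    }
  }
  tab
}

# ---- serialization round trip ----------------------------------------------

#' Serialize a parameter set back to its plain-text form
#'
#' Writes files in the same format as the packaged set; reloading gives a
#' parameter set whose decimal text form is identical.
#'
#' @param params An \code{rna_params} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_params <- function(params, dir) {
  dir.create(file.path(dir, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  at <- params$atom_types
  hdr <- "# rnarefine parameter file v1"
  lines <- c(hdr,
             "# type\tsigma\tepsilon\tcharge\telement\tgb_radius\tgb_screen",
             sprintf("%s\t%.4f\t%.4f\t%.4f\t%s\t%.2f\t%.2f", at$type,
                     at$sigma, at$epsilon, at$charge, at$element,
                     at$gb_radius, at$gb_screen))
  writeLines(lines, file.path(dir, "atom_types.tsv"))
  b <- params$bonds; a <- params$angles; tt <- params$torsions
  lines <- c(hdr, "# BOND t1 t2 k[kcal/mol/A^2] r0[A]",
             sprintf("BOND %s %s %.1f %.4f", b$t1, b$t2, b$k, b$r0),
             "# ANGLE t1 tc t2 k[kcal/mol/rad^2] theta0[deg]",
             sprintf("ANGLE %s %s %s %.1f %.4f", a$t1, a$tc, a$t2, a$k,
                     a$theta0),
             "# TORSION t1 t2 t3 t4 k[kcal/mol] n gamma[deg] (X = wildcard)",
             sprintf("TORSION %s %s %s %s %.4f %d %.1f", tt$t1, tt$t2,
                     tt$t3, tt$t4, tt$k, tt$n, tt$gamma))
  writeLines(lines, file.path(dir, "bonded.tsv"))
  ad <- params$addons
  lines <- c(hdr,
             sprintf("%s = %s", c("k1", "d", "theta0", "k2", "k3", "k4",
                                  "pair_energy_threshold"),
                     vapply(c("k1", "d", "theta0", "k2", "k3", "k4",
                              "pair_energy_threshold"),
                            function(k) format(ad[[k]]), "")),
             vapply(names(ad$hbideal), function(k)
               sprintf("HBIDEAL %s %s", k, format(ad$hbideal[[k]])), ""))
  if (!is.null(ad$pairhb))
    lines <- c(lines, sprintf("PAIRHB %s %s %s %s %s %s %s",
                              ad$pairhb$class1, ad$pairhb$class2,
                              ad$pairhb$donor_class, ad$pairhb$donor,
                              ad$pairhb$hydrogen, ad$pairhb$acceptor_class,
                              ad$pairhb$acceptor))
  for (key in names(ad$pairt)) {
    v <- c(t(ad$pairt[[key]]$R), ad$pairt[[key]]$t)
    lines <- c(lines, sprintf("PAIRT %s %s", key,
                              paste(sprintf("%.6f", v), collapse = " ")))
  }
  writeLines(lines, file.path(dir, "addons.conf"))
  for (tpl in params$templates) {
    at <- tpl$atoms
    lines <- c("# rnarefine residue template v1",
               paste("residue", tpl$name))
    if (length(tpl$aliases))
      lines <- c(lines, paste("aliases", paste(tpl$aliases, collapse = " ")))
    lines <- c(lines, paste("class", tpl$class), paste("kind", tpl$kind),
               paste("formal_charge", format(tpl$formal_charge)), "atoms",
               sprintf("%s\t%s\t%s\t%.4f\t%.4f\t%.4f\t%.4f\t%s", at$name,
                       at$type, at$element, at$charge, at$x, at$y, at$z,
                       at$ter),
               "bonds", sprintf("%s\t%s", tpl$bonds[, 1], tpl$bonds[, 2]),
               "donors",
               if (nrow(tpl$donors)) sprintf("%s\t%s", tpl$donors[, 1],
                                             tpl$donors[, 2]) else character(),
               "acceptors", tpl$acceptors, "wc_edge", tpl$wc_edge, "end")
    writeLines(lines, file.path(dir, "templates",
                                paste0(tpl$name, ".tpl")))
  }
  invisible(dir)
}

#' @export
print.rna_params <- function(x, ...) {
  cat("Force-field parameter set\n")
  cat("  atom types: ", nrow(x$atom_types), "\n", sep = "")
  cat("  bond/angle/torsion entries: ", nrow(x$bonds), "/", nrow(x$angles),
      "/", nrow(x$torsions), "\n", sep = "")
  cat("  residue templates: ", paste(names(x$templates), collapse = ", "),
      "\n", sep = "")
  cat("  add-on constants: k1=", x$addons$k1, " kcal/mol, d=", x$addons$d,
      " A^2, k2=k3=k4=", x$addons$k2, " kcal/mol/A^2, pair threshold=",
      x$addons$pair_energy_threshold, " kcal/mol\n", sep = "")
  invisible(x)
}
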