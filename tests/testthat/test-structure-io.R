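# PDB reading/writing, atom-name normalization, topology construction
# and hydrogen completion.

pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     el = substr(name, 1, 1)) {
  nm <- if (nchar(el) == 1L && nchar(name) < 4L)
    sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, chain, resnum, x, y, z, el)
}

test_that("single ATOM records parse with name normalization", {
  s <- read_pdb(c(pdb_line(1, "C1'", "A", "A", 1, 1, 2, 3),
                  pdb_line(2, "O1P", "A", "A", 1, 4, 5, 6, "O")))
  expect_s3_class(s, "rna_structure")
  expect_identical(s$atoms$name, c("C1'", "OP1"))
  expect_equal(s$atoms$x, c(1, 4))
})

test_that("asterisk sugar names normalize to primes", {
  expect_identical(unname(normalize_atom_name("C1*")), "C1'")
  expect_identical(unname(normalize_atom_name("O1P")), "OP1")
  expect_identical(unname(normalize_atom_name("H5'1")), "H5'")
})

test_that("only the first MODEL block is retained", {
  txt <- c("MODEL     1",
           pdb_line(1, "C1'", "A", "A", 1, 0, 0, 0),
           "ENDMDL", "MODEL     2",
           pdb_line(1, "C1'", "A", "A", 1, 9, 9, 9),
           "ENDMDL")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 0)
})

test_that("unparsable records warn with a line number and are counted", {
  txt <- c(pdb_line(1, "C1'", "A", "A", 1, 0, 0, 0),
           "ATOM  garbage line with no columns")
  expect_warning(s <- read_pdb(txt), "line 2")
  expect_equal(s$skipped, 1L)
  expect_equal(nrow(s$atoms), 1L)
})

test_that("input with no parsable records is an error", {
  expect_error(read_pdb("REMARK nothing here"), "no ATOM/HETATM")
  expect_error(write_pdb(structure(list(atoms = DUPLEX_GC2$atoms[0, ]),
                                   class = "rna_structure")), "empty")
})

test_that("waters and ions are dropped with a count", {
  txt <- c(pdb_line(1, "C1'", "A", "A", 1, 0, 0, 0),
           pdb_line(2, "O", "HOH", "A", 99, 1, 1, 1))
  s <- read_pdb(txt)
  expect_equal(s$dropped_solvent, 1L)
  expect_equal(nrow(s$atoms), 1L)
})

test_that("write/read round trip preserves names, numbering, coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(DUPLEX_6, f)
  s2 <- read_pdb(f)
  expect_identical(s2$atoms$name, DUPLEX_6$atoms$name)
  expect_identical(s2$atoms$resnum, DUPLEX_6$atoms$resnum)
  expect_identical(s2$atoms$chain, DUPLEX_6$atoms$chain)
  expect_lt(max(abs(get_coords(s2) - get_coords(DUPLEX_6))), 1e-3 + 1e-9)
  # TER between the two chains
  txt <- write_pdb(DUPLEX_6)
  expect_equal(sum(grepl("^TER", txt)), 2L)
})

test_that("topology bond counts match the templates", {
  # single adenosine with 5'-OH (no phosphate)
  tpl <- residue_template("A", PARAMS)
  keep <- !(tpl$atoms$name %in% c("P", "OP1", "OP2"))
  atoms <- data.frame(serial = seq_len(sum(keep)),
                      name = tpl$atoms$name[keep], resname = "A",
                      chain = "A", resnum = 1L, icode = " ",
                      x = tpl$atoms$x[keep], y = tpl$atoms$y[keep],
                      z = tpl$atoms$z[keep],
                      element = tpl$atoms$element[keep], record = "ATOM",
                      stringsAsFactors = FALSE)
  s <- rnarefine:::new_structure(atoms)
  topo <- build_topology(s, PARAMS)
  # oracle: count template bonds whose atoms are present
  present <- tpl$atoms$name[keep]
  nb <- sum(tpl$bonds[, 1] %in% present & tpl$bonds[, 2] %in% present)
  expect_equal(nrow(topo$bonds), nb)
})

test_that("dinucleotide gets exactly one inter-residue bond; chains none", {
  topo <- build_topology(DUPLEX_GC2, PARAMS)
  a <- DUPLEX_GC2$atoms
  inter <- apply(topo$bonds, 1, function(b)
    a$res[b[1]] != a$res[b[2]])
  expect_equal(sum(inter), 2L)   # one junction per chain
  cross_chain <- apply(topo$bonds, 1, function(b)
    a$chain[b[1]] != a$chain[b[2]])
  expect_equal(sum(cross_chain), 0L)
})

test_that("unknown residues and missing heavy atoms are reported", {
  s <- DUPLEX_GC2
  s$atoms$resname[s$atoms$res == 1] <- "QQQ"
  expect_error(build_topology(rnarefine:::index_residues(s), PARAMS),
               "chain A residue 1")
  s2 <- DUPLEX_GC2
  s2$atoms <- s2$atoms[s2$atoms$name != "N1" | s2$atoms$res != 1, ]
  s2 <- rnarefine:::index_residues(s2)
  expect_error(build_topology(s2, PARAMS), "missing heavy atom")
})

test_that("the bond graph is invariant under atom reordering", {
  s <- DUPLEX_GC2
  set.seed(1)
  ord <- unlist(lapply(split(seq_len(nrow(s$atoms)), s$atoms$res),
                       sample))
  s2 <- s
  s2$atoms <- s$atoms[ord, ]
  s2 <- rnarefine:::new_structure(s2$atoms)
  t1 <- build_topology(s, PARAMS)
  t2 <- build_topology(s2, PARAMS)
  key <- function(s, t) {
    a <- s$atoms
    sort(apply(t$bonds, 1, function(b)
      paste(sort(paste(a$chain[b], a$resnum[b], a$name[b])),
            collapse = "|")))
  }
  expect_identical(key(s, t1), key(s2, t2))
})

test_that("hydrogen completion is deterministic, idempotent and complete", {
  # heavy-atom-only G residue regains the full template atom count
  tpl <- residue_template("G", PARAMS)
  keep <- tpl$atoms$element != "H" &
    !(tpl$atoms$name %in% c("P", "OP1", "OP2"))
  atoms <- data.frame(serial = seq_len(sum(keep)),
                      name = tpl$atoms$name[keep], resname = "G",
                      chain = "A", resnum = 1L, icode = " ",
                      x = tpl$atoms$x[keep], y = tpl$atoms$y[keep],
                      z = tpl$atoms$z[keep],
                      element = tpl$atoms$element[keep], record = "ATOM",
                      stringsAsFactors = FALSE)
  s <- rnarefine:::new_structure(atoms)
  sh <- add_hydrogens(s, PARAMS)
  # all template atoms except the 5'-phosphate group
  expect_equal(nrow(sh$atoms), nrow(tpl$atoms) - 3L)
  # placed at template-ideal positions: re-protonation changes nothing
  sh2 <- add_hydrogens(sh, PARAMS)
  expect_identical(sh$atoms$name, sh2$atoms$name)
  expect_equal(get_coords(sh2), get_coords(sh), tolerance = 1e-12)
  # uracil: N3 carries the imino hydrogen, glycosidic N1 carries none
  u <- residue_template("U", PARAMS)
  expect_true(any(u$donors[, 1] == "N3" & u$donors[, 2] == "H3"))
  adj <- rnarefine:::template_adjacency(u)
  n1 <- match("N1", u$atoms$name)
  expect_false(any(u$atoms$element[adj[[n1]]] == "H"))
})
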