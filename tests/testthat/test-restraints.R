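# Restraint construction: Vienna parsing, base-pair detection and
# user-imposed secondary structure, hydrogen-bond/planarity assignment,
# conformer library and custom restraints.

# a minimal single-chain structure with n one-atom residues, for parsers
chainN <- function(n, chain = "A") {
  atoms <- data.frame(serial = seq_len(n), name = "C1'", resname = "A",
                      chain = chain, resnum = seq_len(n), icode = " ",
                      x = 3 * seq_len(n), y = 0, z = 0, element = "C",
                      record = "ATOM", stringsAsFactors = FALSE)
  rnarefine:::new_structure(atoms)
}

test_that("Vienna dot-bracket parsing matches a stack oracle", {
  s7 <- chainN(7)
  pr <- parse_vienna("((...))", s7)
  expect_equal(pr$i, c(1, 2))
  expect_equal(pr$j, c(7, 6))
  expect_equal(nrow(parse_vienna("......", chainN(6))), 0L)
  # pseudoknot: bracket tiers are independent
  pk <- parse_vienna("([)]", chainN(4))
  expect_equal(pk[order(pk$i), ]$j, c(3, 4))
  # property: against an independent stack-matching oracle
  oracle <- function(s) {
    st <- integer(); out <- NULL
    for (k in seq_along(s)) {
      if (s[k] == "(") st <- c(st, k)
      else if (s[k] == ")") { out <- rbind(out, c(st[length(st)], k))
        st <- st[-length(st)] }
    }
    if (is.null(out)) return(NULL)
    out[order(out[, 1]), , drop = FALSE]
  }
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    s <- character(n); depth <- 0
    for (k in seq_len(n)) {
      op <- runif(1) < 0.4 && (n - k) > depth
      cl <- depth > 0 && runif(1) < 0.3
      s[k] <- if (op) "(" else if (cl) ")" else "."
      depth <- depth + (s[k] == "(") - (s[k] == ")")
    }
    while (depth > 0) { s <- c(s, ")"); depth <- depth - 1 }
    got <- parse_vienna(paste(s, collapse = ""), chainN(length(s)))
    want <- oracle(s)
    if (is.null(want)) expect_equal(nrow(got), 0L)
    else {
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(got$i, want[, 1])
      expect_equal(got$j, want[, 2])
    }
  }
})

test_that("unbalanced or invalid Vienna strings fail with a position", {
  expect_error(parse_vienna("((..)", chainN(5)), "position 1")
  expect_error(parse_vienna(".))..", chainN(5)), "position 2")
  expect_error(parse_vienna("..x..", chainN(5)), "position 3")
  expect_error(parse_vienna("...", chainN(5)), "length")
  two <- rnarefine:::new_structure(rbind(chainN(2)$atoms,
                                         chainN(2, "B")$atoms))
  expect_error(parse_vienna("....", two), "contact list")
})

test_that("contact lists resolve chain-qualified residues", {
  pr <- parse_contacts(c("A:1 B:2", "# comment", ""),
                       rnarefine:::new_structure(
                         rbind(chainN(2)$atoms, chainN(2, "B")$atoms)))
  expect_equal(nrow(pr), 1L)
  expect_error(parse_contacts("A:9 B:1", DUPLEX_6), "cannot resolve")
})

test_that("the detector finds every pair of an ideal helix below -2 kcal/mol", {
  dx <- generate_aform_duplex("GGCGCAUG", PARAMS)
  bp <- detect_base_pairs(dx, PARAMS)
  expect_equal(nrow(bp), 8L)
  expect_true(all(bp$energy < PARAMS$addons$pair_energy_threshold))
  # each strand-1 residue pairs its antiparallel partner
  expect_equal(bp$j, 16 + 1 - bp$i)
})

test_that("distant bases are not paired", {
  # two isolated G and C residues 20 A apart
  g <- residue_template("G", PARAMS)
  c_ <- residue_template("C", PARAMS)
  mk <- function(tpl, chain, shift) {
    keep <- !(tpl$atoms$name %in% c("P", "OP1", "OP2"))
    data.frame(serial = NA_integer_, name = tpl$atoms$name[keep],
               resname = tpl$name, chain = chain, resnum = 1L,
               icode = " ", x = tpl$atoms$x[keep] + shift,
               y = tpl$atoms$y[keep], z = tpl$atoms$z[keep],
               element = tpl$atoms$element[keep], record = "ATOM",
               stringsAsFactors = FALSE)
  }
  s <- rnarefine:::new_structure(rbind(mk(g, "A", 0), mk(c_, "B", 20)))
  expect_equal(nrow(detect_base_pairs(s, PARAMS)), 0L)
})

test_that("detection is symmetric under residue order in the file", {
  dx <- generate_aform_duplex("GAUC", PARAMS)
  rev_atoms <- do.call(rbind, rev(split(dx$atoms, dx$atoms$res)))
  s2 <- rnarefine:::new_structure(rev_atoms)
  key <- function(s, bp) {
    rt <- rnarefine:::residue_table(s)
    sort(paste(pmin(paste0(rt$chain[bp$i], rt$resnum[bp$i]),
                    paste0(rt$chain[bp$j], rt$resnum[bp$j])),
               pmax(paste0(rt$chain[bp$i], rt$resnum[bp$i]),
                    paste0(rt$chain[bp$j], rt$resnum[bp$j]))))
  }
  expect_identical(key(dx, detect_base_pairs(dx, PARAMS)),
                   key(s2, detect_base_pairs(s2, PARAMS)))
})

test_that("user secondary structure bypasses the detector entirely", {
  # single chain helix-like strand: take chain A of a duplex and pair it
  # against chain B via contacts; detector must never run
  dx <- generate_aform_duplex("GGCGCAUG", PARAMS)
  called <- 0L
  local_mocked_bindings(
    detect_base_pairs = function(...) { called <<- called + 1L
      stop("detector must not run") },
    .package = "rnarefine")
  contacts <- paste0("A:", 1:4, " B:", 8:5)
  rset <- build_restraints(dx, PARAMS, default_config(),
                           contacts = paste(contacts, collapse = "\n"))
  expect_identical(called, 0L)
  expect_equal(nrow(rset$pairs), 4L)
  expect_identical(rset$source, "user")
  # exactly the user pairs are restrained
  expect_equal(rset$pairs$i, 1:4)
})

test_that("hydrogen-bond triples follow the Watson-Crick edge tables", {
  dx <- generate_aform_duplex("GA", PARAMS)   # pairs: G-C and A-U
  bp <- detect_base_pairs(dx, PARAMS)
  expect_equal(nrow(bp), 2L)
  hb <- assign_hbond_restraints(bp, dx, PARAMS)
  rt <- rnarefine:::residue_table(dx)
  per_pair <- table(vapply(seq_len(nrow(hb)), function(k)
    min(dx$atoms$res[hb$d[k]], dx$atoms$res[hb$a[k]]), 0))
  gc_res <- bp$i[rt$resname[bp$i] %in% c("G", "C")]
  au_res <- bp$i[rt$resname[bp$i] %in% c("A", "U")]
  expect_equal(unname(per_pair[as.character(gc_res)]), 3L)
  expect_equal(unname(per_pair[as.character(au_res)]), 2L)
  expect_equal(nrow(assign_hbond_restraints(bp[0, ], dx, PARAMS)), 0L)
})

test_that("planarity groups are one per pair over both bases' heavy atoms", {
  dx <- generate_aform_duplex("GGCGCAUG", PARAMS)
  bp <- detect_base_pairs(dx, PARAMS)
  pg <- assign_planarity_groups(bp, dx)
  expect_length(pg, nrow(bp))
  a <- dx$atoms
  g1 <- pg[[1]]
  expect_setequal(unique(a$res[g1]), c(bp$i[1], bp$j[1]))
  expect_true(all(a$element[g1] != "H"))
  expect_false(any(a$name[g1] %in% c("C1'", "P", "O4'")))
  # planarity disabled: no groups are built
  cfg <- merge_config(list(planarity = "off"))
  rset <- build_restraints(dx, PARAMS, cfg)
  expect_length(rset$planarity, 0L)
})

test_that("the packaged conformer library is schema-consistent and stable", {
  lib <- build_builtin_library()
  expect_gt(length(lib$fragments), 1L)
  expect_equal(lib$schema[1], "P")
  for (fr in lib$fragments) expect_equal(nrow(fr), length(lib$schema))
  lib2 <- build_builtin_library()
  expect_identical(lib, lib2)
})

test_that("conformer selection agrees with a brute-force scan", {
  lib <- build_builtin_library()
  # exact copies and rigidly moved copies select their own entry
  sel <- select_reference_conformer(lib$fragments[[3]], lib)
  expect_equal(sel$index, 3L)
  expect_equal(sel$rmsd, 0, tolerance = 1e-12)
  set.seed(8)
  R <- random_rotation()
  moved <- sweep(lib$fragments[[5]] %*% R, 2, c(10, -4, 2), `+`)
  sel <- select_reference_conformer(moved, lib)
  expect_equal(sel$index, 5L)
  expect_lt(sel$rmsd, 1e-8)
  # 100 random fragments vs an independent exhaustive scan
  for (rep in 1:100) {
    base <- lib$fragments[[sample(length(lib$fragments), 1)]]
    frag <- base + 0.25 * matrix(rnorm(length(base)), nrow(base), 3)
    got <- select_reference_conformer(frag, lib)
    rmsds <- vapply(lib$fragments, function(fr)
      quaternion_rmsd(fr, frag), 0)
    expect_equal(got$index, unname(which.min(rmsds)))
    expect_equal(got$rmsd, unname(min(rmsds)), tolerance = 1e-8)
  }
  expect_error(select_reference_conformer(matrix(0, 4, 3), lib),
               "schema")
})

test_that("custom restraint files parse into spring definitions", {
  dx <- DUPLEX_6
  txt <- c("# distance restraint between the terminal glycosidic atoms",
           "DIST A 1 N9 B 6 N1 2.85 5.0",
           "POSN A 1 P 1.0 2.0 3.0 10.0")
  # residue A1 has no 5' phosphate: use C1' instead for POSN
  txt[3] <- "POSN A 1 C1' 1.0 2.0 3.0 10.0"
  sp <- parse_restraint_file(txt, dx)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$rest[1], 2.85)
  expect_equal(sp$k, c(5, 10))
  expect_identical(sp$type, c("dist", "posn"))
  expect_equal(unlist(sp[2, c("px", "py", "pz")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(nrow(parse_restraint_file("", dx)), 0L)
  expect_error(parse_restraint_file("DIST A 1 N9 B 6 N1 2.85 -1", dx),
               "negative")
  expect_error(parse_restraint_file("DIST A 1 XX B 6 N1 2.85 1", dx),
               "line 1")
})
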