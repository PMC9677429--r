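# Bond detection, hydrogen extension, atom typing, charge scaling and the
# databank file format.

two_atoms <- function(el1, el2, d) {
  epmm_structure(data.frame(
    elety = c(el1, el2), element = c(el1, el2), resid = "XXX",
    chain = "A", resno = 1:2, x = c(0, d), y = 0, z = 0))
}

test_that("bond detection follows radii plus tolerance", {
  cc <- two_atoms("C", "C", 1.54)
  expect_identical(nrow(detect_bonds(cc)), 1L)
  # metal override: Mg radius 0.01 suppresses, 1.36 restores Mg-O bonds
  mgo <- two_atoms("MG", "O", 2.1)
  expect_identical(nrow(detect_bonds(mgo, covalent_radii(c(MG = 0.01)))), 0L)
  expect_identical(nrow(detect_bonds(mgo, covalent_radii())), 1L)
  # single atom: empty bond list
  one <- two_atoms("C", "C", 1.54)[1, ]
  expect_identical(nrow(detect_bonds(one)), 0L)
  # duplicate atoms at zero distance are an error
  expect_error(detect_bonds(two_atoms("C", "C", 0)), "zero distance")
})

test_that("hydrogens are extended to neutron distances along the bond", {
  oh <- epmm_structure(data.frame(
    elety = c("O", "H"), element = c("O", "H"), resid = "HOH", chain = "W",
    resno = 1, x = c(0, 0.82 / sqrt(2)), y = c(0, 0.82 / sqrt(2)), z = 0))
  b <- detect_bonds(oh)
  ext <- extend_hydrogens(oh, b)
  v <- c(ext$x[2], ext$y[2], ext$z[2])
  expect_equal(sqrt(sum(v^2)), 0.983, tolerance = 1e-10)
  # direction preserved
  expect_equal(v / sqrt(sum(v^2)), c(1, 1, 0) / sqrt(2), tolerance = 1e-10)
  # already at the table distance: unchanged
  ext2 <- extend_hydrogens(ext, b)
  expect_equal(ext2$x, ext$x, tolerance = 1e-10)
})

test_that("water extension preserves the H-O-H angle", {
  w <- make_water_structure()
  b <- detect_bonds(w)
  angle <- function(st) {
    u <- c(st$x[2] - st$x[1], st$y[2] - st$y[1], st$z[2] - st$z[1])
    v <- c(st$x[3] - st$x[1], st$y[3] - st$y[1], st$z[3] - st$z[1])
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  ext <- extend_hydrogens(w, b)
  expect_equal(angle(ext), angle(w), tolerance = 1e-9)
  expect_equal(sqrt((ext$x[2] - ext$x[1])^2 + (ext$y[2] - ext$y[1])^2 +
                      (ext$z[2] - ext$z[1])^2), 0.983, tolerance = 1e-9)
})

test_that("hydrogen extension errors name the offending atom", {
  lone_h <- epmm_structure(data.frame(
    elety = "H", element = "H", resid = "XXX", chain = "A", resno = 1,
    x = 0, y = 0, z = 0))
  expect_error(extend_hydrogens(lone_h, detect_bonds(lone_h)), "H.*0 heavy")
  bridge <- epmm_structure(data.frame(
    elety = c("O", "H", "O"), element = c("O", "H", "O"), resid = "XXX",
    chain = "A", resno = 1, x = c(0, 1.0, 2.0), y = 0, z = 0))
  expect_error(extend_hydrogens(bridge, detect_bonds(bridge)), "2 heavy")
})

test_that("atom typing picks the most specific entry and is order-stable", {
  db <- fixture_db()
  w <- make_water_structure()
  types <- assign_atom_types(w, detect_bonds(w), db)
  expect_identical(types, c("O_water", "H_O", "H_O"))
  # unknown element errors listing the atom
  fe <- two_atoms("FE", "O", 1.9)
  expect_error(assign_atom_types(fe, detect_bonds(fe), db), "FE")
  # permutation of atom order yields the identical mapping
  tc <- make_toy_complex(toy_complex_spec(seed = 3))
  st <- tc$structure
  types1 <- assign_atom_types(st, detect_bonds(st), db)
  perm <- rev(seq_len(nrow(st)))
  st2 <- epmm_structure(as.data.frame(st)[perm, ])
  types2 <- assign_atom_types(st2, detect_bonds(st2), db)
  expect_identical(types2, types1[perm])
})

test_that("fallback specificity order is full key, count, element", {
  db <- databank(list(
    full = list(key = atom_type_key("O", c("H", "H")),
                params = pseudoatom_parameters("O", 2, 6.7, zeta = 2.2)),
    cnt = list(key = atom_type_key("O", c("COUNT", 2)),
               params = pseudoatom_parameters("O", 2, 6.2, zeta = 2.2)),
    any = list(key = atom_type_key("O", "ANY"),
               params = pseudoatom_parameters("O", 2, 6.0, zeta = 2.2)),
    H = list(key = atom_type_key("H", "ANY"),
             params = pseudoatom_parameters("H", 0, 1, zeta = 2.0)),
    C = list(key = atom_type_key("C", "ANY"),
             params = pseudoatom_parameters("C", 2, 4, zeta = 1.57))))
  w <- make_water_structure()
  expect_identical(assign_atom_types(w, detect_bonds(w), db)[1], "full")
  # O with two C neighbors: no full key, count level matches
  ether <- epmm_structure(data.frame(
    elety = c("C", "O", "C"), element = c("C", "O", "C"), resid = "ETH",
    chain = "A", resno = 1, x = c(-1.43, 0, 1.43), y = 0, z = 0))
  expect_identical(assign_atom_types(ether, detect_bonds(ether), db)[2],
                   "cnt")
  # O with one C: falls through to the element entry
  co <- epmm_structure(data.frame(
    elety = c("C", "O"), element = c("C", "O"), resid = "CO", chain = "A",
    resno = 1, x = c(0, 1.2), y = 0, z = 0))
  expect_identical(assign_atom_types(co, detect_bonds(co), db)[2], "any")
})

test_that("ambiguous equal-specificity matches are an error", {
  db <- databank(list(
    a1 = list(key = atom_type_key("O", "ANY"),
              params = pseudoatom_parameters("O", 2, 6.1, zeta = 2.2)),
    a2 = list(key = atom_type_key("O", "ANY"),
              params = pseudoatom_parameters("O", 2, 6.2, zeta = 2.2))))
  lone <- epmm_structure(data.frame(
    elety = "O", element = "O", resid = "X", chain = "A", resno = 1,
    x = 0, y = 0, z = 0))
  expect_error(assign_atom_types(lone, detect_bonds(lone), db), "ambiguous")
})

test_that("charge scaling hits formal charges exactly and proportionally", {
  toy <- toy_scaled_model()
  m <- toy$model
  for (k in seq_along(m$meta$fragments)) {
    q <- sum(vapply(m$atoms[m$meta$fragments[[k]]], epmm:::.atom_charge,
                    numeric(1)))
    expect_equal(q, m$meta$formal_charges[k], tolerance = 1e-8)
  }
  expect_equal(molecular_charge(m), sum(m$meta$formal_charges),
               tolerance = 1e-8)
  # fragment already at its formal charge: populations unchanged
  w <- transfer_parameters(make_water_structure(), fixture_db())
  pv0 <- vapply(w$atoms, function(a) a$params$P_val, numeric(1))
  ws <- scale_fragment_charges(w, list(fragment_charge_spec("W1", 0)))
  pv1 <- vapply(ws$atoms, function(a) a$params$P_val, numeric(1))
  expect_equal(pv1, pv0, tolerance = 1e-10)
})

test_that("two-atom scaling distributes the shift proportionally to P_val", {
  # hand linear algebra: P_val (4, 1), charge +0.4 -> target 0 means adding
  # 0.4 electrons split 4:1, i.e. (4.32, 1.08)
  db <- databank(list(
    C = list(key = atom_type_key("C", "ANY"),
             params = pseudoatom_parameters("C", 2, 4, zeta = 1.57)),
    H = list(key = atom_type_key("H", "ANY"),
             params = pseudoatom_parameters("H", 0, 0.6, zeta = 2.0))))
  st <- two_atoms("C", "H", 1.09)
  st$resno <- 1
  m <- transfer_parameters(st, db, extend_h = FALSE)
  expect_equal(molecular_charge(m), 0.4, tolerance = 1e-12)
  ms <- scale_fragment_charges(m, list(fragment_charge_spec("A1", 0)))
  pv <- vapply(ms$atoms, function(a) a$params$P_val, numeric(1))
  expect_equal(pv, c(4 + 0.4 * 4 / 4.6, 0.6 + 0.4 * 0.6 / 4.6),
               tolerance = 1e-10)
})

test_that("scaling a zero-valence fragment is an error", {
  db <- databank(list(
    H = list(key = atom_type_key("H", "ANY"),
             params = pseudoatom_parameters("H", 0, 0, zeta = 2.0))))
  st <- two_atoms("H", "H", 2.0)
  st$resno <- 1
  m <- transfer_parameters(st, db, extend_h = FALSE)
  expect_error(scale_fragment_charges(m, list(fragment_charge_spec("A1", 0))),
               "zero total valence")
})

test_that("transfer is deterministic and independent of atom order", {
  db <- fixture_db()
  tc <- make_toy_complex(toy_complex_spec(seed = 5))
  m1 <- transfer_parameters(tc$structure, db)
  perm <- sample(seq_len(nrow(tc$structure)))
  st2 <- epmm_structure(as.data.frame(tc$structure)[perm, ])
  m2 <- transfer_parameters(st2, db)
  q1 <- vapply(m1$atoms, epmm:::.atom_charge, numeric(1))
  q2 <- vapply(m2$atoms, epmm:::.atom_charge, numeric(1))
  expect_equal(q2, q1[perm], tolerance = 1e-12)
  lab1 <- vapply(m1$atoms, function(a) a$label, character(1))
  lab2 <- vapply(m2$atoms, function(a) a$label, character(1))
  expect_identical(lab2, lab1[perm])
  # scaled charges agree atom by atom too
  s1 <- scale_fragment_charges(m1, tc$charge_specs)
  s2 <- scale_fragment_charges(m2, tc$charge_specs)
  p1 <- vapply(s1$atoms, function(a) a$params$P_val, numeric(1))
  p2 <- vapply(s2$atoms, function(a) a$params$P_val, numeric(1))
  expect_equal(p2, p1[perm], tolerance = 1e-12)
})

test_that("databank files round-trip bit-identically", {
  db <- fixture_db()
  f1 <- tempfile(fileext = ".txt")
  f2 <- tempfile(fileext = ".txt")
  write_databank(db, f1)
  db2 <- read_databank(f1)
  write_databank(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(names(db2$entries), names(db$entries))
  # the shipped fixture databank file matches the in-code generator
  shipped <- system.file("extdata", "fixture_databank.txt", package = "epmm")
  f3 <- tempfile(fileext = ".txt")
  write_databank(db, f3)
  expect_identical(readLines(f3), readLines(shipped))
})

test_that("wavefunction table files round-trip", {
  wf <- default_wavefunctions()
  f <- tempfile(fileext = ".txt")
  write_wavefunctions(wf, f)
  wf2 <- read_wavefunctions(f)
  expect_equal(wf2$elements$O$zeta, wf$elements$O$zeta)
  expect_identical(names(wf2$elements), names(wf$elements))
})
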