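# Multipole-moment, exact-potential and hybrid EPMM energies.

test_that("monopole pair reproduces Coulomb's law to 6 significant figures", {
  dm <- make_slater_dimer(2.5, 2.5, 3.0, q_a = +1, q_b = -1)
  e <- multipole_pair_energy(dm$a$atoms[[1]], dm$b$atoms[[1]])
  expect_equal(e, -332.0637 / 3, tolerance = 5e-7)
})

test_that("atoms with zero multipoles do not interact through MM", {
  dm <- make_slater_dimer(1.0, 1.2, 2.0)   # both neutral, spherical
  e <- multipole_pair_energy(dm$a$atoms[[1]], dm$b$atoms[[1]])
  expect_lt(abs(e), 1e-10)
})

test_that("collinear point dipoles follow the -2 mu1 mu2 / R^3 law", {
  mk_dip <- function(p10, x) {
    p <- pseudoatom_parameters("H", P_core = 0, P_val = 1,
                               P_lm = c("1,0" = p10), zeta = 1.3)
    pseudoatom(p, c(0, 0, x), frame = diag(3), label = paste0("d", x))
  }
  d1 <- mk_dip(0.2, 0)
  d2 <- mk_dip(0.3, 4)
  mu1 <- unname(atomic_multipole_moments(d1, 1, "local")["1,0"])  # e A
  mu2 <- unname(atomic_multipole_moments(d2, 1, "local")["1,0"])
  e <- multipole_pair_energy(d1, d2)
  expect_equal(e, -2 * mu1 * mu2 / 4^3 * epmm_constants$coulomb_kcal,
               tolerance = 1e-6)
})

test_that("exact and multipole energies agree for non-overlapping densities", {
  dm <- make_slater_dimer(2.0, 2.0, 20, q_a = +1, q_b = -1)
  a <- dm$a$atoms[[1]]
  b <- dm$b$atoms[[1]]
  expect_equal(exact_pair_energy(a, b), multipole_pair_energy(a, b),
               tolerance = 1e-3)
})

test_that("two 1s-Slater clouds match the symbolic Coulomb integral", {
  for (cs in list(c(1.0, 1.0, 1.5), c(1.0, 1.4, 2.0), c(1.3, 0.9, 3.0))) {
    dm <- make_slater_dimer(cs[1], cs[2], cs[3])
    got <- exact_pair_energy(dm$a$atoms[[1]], dm$b$atoms[[1]])
    expect_lt(abs(got - slater_dimer_closed_form(cs[1], cs[2], cs[3])),
              1e-3)
  }
})

test_that("exact pair energy is symmetric in its arguments", {
  db <- fixture_db()
  po <- db$entries$O_C$params
  o1 <- pseudoatom(po, c(0, 0, 0), frame = diag(3), label = "o1")
  o2 <- pseudoatom(po, c(0.8, 1.1, 2.2),
                   frame = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                   label = "o2")
  expect_equal(exact_pair_energy(o1, o2), exact_pair_energy(o2, o1),
               tolerance = 1e-4)
})

test_that("coincident centers are rejected", {
  dm <- make_slater_dimer(1, 1, 1)
  a <- dm$a$atoms[[1]]
  expect_error(multipole_pair_energy(a, a), "coincident")
  expect_error(exact_pair_energy(a, a), "coincident")
})

test_that("hybrid energy uses MM beyond rcrit and EP inside", {
  w1 <- water_model()
  w2 <- water_model(center = c(12, 0, 0), resno = 2, chain = "X")
  e_far <- epmm_energy(w1, w2)
  # all pairs beyond rcrit: penetration identically zero, EPMM == MM
  expect_true(all(e_far$pair_breakdown$method == "MM"))
  expect_identical(e_far$e_pen, 0)
  expect_identical(e_far$e_epmm, e_far$e_mm)

  w3 <- water_model(center = c(2.9, 0.5, 0.3), resno = 3, chain = "Y")
  e_near <- epmm_energy(w1, w3, quad = quad_fast)
  expect_true(any(e_near$pair_breakdown$method == "EP"))
  expect_equal(e_near$e_pen, e_near$e_epmm - e_near$e_mm, tolerance = 1e-12)
})

test_that("penetration is negative for a charged H-bonded dimer", {
  # ammonium-like donor against carboxylate-like acceptor at H-bond geometry
  tm <- epmm:::.toy_templates()
  lys <- tm$plus
  glu <- tm$minus
  stl <- epmm_structure(data.frame(
    elety = lys$elety, element = lys$element, resid = "LYS", chain = "A",
    resno = 1, x = lys$xyz[, 1], y = lys$xyz[, 2], z = lys$xyz[, 3]))
  hpos <- lys$xyz[2, ]
  n <- hpos / sqrt(sum(hpos^2))
  shift <- hpos + 1.90 * n - glu$xyz[3, ]
  gx <- sweep(glu$xyz, 2, shift, `+`)
  stg <- epmm_structure(data.frame(
    elety = glu$elety, element = glu$element, resid = "GLU", chain = "B",
    resno = 1, x = gx[, 1], y = gx[, 2], z = gx[, 3]))
  db <- fixture_db()
  ml <- scale_fragment_charges(transfer_parameters(stl, db),
                               list(fragment_charge_spec("A1", +1)))
  mg <- scale_fragment_charges(transfer_parameters(stg, db),
                               list(fragment_charge_spec("B1", -1)))
  e <- epmm_energy(ml, mg, breakdown = FALSE)
  expect_lt(e$e_pen, 0)
  expect_lt(e$e_epmm, 0)   # attractive salt bridge
  # independent oracle agrees on the hybrid total
  orc <- brute_force_coulomb_oracle(ml, mg)
  expect_equal(e$e_epmm, orc, tolerance = 0.15)
})

test_that("penetration decays monotonically and vanishes by 10 angstrom", {
  seps <- c(2.0, 2.6, 3.2, 4.0, 10)
  pens <- vapply(seps, function(s) {
    dm <- make_slater_dimer(1.1, 1.3, s)
    epmm_energy(dm$a, dm$b, quad = quadrature_spec(rcrit = 12),
                breakdown = FALSE)$e_pen
  }, numeric(1))
  expect_true(all(diff(abs(pens)) < 0))
  expect_lt(abs(pens[length(pens)]), 1e-3)
  expect_true(all(pens[1:3] < 0))   # attractive at overlap
})

test_that("energies are invariant under rigid motion of both models", {
  w1 <- water_model()
  w2 <- water_model(center = c(3.1, 0.4, -0.2), resno = 2, chain = "X")
  e0 <- epmm_energy(w1, w2, quad = quad_fast, breakdown = FALSE)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  tr <- c(5.5, -2.2, 7.1)
  move <- function(m) {
    st <- m$meta$structure
    xyz <- t(R %*% t(as.matrix(st[, c("x", "y", "z")]))) +
      matrix(tr, nrow(st), 3, byrow = TRUE)
    st$x <- xyz[, 1]; st$y <- xyz[, 2]; st$z <- xyz[, 3]
    mm <- transfer_parameters(st, fixture_db(), extend_h = FALSE)
    mm$meta$scaled <- TRUE
    mm
  }
  e1 <- epmm_energy(move(w1), move(w2), quad = quad_fast, breakdown = FALSE)
  expect_equal(e1$e_mm, e0$e_mm, tolerance = 1e-6)
  expect_equal(e1$e_epmm, e0$e_epmm, tolerance = 1e-6)
})

test_that("pair breakdown sums reproduce the totals exactly", {
  w1 <- water_model()
  w2 <- water_model(center = c(3.0, 0.8, 0.1), resno = 2, chain = "X")
  e <- epmm_energy(w1, w2, quad = quad_fast)
  expect_equal(sum(e$pair_breakdown$e_mm), e$e_mm, tolerance = 1e-12)
  expect_equal(sum(e$pair_breakdown$e_epmm), e$e_epmm, tolerance = 1e-12)
  expect_equal(e$e_pen, e$e_epmm - e$e_mm, tolerance = 1e-12)
})

test_that("doubling rcrit barely changes the hybrid energy", {
  w1 <- water_model()
  w2 <- water_model(center = c(3.2, 0.6, 0.4), resno = 2, chain = "X")
  e5 <- epmm_energy(w1, w2, quad = quadrature_spec(rcrit = 5),
                    breakdown = FALSE)
  e10 <- epmm_energy(w1, w2, quad = quadrature_spec(rcrit = 10),
                     breakdown = FALSE)
  expect_lt(abs(e10$e_epmm - e5$e_epmm), 0.05)
})

test_that("models sharing atom identities are rejected", {
  w1 <- water_model()
  expect_error(epmm_energy(w1, w1), "share atom identities")
})

test_that("point-charge Coulomb energies", {
  a <- point_charge_set(1, matrix(c(0, 0, 0), 1))
  b <- point_charge_set(-1, matrix(c(3, 0, 0), 1))
  expect_equal(point_charge_energy(a, b), -332.0637 / 3, tolerance = 1e-12)
  # neutral set at long range: decays to zero
  wat <- point_charge_set(c(-0.834, 0.417, 0.417),
                          rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  far <- point_charge_set(1, matrix(c(80, 0, 0), 1))
  expect_lt(abs(point_charge_energy(wat, far)), 0.06)
  expect_error(point_charge_energy(a, point_charge_set(1, matrix(0, 1, 3))),
               "zero interatomic")
  # monopole-limit agreement: contracted spherical pseudoatoms vs points
  dm <- make_slater_dimer(4, 4, 3.0, q_a = 0.4, q_b = -0.7)
  e_mp <- multipole_pair_energy(dm$a$atoms[[1]], dm$b$atoms[[1]])
  e_pc <- point_charge_energy(point_charge_set(0.4, matrix(c(0, 0, 0), 1)),
                              point_charge_set(-0.7, matrix(c(3, 0, 0), 1)))
  expect_equal(e_mp, e_pc, tolerance = 1e-4)
})

test_that("EP energies are converged at the default grids", {
  db <- fixture_db()
  po <- db$entries$O_P$params
  ph <- db$entries$H_O$params
  o <- pseudoatom(po, c(0, 0, 0), frame = diag(3), label = "o")
  h <- pseudoatom(ph, c(1.9, 0.6, 0), frame = diag(3), label = "h")
  e1 <- exact_pair_energy(o, h, quadrature_spec(99, 590))
  e2 <- exact_pair_energy(o, h, quadrature_spec(199, 974))
  expect_lt(abs(e2 - e1), 0.01)
})
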