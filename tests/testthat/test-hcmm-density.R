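# The Hansen-Coppens pseudoatom density, its normalization, moments and
# frame behavior.

# numerically integrate a pseudoatom density over all space with an
# independent combination of adaptive radial integration and an angular grid
integrate_density <- function(atom, n_ang = 590) {
  ag <- angular_grid(n_ang)
  f <- function(r_A) {
    vapply(r_A, function(r) {
      pts <- ag$points * r
      sum(ag$weights * evaluate_density(atom, pts))
    }, numeric(1)) * (r_A / epmm_constants$bohr_A)^2 / epmm_constants$bohr_A
  }
  stats::integrate(f, 0, 25, rel.tol = 1e-8, subdivisions = 200L)$value
}

test_that("pseudoatom density decays and integrates to its populations", {
  p <- pseudoatom_parameters("O", P_core = 2, P_val = 6.3, kappa = 0.97,
                             zeta = 2.2266)
  at <- pseudoatom(p, c(0, 0, 0))
  # core-only style decay: far point is numerically zero
  expect_lt(evaluate_density(at, c(30, 0, 0)), 1e-12)
  # 4 pi int rho r^2 dr = P_core + P_val for spherical atoms
  expect_equal(integrate_density(at), 8.3, tolerance = 1e-5)
})

test_that("hydrogen-like pseudoatom matches the closed-form Slater density", {
  p <- pseudoatom_parameters("H", P_core = 0, P_val = 1, kappa = 1, zeta = 1)
  wf <- wavefunction_table(list(H = data.frame(
    label = "1s", n = 1L, zeta = 1, occ = 1, role = "valence")))
  at <- pseudoatom(p, c(0, 0, 0), wf = wf)
  r_A <- 0.5
  r_B <- r_A / epmm_constants$bohr_A
  expect_equal(evaluate_density(at, c(r_A, 0, 0)), exp(-2 * r_B) / pi,
               tolerance = 1e-12)
})

test_that("kappa scaling preserves the valence normalization", {
  for (k in c(0.8, 1.0, 1.2)) {
    p <- pseudoatom_parameters("C", P_core = 2, P_val = 4, kappa = k,
                               zeta = 1.5679)
    at <- pseudoatom(p, c(0, 0, 0))
    expect_equal(integrate_density(at), 6, tolerance = 1e-5,
                 label = paste("kappa =", k))
  }
})

test_that("deformation terms carry zero net charge", {
  p <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                             P_lm = c("1,0" = 0.3, "2,2" = -0.2,
                                      "3,-1" = 0.15, "4,0" = 0.1),
                             zeta = 2.2266)
  at <- pseudoatom(p, c(0, 0, 0), frame = diag(3))
  # total integral equals the spherical populations alone
  expect_equal(integrate_density(at, n_ang = 974), 8, tolerance = 1e-5)
})

test_that("density is equivariant under joint rotation of frame and point", {
  p <- pseudoatom_parameters("N", P_core = 2, P_val = 5,
                             P_lm = c("1,0" = 0.2, "2,1" = -0.1,
                                      "4,-3" = 0.05),
                             zeta = 1.917)
  at0 <- pseudoatom(p, c(0, 0, 0), frame = diag(3))
  pts <- matrix(c(0.7, 0.2, -0.4, 1.1, -0.5, 0.3, 0.1, 0.9, 0.6), 3,
                byrow = TRUE)
  rho0 <- evaluate_density(at0, pts)
  set.seed(11)
  for (i in 1:10) {
    # random rotation via QR of a gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    atR <- pseudoatom(p, c(0, 0, 0), frame = R %*% diag(3))
    rhoR <- evaluate_density(atR, t(R %*% t(pts)))
    expect_equal(rhoR, rho0, tolerance = 1e-10)
  }
})

test_that("aspherical populations require a resolved local frame", {
  p <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                             P_lm = c("1,0" = 0.1), zeta = 2.2266)
  expect_error(pseudoatom(p, c(0, 0, 0), frame = NULL), "local frame")
  # spherical-only atoms do not need one
  p0 <- pseudoatom_parameters("O", P_core = 2, P_val = 6, zeta = 2.2266)
  expect_s3_class(pseudoatom(p0, c(0, 0, 0)), "pseudoatom")
})

test_that("atomic multipole moments follow the population algebra", {
  # neutral spherical atom: all moments vanish
  p0 <- pseudoatom_parameters("O", P_core = 2, P_val = 6, zeta = 2.2266)
  m0 <- atomic_multipole_moments(pseudoatom(p0, c(1, 2, 3)), max_l = 4)
  expect_lt(max(abs(m0)), 1e-12)
  # single P_10: dipole along local z only, linear in the population
  p1 <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                              P_lm = c("1,0" = 0.2), zeta = 2.2266)
  p2 <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                              P_lm = c("1,0" = 0.4), zeta = 2.2266)
  m1 <- atomic_multipole_moments(pseudoatom(p1, c(0, 0, 0), frame = diag(3)),
                                 max_l = 2, frame = "local")
  m2 <- atomic_multipole_moments(pseudoatom(p2, c(0, 0, 0), frame = diag(3)),
                                 max_l = 2, frame = "local")
  expect_lt(max(abs(m1[setdiff(names(m1), "1,0")])), 1e-12)
  expect_equal(m2["1,0"], 2 * m1["1,0"], tolerance = 1e-12)
})

test_that("reported dipole matches a quadrature oracle", {
  p <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                             P_lm = c("1,0" = 0.2), zeta = 2.2266)
  at <- pseudoatom(p, c(0, 0, 0), frame = diag(3))
  mom <- atomic_multipole_moments(at, max_l = 1, frame = "local")
  # oracle: mu_z = -int rho z d3r on a dense product grid (charge density
  # convention: electrons negative)
  gr <- radial_grid(120, 1.1)
  ag <- angular_grid(590)
  np <- nrow(ag$points)
  pts <- ag$points[rep(seq_len(np), times = length(gr$r)), ] *
    rep(gr$r, each = np)
  w <- rep(gr$weights, each = np) * rep(ag$weights, times = length(gr$r))
  rho <- evaluate_density(at, pts * epmm_constants$bohr_A)
  mu_z <- -sum(w * rho * pts[, 3]) * epmm_constants$bohr_A
  expect_equal(unname(mom["1,0"]), mu_z, tolerance = 1e-8)
})

test_that("global-frame moments rotate with the atom frame", {
  p <- pseudoatom_parameters("O", P_core = 2, P_val = 6,
                             P_lm = c("1,0" = 0.2), zeta = 2.2266)
  # frame with local z along global +x: dipole should appear on Q_{1,1} (x)
  fr <- cbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
  at <- pseudoatom(p, c(0, 0, 0), frame = fr)
  mg <- atomic_multipole_moments(at, max_l = 1, frame = "global")
  ml <- atomic_multipole_moments(at, max_l = 1, frame = "local")
  expect_equal(unname(mg["1,1"]), unname(ml["1,0"]), tolerance = 1e-10)
  expect_lt(abs(mg["1,0"]), 1e-10)
})

test_that("molecular charge sums atomic monopoles", {
  expect_identical(molecular_charge(density_model(list())), 0)
  w <- water_model()
  expect_equal(molecular_charge(w), 0, tolerance = 1e-6)
  toy <- toy_scaled_model()
  frag1 <- toy$model$meta$fragments[[1]]
  sub <- epmm:::.model_subset(toy$model, frag1)
  expect_equal(molecular_charge(sub),
               toy$toy$charge_specs[[1]]$formal_charge, tolerance = 1e-8)
})
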