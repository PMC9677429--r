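# Shared fixtures and independent closed-form oracles.

# Coulomb interaction (atomic units) of two unit exponential charge clouds
# rho_i(r) = a_i^3/(8 pi) exp(-a_i r) with a_i = 2 zeta_i, at separation R
# (Bohr). Derived symbolically from the bipolar expansion; the equal-
# exponent limit is the textbook two-cloud integral.
slater_cloud_coulomb_au <- function(zeta_a, zeta_b, R) {
  a <- 2 * zeta_a
  b <- 2 * zeta_b
  if (abs(a - b) < 1e-9) {
    1 / R - exp(-a * R) *
      (1 / R + 11 * a / 16 + 3 * a^2 * R / 16 + a^3 * R^2 / 48)
  } else {
    (-R * a^6 * b * exp(R * a) / 2 + R * a^4 * b^3 * exp(R * a) / 2 -
       R * a^3 * b^4 * exp(R * b) / 2 + R * a * b^6 * exp(R * b) / 2 -
       a^6 * exp(R * a) + a^6 * exp(R * (a + b)) +
       3 * a^4 * b^2 * exp(R * a) - 3 * a^4 * b^2 * exp(R * (a + b)) -
       3 * a^2 * b^4 * exp(R * b) + 3 * a^2 * b^4 * exp(R * (a + b)) +
       b^6 * exp(R * b) - b^6 * exp(R * (a + b))) *
      exp(-R * (a + b)) / (R * (a^6 - 3 * a^4 * b^2 + 3 * a^2 * b^4 - b^6))
  }
}

# full closed-form interaction (kcal/mol) of a Slater dimer from
# make_slater_dimer(): unit nuclei, clouds of (1 - q) electrons
slater_dimer_closed_form <- function(zeta_a, zeta_b, separation_A,
                                     q_a = 0, q_b = 0) {
  R <- separation_A / epmm_constants$bohr_A
  v_cloud <- function(zeta, r) 1 / r - exp(-2 * zeta * r) * (1 / r + zeta)
  na <- 1 - q_a
  nb <- 1 - q_b
  e <- 1 / R - nb * v_cloud(zeta_b, R) - na * v_cloud(zeta_a, R) +
    na * nb * slater_cloud_coulomb_au(zeta_a, zeta_b, R)
  e * epmm_constants$hartree_kcal
}

# cached fixture databank and toy complex (building the model once keeps the
# suite fast; tests treat these as read-only)
fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- make_fixture_databank()
    db
  }
})

toy_model_cache <- new.env()
toy_scaled_model <- function(seed = 42) {
  key <- paste0("m", seed)
  if (is.null(toy_model_cache[[key]])) {
    tc <- make_toy_complex(toy_complex_spec(seed = seed))
    m <- transfer_parameters(tc$structure, fixture_db())
    toy_model_cache[[key]] <- list(
      toy = tc, model = scale_fragment_charges(m, tc$charge_specs))
  }
  toy_model_cache[[key]]
}

# a transfered (unscaled-flag forced) water model at a given position
water_model <- function(center = c(0, 0, 0), resno = 1, chain = "W") {
  m <- transfer_parameters(make_water_structure(center, resno, chain),
                           fixture_db())
  m$meta$scaled <- TRUE
  m
}

# small but adequate quadrature for fast EP tests
quad_fast <- quadrature_spec(n_radial = 60, n_angular = 194)

# cached full pipeline report on the toy complex
toy_report <- local({
  rep <- NULL
  function() {
    if (is.null(rep)) {
      toy <- toy_scaled_model()
      part <- partition_fragments(toy$model$meta$structure)
      rep <<- residue_energy_table(toy$model, part, quad = quad_fast)
    }
    rep
  }
})
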