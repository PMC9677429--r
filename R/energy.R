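# Intermolecular electrostatic energies: Buckingham-type multipole-moment
# (MM) energies, exact-potential (EP) numerical Coulomb integrals of the
# continuous pseudoatom densities, the EPMM hybrid and its penetration
# contribution, and point-charge Coulomb energies.

# --- multipole-moment pair energy -------------------------------------------
#
# The interaction of the two truncated point-multipole sets is evaluated by
# contracting the analytic multipolar potential of atom a against a spherical
# "equivalent shell" carrying exactly the multipole moments of atom b. The
# angular quadrature is exact for the shell harmonics and the re-expansion
# error decays as (s/R)^(grid order), so the result is the spherical-tensor
# multipole energy to near machine precision without explicit interaction
# tensors.

.mm_pair_energy_au <- function(a, b, max_l = 4, n_angular = 302) {
  Rab <- .A2B(b$position - a$position)
  R <- sqrt(sum(Rab^2))
  if (R < 1e-8) stop("coincident atom centers in multipole energy")
  s <- min(0.4, R / 4)           # shell radius, Bohr
  grid <- angular_grid(n_angular)
  u <- grid$points
  pts <- sweep(u * s, 2, .A2B(b$position), `+`)
  # shell surface density reproducing b's moments (truncated at max_l)
  lm <- .lm_pairs(max_l)
  u_loc <- u %*% b$frame
  sigma <- numeric(nrow(u))
  for (k in seq_len(nrow(lm))) {
    l <- lm[k, 1]
    M <- b$M_local[paste(l, lm[k, 2], sep = ",")]
    if (M == 0) next
    sigma <- sigma + M * (2 * l + 1) / (4 * pi * s^(l + 2)) *
      real_sph_harm(l, lm[k, 2], u_loc)
  }
  v <- .atom_potential_multipole(a, pts, max_l = max_l)
  sum(grid$weights * s^2 * sigma * v)
}

#' Multipole-moment electrostatic pair energy
#'
#' Buckingham-type spherical-tensor interaction of the atomic multipole
#' moments of two pseudoatoms, including all couplings with
#' \eqn{l_a \le} `max_l` and \eqn{l_b \le} `max_l`. Exact for
#' non-overlapping densities.
#'
#' @param a,b [pseudoatom()] objects belonging to different molecules.
#' @param max_l Highest multipole order on each center (default 4).
#' @return Energy in kcal/mol.
#' @export
multipole_pair_energy <- function(a, b, max_l = 4) {
  .H2KCAL(.mm_pair_energy_au(a, b, max_l = max_l))
}

# --- exact-potential pair energy --------------------------------------------

# atom-centered quadrature of rho_center against the analytic electron
# potential of the partner atom; the grid is anchored to the pair geometry
# (z along the interatomic axis, azimuth from the center atom's local frame)
# so energies are exactly invariant under rigid motion of both molecules
.ee_half_integral <- function(center, partner, quad) {
  rg <- radial_grid(quad$n_radial, .rm_for_element(center$params$element))
  ag <- angular_grid(quad$n_angular)
  zax <- partner$position - center$position
  zax <- zax / sqrt(sum(zax^2))
  xax <- center$frame[, 1]
  xax <- xax - sum(xax * zax) * zax
  nx <- sqrt(sum(xax^2))
  xax <- if (nx < 1e-8) .perp_vector(zax) else xax / nx
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  M <- cbind(xax, yax, zax)
  np <- nrow(ag$points)
  nr <- length(rg$r)
  upts <- ag$points %*% t(M)
  pts <- upts[rep(seq_len(np), times = nr), , drop = FALSE] *
    rep(rg$r, each = np)
  pts <- sweep(pts, 2, .A2B(center$position), `+`)
  w <- rep(rg$weights, each = np) * rep(ag$weights, times = nr)
  rho <- evaluate_density(center, .B2A(pts))
  sum(w * rho * .atom_potential_electrons(partner, pts))
}

.ep_pair_energy_au <- function(a, b, quad) {
  Rab <- .A2B(b$position - a$position)
  R <- sqrt(sum(Rab^2))
  if (R < 1e-8) stop("coincident atom centers in exact-potential energy")
  # nucleus-nucleus and nucleus-electron terms are analytic (the Slater
  # potentials evaluated at the nuclei); only the smooth electron-electron
  # integral needs quadrature, symmetrized over both centers so the energy
  # is symmetric in (a, b) and the leading one-center error cancels.
  pa <- matrix(.A2B(a$position), 1)
  pb <- matrix(.A2B(b$position), 1)
  e_nn <- a$Z * b$Z / R
  e_ne <- -a$Z * .atom_potential_electrons(b, pa) -
    b$Z * .atom_potential_electrons(a, pb)
  e_ee <- 0.5 * (.ee_half_integral(b, a, quad) + .ee_half_integral(a, b, quad))
  e_nn + e_ne + e_ee
}

#' Exact Coulomb pair energy of two continuous pseudoatom densities
#'
#' Full electrostatic interaction of the two pseudoatom charge distributions
#' (continuous electron density plus nuclear point charge): the analytic
#' electrostatic potential of atom `a` (closed forms for Slater-type
#' primitives via incomplete gamma functions) is integrated against the
#' density of atom `b` on an atom-centered radial x angular quadrature grid.
#'
#' @param a,b [pseudoatom()] objects.
#' @param quad A [quadrature_spec()].
#' @return Energy in kcal/mol.
#' @export
exact_pair_energy <- function(a, b, quad = quadrature_spec()) {
  stopifnot(inherits(quad, "quadrature_spec"))
  .H2KCAL(.ep_pair_energy_au(a, b, quad))
}

# --- hybrid EPMM model-model energy -----------------------------------------

#' Hybrid exact-potential/multipole-moment interaction energy
#'
#' For every inter-model atom pair the exact Coulomb integral (EP) is used
#' when the separation is at most `quad$rcrit` and the multipole-moment (MM)
#' energy beyond it. The pure multipole energy over all pairs (`e_mm`, the
#' aMM energy) is always computed as well; the penetration energy is their
#' difference `e_pen = e_epmm - e_mm`, the short-range correction from
#' overlapping charge clouds.
#'
#' @param model_a,model_b [density_model()] objects with disjoint atoms.
#' @param quad A [quadrature_spec()].
#' @param max_l Multipole truncation order per center.
#' @param breakdown Keep the per-pair contribution table (default TRUE).
#' @return Object of class `interaction_energy` with fields `e_mm`,
#'   `e_epmm`, `e_pen` (kcal/mol) and `pair_breakdown`.
#' @export
epmm_energy <- function(model_a, model_b, quad = quadrature_spec(),
                        max_l = 4, breakdown = TRUE) {
  stopifnot(inherits(model_a, "density_model"),
            inherits(model_b, "density_model"))
  pos_a <- t(vapply(model_a$atoms, function(x) x$position, numeric(3)))
  pos_b <- t(vapply(model_b$atoms, function(x) x$position, numeric(3)))
  lab_a <- vapply(model_a$atoms, function(x) x$label, character(1))
  lab_b <- vapply(model_b$atoms, function(x) x$label, character(1))
  if (length(intersect(lab_a, lab_b))) {
    stop("models share atom identities: ",
         paste(utils::head(intersect(lab_a, lab_b), 3), collapse = ", "))
  }
  na <- nrow(pos_a); nb <- nrow(pos_b)
  rows <- vector("list", na * nb)
  k <- 0
  for (i in seq_len(na)) {
    a <- model_a$atoms[[i]]
    d <- sqrt(colSums((t(pos_b) - pos_a[i, ])^2))
    for (j in seq_len(nb)) {
      b <- model_b$atoms[[j]]
      e_mm <- .H2KCAL(.mm_pair_energy_au(a, b, max_l = max_l))
      if (d[j] <= quad$rcrit) {
        e_used <- .H2KCAL(.ep_pair_energy_au(a, b, quad))
        method <- "EP"
      } else {
        e_used <- e_mm
        method <- "MM"
      }
      k <- k + 1
      rows[[k]] <- data.frame(atom_a = lab_a[i], atom_b = lab_b[j],
                              distance = d[j], method = method,
                              e_mm = e_mm, e_epmm = e_used)
    }
  }
  pb <- do.call(rbind, rows)
  out <- structure(list(e_mm = sum(pb$e_mm), e_epmm = sum(pb$e_epmm),
                        e_pen = sum(pb$e_epmm) - sum(pb$e_mm),
                        pair_breakdown = if (breakdown) pb else NULL,
                        quad = quad),
                   class = "interaction_energy")
  out
}

#' @export
print.interaction_energy <- function(x, ...) {
  cat(sprintf("Electrostatic interaction energy (kcal/mol):\n"))
  cat(sprintf("  E_MM   = %10.4f\n", x$e_mm))
  cat(sprintf("  E_EPMM = %10.4f\n", x$e_epmm))
  cat(sprintf("  E_pen  = %10.4f\n", x$e_pen))
  if (!is.null(x$pair_breakdown)) {
    cat("  pairs:", nrow(x$pair_breakdown), "(",
        sum(x$pair_breakdown$method == "EP"), "EP /",
        sum(x$pair_breakdown$method == "MM"), "MM )\n")
  }
  invisible(x)
}

# --- point-charge Coulomb energy --------------------------------------------

#' Point-charge set
#'
#' @param charges Numeric vector of partial charges (e).
#' @param positions n x 3 matrix of coordinates (angstrom).
#' @return Object of class `point_charge_set`.
#' @export
point_charge_set <- function(charges, positions) {
  positions <- as.matrix(positions)
  if (length(charges) != nrow(positions)) {
    stop("one charge per coordinate row required")
  }
  if (any(!is.finite(charges)) || any(!is.finite(positions))) {
    stop("charges and positions must be finite")
  }
  structure(list(charges = as.numeric(charges), positions = positions),
            class = "point_charge_set")
}

#' Coulomb energy of two point-charge sets
#'
#' \eqn{E = k \sum_{ij} q_i q_j / r_{ij}} with
#' \eqn{k = 332.0637} kcal A / (mol e^2), the point-charge comparison mode
#' used for force-field partial charges.
#'
#' @param a,b [point_charge_set()] objects (disjoint atoms).
#' @return Energy in kcal/mol.
#' @export
point_charge_energy <- function(a, b) {
  stopifnot(inherits(a, "point_charge_set"), inherits(b, "point_charge_set"))
  d <- sqrt(outer(rowSums(a$positions^2), rowSums(b$positions^2), `+`) -
              2 * a$positions %*% t(b$positions))
  if (any(d < 1e-8)) stop("zero interatomic distance in point-charge energy")
  epmm_constants$coulomb_kcal * sum(outer(a$charges, b$charges) / d)
}
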