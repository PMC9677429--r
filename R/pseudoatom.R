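# The Hansen-Coppens pseudoatom: parameters, positioned atoms, continuous
# density evaluation, analytic electrostatic potentials and multipole moments.
#
# The pseudoatom density is
#   rho(r) = P_core rho_core(r) + P_val kappa^3 rho_val(kappa r)
#          + sum_l kappa'^3 R_l(kappa' r) sum_m P_lm d_lm(theta, phi)
# with rho_core/rho_val per-electron spherical densities from the atomic
# wavefunction table, R_l density-normalized single-zeta Slater radial
# functions and d_lm density-normalized real spherical harmonics evaluated
# in the atom-local frame.

#' Pseudoatom multipole parameters
#'
#' @param element Chemical element symbol.
#' @param P_core Core population (electrons); must equal the number of core
#'   electrons of the element's wavefunction entry.
#' @param P_val Valence population (electrons).
#' @param kappa,kappa_prime Expansion-contraction parameters for the valence
#'   and deformation densities (physically sane range 0.5 to 2).
#' @param P_lm Named numeric vector of multipole populations, names of the
#'   form `"l,m"` (e.g. `c("1,0" = 0.15)`); orders up to l = 4.
#' @param zeta Slater exponent of the deformation radial functions (1/Bohr).
#' @param n_l Integer vector of radial powers n(l) for l = 0..4; requires
#'   n(l) >= l.
#' @param frame_rule Local-frame rule: `"ZX"` (z to the first frame neighbor,
#'   x orthogonalized to the second), `"BISECT_Z"` (z along the bisector of
#'   the first two neighbors, for symmetric environments such as water
#'   oxygen) or `"NONE"`.
#' @return Object of class `pseudoatom_params`.
#' @export
pseudoatom_parameters <- function(element, P_core, P_val, kappa = 1,
                                  kappa_prime = 1, P_lm = numeric(0),
                                  zeta = 1, n_l = c(2L, 2L, 2L, 3L, 4L),
                                  frame_rule = "ZX") {
  if (kappa <= 0.5 || kappa >= 2 || kappa_prime <= 0.5 || kappa_prime >= 2) {
    stop("kappa and kappa_prime must lie in (0.5, 2)")
  }
  if (zeta <= 0) stop("zeta must be positive")
  n_l <- as.integer(n_l)
  if (length(n_l) != 5 || any(n_l < 0:4)) {
    stop("n_l must give n(l) >= l for l = 0..4")
  }
  if (length(P_lm)) {
    lm <- .parse_lm_names(names(P_lm))
    if (any(lm[, 1] > 4)) stop("multipole populations limited to l <= 4")
  }
  structure(list(element = toupper(element), P_core = P_core, P_val = P_val,
                 kappa = kappa, kappa_prime = kappa_prime,
                 P_lm = P_lm, zeta = zeta, n_l = n_l,
                 frame_rule = frame_rule),
            class = "pseudoatom_params")
}

.parse_lm_names <- function(nm) {
  if (is.null(nm) || any(!grepl("^-?[0-9]+,-?[0-9]+$", nm))) {
    stop("P_lm names must have the form 'l,m'")
  }
  t(vapply(strsplit(nm, ","), function(x) as.integer(x), integer(2)))
}

#' Construct a positioned pseudoatom
#'
#' Precomputes, in atomic units, the spherical primitive expansion, the
#' deformation terms and the local-frame multipole potential coefficients
#' used by the density, potential and energy routines.
#'
#' @param params A [pseudoatom_parameters()] object.
#' @param position Cartesian coordinates in angstrom (length 3).
#' @param label Atom label (name + residue identity).
#' @param frame 3x3 rotation matrix whose columns are the local x, y, z axes
#'   expressed in global coordinates, or `NULL` when the atom carries no
#'   aspherical terms.
#' @param wf Wavefunction table (defaults to the packaged one).
#' @return Object of class `pseudoatom`.
#' @export
pseudoatom <- function(params, position, label = params$element,
                       frame = NULL, wf = default_wavefunctions()) {
  stopifnot(inherits(params, "pseudoatom_params"))
  position <- as.numeric(position)
  if (length(position) != 3 || any(!is.finite(position))) {
    stop("position must be 3 finite coordinates (angstrom)")
  }
  el <- params$element
  Z <- .Z_for(el)
  n_core <- .wf_electrons(wf, el, "core")
  if (abs(params$P_core - n_core) > 1e-9) {
    stop("P_core (", params$P_core, ") must equal the core electron count (",
         n_core, ") for ", el)
  }
  # spherical primitives: core + kappa-scaled valence, populations folded in
  core <- .wf_density_prims(wf, el, "core")
  val <- .wf_density_prims(wf, el, "valence")
  k <- params$kappa
  sph <- rbind(
    if (nrow(core)) transform(core, c0 = c0 * params$P_core),
    if (nrow(val)) data.frame(c0 = val$c0 * params$P_val * k^(val$m + 3),
                              m = val$m, a = val$a * k)
  )
  if (is.null(sph)) sph <- data.frame(c0 = numeric(), m = numeric(), a = numeric())
  sph <- sph[sph$c0 != 0, , drop = FALSE]

  # deformation terms grouped by l
  def <- list()
  has_aspherical <- FALSE
  if (length(params$P_lm)) {
    lm <- .parse_lm_names(names(params$P_lm))
    kp <- params$kappa_prime
    for (l in sort(unique(lm[, 1]))) {
      sel <- lm[, 1] == l
      n <- params$n_l[l + 1]
      Nl <- params$zeta^(n + 3) / factorial(n + 2)
      prim <- list(c0 = kp^(3 + n) * Nl, m = n, a = params$zeta * kp)
      ms <- lm[sel, 2]
      pv <- unname(params$P_lm[sel])
      keep <- pv != 0
      if (!any(keep)) next
      if (l >= 1) has_aspherical <- TRUE
      def[[length(def) + 1]] <- list(
        l = l, prim = prim, m = ms[keep], P = pv[keep],
        clm = vapply(ms[keep], function(m) density_norm_constant(l, m),
                     numeric(1)))
    }
  }
  if (has_aspherical && is.null(frame)) {
    stop("unresolved local frame for atom '", label,
         "' with aspherical populations (l >= 1)")
  }
  if (is.null(frame)) frame <- diag(3)
  frame <- as.matrix(frame)
  if (max(abs(crossprod(frame) - diag(3))) > 1e-8) {
    stop("frame must be an orthonormal 3x3 matrix")
  }

  at <- structure(list(params = params, position = position, label = label,
                       frame = frame, Z = Z, sph_prims = sph,
                       def_terms = def),
                  class = "pseudoatom")
  at$M_local <- .atom_moment_coefficients(at)
  at
}

# net atomic charge (e): Z - P_core - P_val - P_00
.atom_charge <- function(atom) {
  p <- atom$params
  p00 <- if (!is.null(names(p$P_lm)) && "0,0" %in% names(p$P_lm)) {
    unname(p$P_lm["0,0"])
  } else 0
  atom$Z - p$P_core - p$P_val - p00
}

# local-frame potential coefficients M_lm (a.u.): far-field potential is
# V(r) = sum_lm M_lm y_lm(Omega_local) / r^(l+1)
.atom_moment_coefficients <- function(atom) {
  lm <- .lm_pairs(4)
  M <- numeric(nrow(lm))
  names(M) <- paste(lm[, 1], lm[, 2], sep = ",")
  M["0,0"] <- sqrt(4 * pi) * .atom_charge(atom)
  for (d in atom$def_terms) {
    if (d$l == 0) next  # folded into the monopole
    rl <- .prim_rl_moment(d$prim$c0, d$prim$m, d$prim$a, d$l)
    for (i in seq_along(d$m)) {
      key <- paste(d$l, d$m[i], sep = ",")
      # electrons carry negative charge
      M[key] <- M[key] - d$P[i] * d$clm[i] * 4 * pi / (2 * d$l + 1) * rl
    }
  }
  M
}

# displacement geometry helper: points (n x 3, Bohr, global) relative to atom
.atom_geometry <- function(atom, points_bohr) {
  if (is.null(dim(points_bohr))) points_bohr <- matrix(points_bohr, ncol = 3)
  d <- sweep(points_bohr, 2, .A2B(atom$position))
  r <- sqrt(rowSums(d^2))
  u <- d / pmax(r, 1e-300)
  u_loc <- u %*% atom$frame   # t(frame) %*% u, rowwise
  list(r = r, u_loc = u_loc)
}

#' Evaluate the pseudoatom electron density
#'
#' Returns the continuous electron density (e/Bohr^3) of one pseudoatom at
#' arbitrary points, i.e. the core, kappa-scaled valence and aspherical
#' deformation terms of the multipole model evaluated in the atom-local
#' frame.
#'
#' @param atom A [pseudoatom()].
#' @param points Evaluation points in angstrom: length-3 vector or n x 3
#'   matrix.
#' @return Numeric vector of densities (e/Bohr^3).
#' @export
evaluate_density <- function(atom, points) {
  stopifnot(inherits(atom, "pseudoatom"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points))) stop("evaluation points must be finite")
  g <- .atom_geometry(atom, .A2B(points))
  rho <- .prim_density(g$r, atom$sph_prims)
  for (d in atom$def_terms) {
    radial <- d$prim$c0 * g$r^d$prim$m * exp(-d$prim$a * g$r)
    ang <- numeric(length(g$r))
    for (i in seq_along(d$m)) {
      ang <- ang + d$P[i] * d$clm[i] * real_sph_harm(d$l, d$m[i], g$u_loc)
    }
    rho <- rho + radial * ang
  }
  rho
}

# Analytic electrostatic potential (a.u., e/Bohr) of the electron density
# alone (positive number for positive density) at points in Bohr.
.atom_potential_electrons <- function(atom, points_bohr) {
  g <- .atom_geometry(atom, points_bohr)
  v <- .prim_table_potential(g$r, atom$sph_prims)
  for (d in atom$def_terms) {
    radial <- .prim_potential_l(g$r, d$prim$c0, d$prim$m, d$prim$a, d$l)
    ang <- numeric(length(g$r))
    for (i in seq_along(d$m)) {
      ang <- ang + d$P[i] * d$clm[i] * real_sph_harm(d$l, d$m[i], g$u_loc)
    }
    v <- v + radial * ang
  }
  v
}

# Exact analytic electrostatic potential (a.u., e/Bohr) of the full
# pseudoatom charge density (nucleus minus electrons) at points in Bohr.
.atom_potential_exact <- function(atom, points_bohr) {
  if (is.null(dim(points_bohr))) points_bohr <- matrix(points_bohr, ncol = 3)
  d <- sweep(points_bohr, 2, .A2B(atom$position))
  r <- sqrt(rowSums(d^2))
  atom$Z / pmax(r, 1e-12) - .atom_potential_electrons(atom, points_bohr)
}

# Multipolar (point-multipole) potential of the atom, truncated at max_l.
.atom_potential_multipole <- function(atom, points_bohr, max_l = 4) {
  g <- .atom_geometry(atom, points_bohr)
  lm <- .lm_pairs(max_l)
  v <- numeric(length(g$r))
  for (k in seq_len(nrow(lm))) {
    key <- paste(lm[k, 1], lm[k, 2], sep = ",")
    M <- atom$M_local[key]
    if (M == 0) next
    v <- v + M * real_sph_harm(lm[k, 1], lm[k, 2], g$u_loc) /
      g$r^(lm[k, 1] + 1)
  }
  v
}

#' Atomic spherical multipole moments
#'
#' Moments of the total pseudoatom charge density (nucleus minus electrons)
#' about the atom center, in the real spherical-tensor convention in which
#' the far-field potential is
#' \eqn{V = \sum_{lm} Q_{lm} \sqrt{4\pi/(2l+1)}\, y_{lm}\, r^{-(l+1)}}.
#' The monopole equals the net atomic charge \eqn{Z - P_{core} - P_{val}}
#' (minus \eqn{P_{00}} when present); moments with \eqn{l \ge 1} are linear
#' in the multipole populations with radial expectation values
#' \eqn{\langle r^l \rangle} of the deformation radial functions.
#'
#' @param atom A [pseudoatom()].
#' @param max_l Highest order to report (<= 4).
#' @param frame `"global"` (default) or `"local"`.
#' @return Named vector of moments in e angstrom^l, names `"l,m"`.
#' @export
atomic_multipole_moments <- function(atom, max_l = 4, frame = "global") {
  stopifnot(inherits(atom, "pseudoatom"), max_l <= 4)
  M <- atom$M_local
  lm <- .lm_pairs(max_l)
  keys <- paste(lm[, 1], lm[, 2], sep = ",")
  M <- M[keys]
  if (frame == "global") {
    out <- M
    for (l in 1:max_l) {
      if (max_l < 1) break
      sel <- lm[, 1] == l
      if (!any(M[sel] != 0)) next
      D <- .real_harmonic_rotation(l, atom$frame)
      out[sel] <- as.numeric(D %*% M[sel])
    }
    M <- out
  } else if (frame != "local") stop("frame must be 'global' or 'local'")
  # convert potential coefficients to Racah-style moments in e A^l
  Q <- M / sqrt(4 * pi / (2 * lm[, 1] + 1)) * epmm_constants$bohr_A^lm[, 1]
  names(Q) <- keys
  Q
}

# Rotation matrix D^l for real spherical harmonics: y_lm(R u) = sum_m' D[m,m'] y_lm'(u).
# Computed exactly (for polynomial degree <= 2l) by angular quadrature.
.real_harmonic_rotation <- function(l, R) {
  grid <- angular_grid(194)
  u <- grid$points
  Ru <- u %*% t(R)
  ms <- seq(-l, l)
  Yl <- sapply(ms, function(m) real_sph_harm(l, m, u))
  YRl <- sapply(ms, function(m) real_sph_harm(l, m, Ru))
  t(YRl) %*% (Yl * grid$weights)
}

#' Molecular density model
#'
#' An ordered collection of positioned pseudoatoms forming a continuous
#' molecular charge distribution.
#'
#' @param atoms List of [pseudoatom()] objects.
#' @param meta Optional named list of provenance metadata.
#' @return Object of class `density_model`.
#' @export
density_model <- function(atoms, meta = list()) {
  stopifnot(all(vapply(atoms, inherits, logical(1), "pseudoatom")))
  structure(list(atoms = atoms, meta = meta), class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("Molecular density model:", length(x$atoms), "pseudoatoms, charge",
      sprintf("%+.4f e", molecular_charge(x)), "\n")
  invisible(x)
}

#' Total modeled charge of a density model
#'
#' Sum of atomic monopoles \eqn{Z - P_{core} - P_{val} - P_{00}}.
#'
#' @param model A [density_model()].
#' @return Charge in e.
#' @export
molecular_charge <- function(model) {
  stopifnot(inherits(model, "density_model"))
  if (!length(model$atoms)) return(0)
  sum(vapply(model$atoms, .atom_charge, numeric(1)))
}

# subset a model by atom indices, keeping metadata
.model_subset <- function(model, idx) {
  out <- model
  out$atoms <- model$atoms[idx]
  out
}

#' Evaluate the total model electron density
#'
#' @param model A [density_model()].
#' @param points n x 3 matrix of points (angstrom).
#' @param cutoff Per-atom evaluation cutoff in angstrom (atom contributions
#'   beyond it are negligible and skipped).
#' @return Vector of densities (e/Bohr^3).
#' @export
model_density <- function(model, points, cutoff = 8) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rho <- numeric(nrow(points))
  for (at in model$atoms) {
    d2 <- (points[, 1] - at$position[1])^2 +
      (points[, 2] - at$position[2])^2 + (points[, 3] - at$position[3])^2
    sel <- d2 <= cutoff^2
    if (!any(sel)) next
    rho[sel] <- rho[sel] + evaluate_density(at, points[sel, , drop = FALSE])
  }
  rho
}
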