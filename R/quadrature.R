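# Numerical integration grids: the angular-grid ladder on the sphere and the
# mapped Gauss-Chebyshev radial grid used for exact-potential integrations.

# Supported angular grid sizes (requested -> n_theta x n_phi product rule).
# Gauss-Legendre nodes in cos(theta), uniform trapezoid in phi; the rule is
# exact for spherical polynomials up to degree min(2*n_theta - 1, n_phi - 1).
.angular_ladder <- list(
  `26`  = c(4, 7),
  `50`  = c(5, 10),
  `110` = c(7, 16),
  `194` = c(10, 20),
  `302` = c(12, 25),
  `434` = c(15, 29),
  `590` = c(17, 35),
  `974` = c(22, 44)
)

#' Angular quadrature grid on the unit sphere
#'
#' Returns a product Gauss-Legendre (polar) x uniform (azimuthal) grid whose
#' size approximates the requested point count. Only the ladder sizes
#' 26, 50, 110, 194, 302, 434, 590 and 974 are supported; the actual point
#' count may differ slightly from the nominal one.
#'
#' @param n_angular Nominal grid size (one of the ladder values).
#' @return List with `points` (n x 3 unit vectors) and `weights`
#'   (summing to \eqn{4\pi}).
#' @export
angular_grid <- function(n_angular) {
  key <- as.character(n_angular)
  if (!key %in% names(.angular_ladder)) {
    stop("n_angular must be one of the supported ladder sizes: ",
         paste(names(.angular_ladder), collapse = ", "))
  }
  ck <- paste0("ang_", key)
  if (!is.null(.epmm_cache[[ck]])) return(.epmm_cache[[ck]])
  nt <- .angular_ladder[[key]][1]
  np <- .angular_ladder[[key]][2]
  gl <- pracma::gaussLegendre(nt, -1, 1)
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(np) - 1) / np
  pts <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = np)
  )
  w <- rep(gl$w, times = np) * (2 * pi / np)
  out <- list(points = pts, weights = w)
  .epmm_cache[[ck]] <- out
  out
}

#' Mapped Gauss-Chebyshev radial quadrature
#'
#' Gauss-Chebyshev (second kind) nodes mapped onto \eqn{[0, \infty)} with the
#' rational map \eqn{r = r_m (1 + x)/(1 - x)} commonly used for atom-centered
#' molecular integration. Weights include the Jacobian and the \eqn{r^2}
#' volume factor, so \eqn{\int_0^\infty g(r) r^2 dr \approx \sum w_i g(r_i)}.
#'
#' @param n_radial Number of radial points (>= 20).
#' @param r_m Map midpoint in Bohr (element-dependent scale).
#' @return List with `r` (Bohr) and `weights`.
#' @export
radial_grid <- function(n_radial, r_m = 1.0) {
  if (n_radial < 20) stop("n_radial must be at least 20")
  ck <- paste0("rad_", n_radial, "_", r_m)
  if (!is.null(.epmm_cache[[ck]])) return(.epmm_cache[[ck]])
  i <- seq_len(n_radial)
  th <- i * pi / (n_radial + 1)
  x <- cos(th)
  # plain-integration weights of GC2 nodes: pi/(n+1) * sin(theta)
  wx <- pi / (n_radial + 1) * sin(th)
  r <- r_m * (1 + x) / (1 - x)
  drdx <- 2 * r_m / (1 - x)^2
  out <- list(r = r, weights = wx * drdx * r^2)
  .epmm_cache[[ck]] <- out
  out
}

# per-element radial map midpoints (Bohr), loosely half Bragg-Slater radii
.radial_rm <- c(H = 0.8, C = 1.3, N = 1.2, O = 1.1, F = 1.0, P = 1.9,
                S = 1.8, CL = 1.7, MG = 1.4, "NA" = 1.7, K = 2.1)

.rm_for_element <- function(element) {
  r <- .radial_rm[toupper(element)]
  if (is.na(r)) 1.3 else unname(r)
}

#' Quadrature specification for exact-potential integrations
#'
#' Bundles the radial and angular grid sizes and the exact-potential zone
#' radius used by the hybrid energy scheme. Defaults follow common practice
#' for databank electrostatics: 99 radial points, a 590-point angular grid
#' and a 5 angstrom exact-potential zone.
#'
#' @param n_radial Radial points per atom (>= 20).
#' @param n_angular Angular grid size from the supported ladder.
#' @param rcrit Exact-potential zone radius in angstrom; atom pairs separated
#'   by more than this use the multipole-moment energy.
#' @param scheme_id Opaque identifier of the integration scheme recorded in
#'   run manifests.
#' @return Object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(n_radial = 99, n_angular = 590, rcrit = 5,
                            scheme_id = "gc2-becke/gl-product") {
  if (rcrit <= 0) stop("rcrit must be positive")
  if (n_radial < 20) stop("n_radial must be at least 20")
  if (!as.character(n_angular) %in% names(.angular_ladder)) {
    stop("n_angular must be on the supported ladder: ",
         paste(names(.angular_ladder), collapse = ", "))
  }
  structure(list(n_radial = as.integer(n_radial),
                 n_angular = as.integer(n_angular),
                 rcrit = rcrit, scheme_id = scheme_id),
            class = "quadrature_spec")
}

#' @export
print.quadrature_spec <- function(x, ...) {
  cat("Quadrature spec: Nrad =", x$n_radial, ", Nang =", x$n_angular,
      ", rcrit =", x$rcrit, "A, scheme =", x$scheme_id, "\n")
  invisible(x)
}
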