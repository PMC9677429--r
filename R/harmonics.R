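# Real spherical harmonics l = 0..4 and the density-normalization constants
# of the Hansen-Coppens multipole formalism.

#' Real spherical harmonics up to l = 4
#'
#' Evaluates the orthonormal real spherical harmonic \eqn{y_{lm}} (so that
#' \eqn{\int y_{lm}^2 d\Omega = 1}) at unit direction vectors. The Cartesian
#' polynomial forms are used; \code{m > 0} are the cosine-type and
#' \code{m < 0} the sine-type combinations.
#'
#' @param l Integer order, 0 to 4.
#' @param m Integer, -l to l.
#' @param u Numeric matrix (n x 3) of unit vectors (or a length-3 vector).
#' @return Numeric vector of length n.
#' @export
real_sph_harm <- function(l, m, u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  stopifnot(l >= 0, l <= 4, abs(m) <= l)
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  key <- paste0(l, ",", m)
  switch(key,
    "0,0"  = rep(0.5 * sqrt(1 / pi), length(x)),
    "1,-1" = sqrt(3 / (4 * pi)) * y,
    "1,0"  = sqrt(3 / (4 * pi)) * z,
    "1,1"  = sqrt(3 / (4 * pi)) * x,
    "2,-2" = 0.5 * sqrt(15 / pi) * x * y,
    "2,-1" = 0.5 * sqrt(15 / pi) * y * z,
    "2,0"  = 0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
    "2,1"  = 0.5 * sqrt(15 / pi) * x * z,
    "2,2"  = 0.25 * sqrt(15 / pi) * (x^2 - y^2),
    "3,-3" = 0.25 * sqrt(35 / (2 * pi)) * y * (3 * x^2 - y^2),
    "3,-2" = 0.5 * sqrt(105 / pi) * x * y * z,
    "3,-1" = 0.25 * sqrt(21 / (2 * pi)) * y * (5 * z^2 - 1),
    "3,0"  = 0.25 * sqrt(7 / pi) * (5 * z^3 - 3 * z),
    "3,1"  = 0.25 * sqrt(21 / (2 * pi)) * x * (5 * z^2 - 1),
    "3,2"  = 0.25 * sqrt(105 / pi) * z * (x^2 - y^2),
    "3,3"  = 0.25 * sqrt(35 / (2 * pi)) * x * (x^2 - 3 * y^2),
    "4,-4" = 0.75 * sqrt(35 / pi) * x * y * (x^2 - y^2),
    "4,-3" = 0.75 * sqrt(35 / (2 * pi)) * y * z * (3 * x^2 - y^2),
    "4,-2" = 0.75 * sqrt(5 / pi) * x * y * (7 * z^2 - 1),
    "4,-1" = 0.75 * sqrt(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
    "4,0"  = (3 / 16) * sqrt(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
    "4,1"  = 0.75 * sqrt(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
    "4,2"  = (3 / 8) * sqrt(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
    "4,3"  = 0.75 * sqrt(35 / (2 * pi)) * x * z * (x^2 - 3 * y^2),
    "4,4"  = (3 / 16) * sqrt(35 / pi) * (x^4 - 6 * x^2 * y^2 + y^4),
    stop("unsupported (l, m): ", key)
  )
}

#' Density-normalization constants of the multipole formalism
#'
#' The aspherical deformation functions \eqn{d_{lm}} of the pseudoatom model
#' are density-normalized: \eqn{\int |d_{lm}| d\Omega = 2} for \eqn{l \ge 1}
#' (a population \eqn{P_{lm} = 1} shifts one electron from the negative to
#' the positive lobe) and \eqn{\int d_{00} d\Omega = 1}. This returns the
#' proportionality constant \eqn{c_{lm}} with
#' \eqn{d_{lm} = c_{lm}\, y_{lm}} for the orthonormal harmonic
#' \eqn{y_{lm}}. Values are computed once by adaptive quadrature of
#' \eqn{\int |y_{lm}| d\Omega} and cached.
#'
#' @param l,m Integers as in [real_sph_harm()].
#' @return Scalar \eqn{c_{lm}}.
#' @export
density_norm_constant <- function(l, m) {
  key <- paste0("clm_", l, "_", m)
  if (!is.null(.epmm_cache[[key]])) return(.epmm_cache[[key]])
  val <- if (l == 0) {
    1 / sqrt(4 * pi)               # d00 = 1/(4 pi)
  } else {
    # |y_lm| factorizes: |Theta(theta)| * |cos(m phi)| (or |sin|);
    # integral over phi is 4 for m != 0 and 2*pi for m = 0.
    phi0 <- if (m >= 0) 0 else pi / (2 * abs(m))
    theta_part <- function(th) {
      u <- cbind(sin(th) * cos(phi0), sin(th) * sin(phi0), cos(th))
      abs(real_sph_harm(l, m, u)) * sin(th)
    }
    it <- stats::integrate(theta_part, 0, pi, rel.tol = 1e-12,
                           subdivisions = 500L)
    phi_int <- if (m == 0) 2 * pi else 4
    2 / (it$value * phi_int)
  }
  .epmm_cache[[key]] <- val
  val
}

# all (l, m) pairs up to max_l as a 2-column matrix
.lm_pairs <- function(max_l) {
  do.call(rbind, lapply(0:max_l, function(l) cbind(l, seq(-l, l))))
}

# matrix of y_lm values: rows = points, cols = lm pairs
.ylm_matrix <- function(u, lm) {
  out <- matrix(0, nrow = nrow(u), ncol = nrow(lm))
  for (k in seq_len(nrow(lm))) out[, k] <- real_sph_harm(lm[k, 1], lm[k, 2], u)
  out
}
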