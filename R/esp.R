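# Electrostatic potential and electron density on cubic grids, iso-density
# masking and Gaussian cube output.

#' Cubic grid specification
#'
#' @param center Grid center, angstrom.
#' @param extent Box edge length(s), angstrom (scalar or length 3);
#'   `extent/voxel` must be integer.
#' @param voxel Voxel spacing, angstrom.
#' @return Object of class `grid_spec` with voxel center coordinates along
#'   each axis.
#' @export
grid_spec <- function(center, extent, voxel) {
  if (voxel <= 0) stop("voxel must be positive")
  extent <- rep(as.numeric(extent), length.out = 3)
  dims <- extent / voxel
  if (max(abs(dims - round(dims))) > 1e-9) {
    stop("extent/voxel must yield integer grid dimensions")
  }
  dims <- as.integer(round(dims))
  if (prod(dims) > 2e8) {
    warning("very large grid (", paste(dims, collapse = "x"),
            " voxels); consider a coarser voxel size")
  }
  axes <- lapply(1:3, function(k) {
    center[k] - extent[k] / 2 + voxel * (seq_len(dims[k]) - 0.5)
  })
  structure(list(center = center, extent = extent, voxel = voxel,
                 dims = dims, axes = axes),
            class = "grid_spec")
}

# all voxel centers as an n x 3 matrix (x fastest)
.grid_points <- function(grid) {
  d <- grid$dims
  cbind(rep(grid$axes[[1]], times = d[2] * d[3]),
        rep(rep(grid$axes[[2]], each = d[1]), times = d[3]),
        rep(grid$axes[[3]], each = d[1] * d[2]))
}

#' Electrostatic potential on a cubic grid
#'
#' Total electrostatic potential (nuclei plus continuous electron density,
#' atomic units e/Bohr) of a density model at every voxel: the analytic
#' exact potential is used for voxels within `rcrit` of an atom and its
#' point-multipole far field beyond. Voxels closer than `cap_radius` to a
#' nucleus are capped at the potential value on that radius and flagged.
#'
#' @param model A [density_model()].
#' @param grid A [grid_spec()].
#' @param rcrit Exact/multipole switch radius per atom, angstrom.
#' @param max_l Far-field multipole order.
#' @param cap_radius Nuclear capping radius, angstrom.
#' @return 3D array (dims of the grid) with attributes `grid` and
#'   `capped_voxels` (indices).
#' @export
esp_on_grid <- function(model, grid, rcrit = 5, max_l = 4,
                        cap_radius = 0.1) {
  pts <- .grid_points(grid)
  ptsb <- .A2B(pts)
  v <- numeric(nrow(pts))
  capped <- logical(nrow(pts))
  for (at in model$atoms) {
    d <- sqrt((pts[, 1] - at$position[1])^2 + (pts[, 2] - at$position[2])^2 +
                (pts[, 3] - at$position[3])^2)
    near <- d <= rcrit
    hot <- d < cap_radius
    if (any(hot)) {
      capped <- capped | hot
      # evaluate at the cap radius instead of the singular point
      shift <- ptsb[hot, , drop = FALSE]
      dirs <- shift - matrix(.A2B(at$position), sum(hot), 3, byrow = TRUE)
      nrm <- sqrt(rowSums(dirs^2))
      onnuc <- which(nrm < 1e-12)
      if (length(onnuc)) {
        dirs[onnuc, ] <- matrix(c(1, 0, 0), length(onnuc), 3, byrow = TRUE)
        nrm[onnuc] <- 1
      }
      shift <- matrix(.A2B(at$position), sum(hot), 3, byrow = TRUE) +
        dirs / nrm * .A2B(cap_radius)
      v[hot] <- v[hot] + .atom_potential_exact(at, shift)
    }
    sel <- near & !hot
    if (any(sel)) {
      v[sel] <- v[sel] + .atom_potential_exact(at, ptsb[sel, , drop = FALSE])
    }
    if (any(!near)) {
      v[!near] <- v[!near] +
        .atom_potential_multipole(at, ptsb[!near, , drop = FALSE], max_l)
    }
  }
  out <- array(v, dim = grid$dims)
  attr(out, "grid") <- grid
  attr(out, "capped_voxels") <- which(capped)
  out
}

#' Electron density on a cubic grid
#'
#' @inheritParams esp_on_grid
#' @param cutoff Per-atom density evaluation cutoff, angstrom.
#' @return 3D array of densities (e/Bohr^3) with attribute `grid`.
#' @export
density_on_grid <- function(model, grid, cutoff = 8) {
  pts <- .grid_points(grid)
  rho <- model_density(model, pts, cutoff = cutoff)
  out <- array(rho, dim = grid$dims)
  attr(out, "grid") <- grid
  out
}

#' Iso-density voxel mask
#'
#' Boolean mask of voxels with electron density at or above `level`
#' (conventionally 0.002 e/Bohr^3 for a molecular envelope). Surface voxels
#' are the mask members with at least one of their 6 axis neighbors outside
#' the mask.
#'
#' @param model A [density_model()].
#' @param grid A [grid_spec()].
#' @param level Iso level in e/Bohr^3 (> 0).
#' @param density Optional precomputed [density_on_grid()] array.
#' @return Logical 3D array with attributes `grid` and `surface` (logical
#'   array of surface voxels).
#' @export
isodensity_mask <- function(model, grid, level = 0.002, density = NULL) {
  if (level <= 0) stop("iso level must be positive")
  if (is.null(density)) density <- density_on_grid(model, grid)
  mask <- density >= level
  d <- dim(mask)
  surf <- array(FALSE, d)
  if (any(mask)) {
    pad <- function(shift_dim, shift) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      n <- d[shift_dim]
      if (shift == 1) {
        idx_dst[[shift_dim]] <- 2:n
        idx_src[[shift_dim]] <- 1:(n - 1)
      } else {
        idx_dst[[shift_dim]] <- 1:(n - 1)
        idx_src[[shift_dim]] <- 2:n
      }
      out <- do.call(`[<-`, c(list(out), idx_dst,
                              list(do.call(`[`, c(list(mask), idx_src)))))
      out
    }
    inside6 <- array(TRUE, d)
    for (k in 1:3) for (s in c(1, -1)) {
      nb <- pad(k, s)
      inside6 <- inside6 & nb
    }
    # boundary voxels of the array count as surface
    surf <- mask & !inside6
  }
  attr(mask, "grid") <- grid
  attr(mask, "surface") <- surf
  mask
}

#' Write a volumetric array as a Gaussian cube file
#'
#' Standard cube format with the Bohr header convention; voxel values are
#' written in the conventional z-fastest order.
#'
#' @param values 3D array from [esp_on_grid()], [density_on_grid()] or
#'   [isodensity_mask()] (logical masks are written as 0/1).
#' @param path Output path.
#' @param model Optional [density_model()] whose atoms are listed in the
#'   header.
#' @param comment Header comment lines (length 2).
#' @export
write_cube <- function(values, path, model = NULL,
                       comment = c("epmm volumetric data", "")) {
  grid <- attr(values, "grid")
  if (is.null(grid)) stop("values must carry a 'grid' attribute")
  v <- values
  if (is.logical(v)) v <- v + 0
  d <- dim(v)
  org <- .A2B(vapply(1:3, function(k) grid$axes[[k]][1], numeric(1)))
  step <- .A2B(grid$voxel)
  atoms <- if (is.null(model)) list() else model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", length(atoms),
                     org[1], org[2], org[3]), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[1], step, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, step, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, step), con)
  for (at in atoms) {
    p <- .A2B(at$position)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", at$Z,
                       .atom_charge(at), p[1], p[2], p[3]), con)
  }
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      row <- v[i, j, ]
      chunks <- split(row, ceiling(seq_along(row) / 6))
      for (ch in chunks) {
        writeLines(paste(sprintf("%13.5E", ch), collapse = " "), con)
      }
    }
  }
  invisible(path)
}
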