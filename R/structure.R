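# Macromolecular structures: PDB input/output (via bio3d), bond detection,
# neutron-distance hydrogen extension and local-frame resolution.

#' Construct a structure table
#'
#' A light tabular representation of a (protonated) macromolecular
#' structure: one row per atom with element, residue identity and
#' coordinates in angstrom. Residue identity is (chain, residue number,
#' insertion code); waters are recognized by residue name HOH/WAT.
#'
#' @param df Data frame with columns `elety` (atom name), `element`,
#'   `resid` (residue name), `chain`, `resno`, `x`, `y`, `z`; optional
#'   `insert`, `occ`, `het`.
#' @return Object of class `epmm_structure` (a data.frame).
#' @export
epmm_structure <- function(df) {
  need <- c("elety", "element", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing structure columns: ",
                         paste(miss, collapse = ", "))
  if (!"insert" %in% names(df)) df$insert <- ""
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"het" %in% names(df)) df$het <- FALSE
  df$element <- toupper(df$element)
  df$resno <- as.integer(df$resno)
  df$insert[is.na(df$insert)] <- ""
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  class(df) <- c("epmm_structure", "data.frame")
  df
}

# unique residue identifier strings
.residue_ids <- function(struct) {
  paste0(struct$chain, struct$resno, ifelse(struct$insert == "", "",
                                            paste0(".", struct$insert)))
}

.coords <- function(struct) as.matrix(struct[, c("x", "y", "z")])

#' Read a protonated structure from a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 columns) through bio3d. For
#' alternate-location atoms the highest-occupancy conformer is kept by
#' default; a specific conformer can be requested.
#'
#' @param path PDB file path.
#' @param altloc `"highest"` (default) or an explicit altloc character.
#' @return An [epmm_structure()].
#' @export
read_structure <- function(path, altloc = "highest") {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) elem[bad] <- bio3d::atom2ele(at$elety[bad])
  df <- data.frame(
    elety = trimws(at$elety), element = toupper(trimws(elem)),
    resid = trimws(at$resid), chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt)
  )
  if (any(df$alt != "")) {
    if (identical(altloc, "highest")) {
      # keep, per (residue, atom name), the highest-occupancy conformer;
      # ties resolved by altloc letter for determinism
      key <- paste(.residue_ids(epmm_structure(df)), df$elety)
      ord <- order(key, -df$occ, df$alt)
      df <- df[ord, ][!duplicated(key[ord]), ]
      df <- df[order(as.integer(rownames(df))), ]
    } else {
      df <- df[df$alt == "" | df$alt == altloc, ]
    }
  }
  df$alt <- NULL
  rownames(df) <- NULL
  epmm_structure(df)
}

#' Write a structure to a PDB file
#'
#' @param struct An [epmm_structure()].
#' @param path Output path.
#' @export
write_structure <- function(struct, path) {
  xyz <- as.vector(t(.coords(struct)))
  bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(struct$het,
                                                         "HETATM", "ATOM"),
                   resno = struct$resno, resid = struct$resid,
                   chain = struct$chain, insert = struct$insert,
                   elety = struct$elety, o = struct$occ,
                   elesy = struct$element)
  invisible(path)
}

#' Detect covalent bonds from interatomic distances
#'
#' Atoms i and j are bonded iff
#' \eqn{|r_i - r_j| \le radius(i) + radius(j) + tolerance}. A tiny override
#' radius (e.g. Mg 0.01 A) suppresses all bonds of that element; the default
#' Mg radius 1.36 A restores its coordination bonds.
#'
#' @param struct An [epmm_structure()].
#' @param radii A [covalent_radii()] table.
#' @param tolerance Distance slack in angstrom (default 0.4).
#' @return Data frame with columns `i`, `j` (row indices, i < j), `dist`.
#' @export
detect_bonds <- function(struct, radii = covalent_radii(), tolerance = 0.4) {
  xyz <- .coords(struct)
  n <- nrow(xyz)
  out <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (n < 2) return(out)
  r <- .radius_for(radii, struct$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, `+`) + tolerance
  diag(d) <- Inf
  if (any(d < 1e-4)) {
    w <- which(d < 1e-4, arr.ind = TRUE)[1, ]
    stop("clashing duplicate atoms at zero distance: rows ", w[1], " and ",
         w[2])
  }
  sel <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  data.frame(i = sel[, 1], j = sel[, 2],
             dist = d[sel])
}

# neighbor index list from a bond table
.neighbor_list <- function(n, bonds) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Default neutron X-H bond distances
#'
#' Standard neutron-diffraction X-H distances (angstrom) keyed by the heavy
#' element. User-editable; a YAML config with an `xh_distances` mapping can
#' override any entry.
#'
#' @return Named numeric vector.
#' @export
neutron_distances <- function() {
  c(C = 1.083, N = 1.009, O = 0.983, S = 1.338, B = 1.185)
}

#' Extend hydrogen positions to neutron distances
#'
#' Moves every hydrogen along its existing X-H bond direction so the bond
#' length equals the tabulated neutron distance. Heavy atoms are unmoved and
#' directions preserved.
#'
#' @param struct An [epmm_structure()].
#' @param bonds Bond table from [detect_bonds()] (computed with any metal
#'   bonds suppressed so hydrogens have a single heavy neighbor).
#' @param distances Named vector of X-H distances (angstrom) by heavy
#'   element; defaults to [neutron_distances()].
#' @return The structure with repositioned hydrogens.
#' @export
extend_hydrogens <- function(struct, bonds, distances = neutron_distances()) {
  nb <- .neighbor_list(nrow(struct), bonds)
  hyd <- which(struct$element == "H")
  for (i in hyd) {
    heavy <- setdiff(nb[[i]], which(struct$element == "H"))
    if (length(heavy) != 1) {
      stop("hydrogen '", struct$elety[i], "' in residue ",
           .residue_ids(struct)[i], " has ", length(heavy),
           " heavy neighbors (expected exactly 1)")
    }
    j <- heavy
    d <- distances[struct$element[j]]
    if (is.na(d)) stop("no neutron distance for ", struct$element[j], "-H")
    v <- c(struct$x[i] - struct$x[j], struct$y[i] - struct$y[j],
           struct$z[i] - struct$z[j])
    v <- v / sqrt(sum(v^2))
    struct$x[i] <- struct$x[j] + d * v[1]
    struct$y[i] <- struct$y[j] + d * v[2]
    struct$z[i] <- struct$z[j] + d * v[3]
  }
  struct
}

#' Assign databank atom types to structure atoms
#'
#' Each atom is mapped to the most specific matching databank entry. Match
#' specificity is: full key (element + sorted bonded-neighbor elements),
#' then element + neighbor count, then element-level fallback. Ambiguous
#' equal-specificity matches and unmatched elements are errors.
#'
#' @param struct An [epmm_structure()].
#' @param bonds Bond table from [detect_bonds()].
#' @param db A [databank()].
#' @return Character vector of entry names, one per atom.
#' @export
assign_atom_types <- function(struct, bonds, db) {
  nb <- .neighbor_list(nrow(struct), bonds)
  ents <- db$entries
  lv <- vapply(ents, function(e) e$key$level, character(1))
  el <- vapply(ents, function(e) e$key$element, character(1))
  out <- character(nrow(struct))
  unmatched <- character(0)
  for (i in seq_len(nrow(struct))) {
    e_i <- struct$element[i]
    nbe <- sort(struct$element[nb[[i]]])
    full <- which(lv == "full" & el == e_i &
                    vapply(ents, function(e) {
                      identical(e$key$neighbors, nbe)
                    }, logical(1)))
    hit <- full
    if (!length(hit)) {
      hit <- which(lv == "count" & el == e_i &
                     vapply(ents, function(e) {
                       identical(e$key$n_neighbors, length(nbe))
                     }, logical(1)))
    }
    if (!length(hit)) hit <- which(lv == "element" & el == e_i)
    if (!length(hit)) {
      unmatched <- c(unmatched, paste0(struct$elety[i], "/",
                                       .residue_ids(struct)[i]))
      next
    }
    if (length(hit) > 1) {
      stop("ambiguous atom type for ", struct$elety[i], " in ",
           .residue_ids(struct)[i], ": entries ",
           paste(names(ents)[hit], collapse = ", "))
    }
    out[i] <- names(ents)[hit]
  }
  if (length(unmatched)) {
    stop("no databank entry matches: ", paste(unmatched, collapse = ", "))
  }
  out
}

# Resolve the local frame of atom i from its bonded neighbors.
# Neighbors are ranked by (nuclear charge desc, distance asc, coordinates)
# so the result is independent of atom input order.
.resolve_frame <- function(struct, nb_idx, i, rule) {
  if (identical(rule, "NONE")) return(NULL)
  xyz <- .coords(struct)
  nbs <- nb_idx[[i]]
  if (!length(nbs)) return(NULL)
  z_nb <- vapply(struct$element[nbs], .Z_for, numeric(1))
  d_nb <- sqrt(colSums((t(xyz[nbs, , drop = FALSE]) - xyz[i, ])^2))
  ord <- order(-z_nb, round(d_nb, 6), xyz[nbs, 1], xyz[nbs, 2], xyz[nbs, 3])
  nbs <- nbs[ord]
  u1 <- xyz[nbs[1], ] - xyz[i, ]
  u1 <- u1 / sqrt(sum(u1^2))
  if (identical(rule, "BISECT_Z") && length(nbs) >= 2) {
    u2 <- xyz[nbs[2], ] - xyz[i, ]
    u2 <- u2 / sqrt(sum(u2^2))
    zax <- u1 + u2
    zax <- zax / sqrt(sum(zax^2))
    xax <- u1 - sum(u1 * zax) * zax
    xax <- xax / sqrt(sum(xax^2))
  } else {
    zax <- u1
    if (length(nbs) >= 2) {
      u2 <- xyz[nbs[2], ] - xyz[i, ]
      xax <- u2 - sum(u2 * zax) * zax
      nx <- sqrt(sum(xax^2))
      if (nx < 1e-6) xax <- .perp_vector(zax) else xax <- xax / nx
    } else {
      # terminal atom: canonical perpendicular (documented fallback)
      xax <- .perp_vector(zax)
    }
  }
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],   # y = z x x (right-handed)
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  fr <- cbind(xax, yax, zax)
  colnames(fr) <- NULL
  fr
}

# deterministic unit vector perpendicular to v
.perp_vector <- function(v) {
  a <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) {
    c(1, 0, 0)
  } else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  w <- a - sum(a * v) * v
  w / sqrt(sum(w^2))
}
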