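# Synthetic fixtures: a self-consistent fixture databank, analytic Slater
# dimers, toy protein-RNA complexes with a triphosphate-like -4 e fragment
# and a +2 e metal with coordinating waters, and an independent brute-force
# Coulomb oracle. Everything is generated in code, deterministically.

#' Build the fixture pseudoatom databank
#'
#' Entries for H, C, N, O, P, S and Mg covering the chemical environments of
#' the toy complexes (water, phosphate and triphosphate oxygens, metal-
#' coordinating oxygens, ammonium-like nitrogen, carboxylate carbon) plus
#' element-level fallbacks. Parameters are physically sane synthetic fixture
#' values self-consistent with the packaged wavefunction table; they are not
#' a published databank and no numerical agreement with one is claimed.
#' Radial powers follow the common conventions, including n(l) = 2,4,6,8 for
#' P and 6,6,6,6 for S deformation functions.
#'
#' @return A [databank()].
#' @export
make_fixture_databank <- function() {
  fr <- c(2L, 2L, 2L, 3L, 4L)   # first-row n(l)
  e <- function(el, nb, P_core, P_val, kappa, kappa_prime, zeta,
                n_l = fr, P_lm = numeric(0), frame = "ZX") {
    list(key = atom_type_key(el, nb),
         params = pseudoatom_parameters(el, P_core, P_val, kappa,
                                        kappa_prime, P_lm, zeta, n_l, frame),
         provenance = "synthetic fixture")
  }
  db <- list(
    H_O   = e("H", "O", 0, 0.66, 1.12, 1.18, 2.0, c(0L, 1L, 2L, 3L, 4L),
              c("1,0" = 0.06)),
    H_N   = e("H", "N", 0, 0.60, 1.12, 1.18, 2.0, c(0L, 1L, 2L, 3L, 4L),
              c("1,0" = 0.06)),
    H_C   = e("H", "C", 0, 0.95, 1.12, 1.18, 2.0, c(0L, 1L, 2L, 3L, 4L),
              c("1,0" = 0.05)),
    H_any = e("H", "ANY", 0, 1.00, 1.10, 1.18, 2.0, c(0L, 1L, 2L, 3L, 4L)),
    O_water = e("O", c("H", "H"), 2, 6.68, 0.975, 1.10, 2.2266, fr,
                c("1,0" = -0.06, "2,0" = 0.05), frame = "BISECT_Z"),
    O_water_mg = e("O", c("H", "H", "MG"), 2, 6.60, 0.975, 1.10, 2.2266, fr,
                   c("1,0" = 0.05)),
    O_P   = e("O", "P", 2, 6.70, 0.972, 1.10, 2.2266, fr,
              c("1,0" = 0.10, "2,0" = -0.04)),
    O_P_mg = e("O", c("MG", "P"), 2, 6.65, 0.972, 1.10, 2.2266, fr,
               c("1,0" = 0.08)),
    O_PP  = e("O", c("P", "P"), 2, 6.55, 0.975, 1.10, 2.2266, fr,
              c("1,0" = -0.04), frame = "BISECT_Z"),
    O_CP  = e("O", c("C", "P"), 2, 6.52, 0.975, 1.10, 2.2266, fr,
              c("1,0" = -0.03)),
    O_C   = e("O", "C", 2, 6.45, 0.972, 1.10, 2.2266, fr,
              c("1,0" = 0.12, "2,0" = 0.05)),
    O_CH  = e("O", c("C", "H"), 2, 6.50, 0.975, 1.10, 2.2266, fr,
              c("1,0" = 0.08)),
    O_any = e("O", "ANY", 2, 6.00, 0.98, 1.10, 2.2266, fr),
    N_CH3 = e("N", c("C", "H", "H", "H"), 2, 5.30, 0.99, 1.05, 1.9170, fr,
              c("1,0" = -0.06)),
    N_any = e("N", "ANY", 2, 5.00, 0.99, 1.05, 1.9170, fr),
    C_HHO = e("C", c("H", "H", "O"), 2, 4.03, 0.99, 0.90, 1.5679, fr,
              c("1,0" = 0.08)),
    C_HHN = e("C", c("H", "H", "N"), 2, 4.05, 0.99, 0.90, 1.5679, fr,
              c("1,0" = 0.06)),
    C_COO = e("C", c("C", "O", "O"), 2, 3.80, 1.01, 0.90, 1.5679, fr,
              c("1,0" = 0.05, "2,0" = 0.10)),
    C_CH3 = e("C", c("C", "H", "H", "H"), 2, 4.10, 0.99, 0.90, 1.5679, fr,
              c("1,0" = 0.03)),
    C_any = e("C", "ANY", 2, 4.00, 1.00, 0.90, 1.5679, fr),
    P_O4  = e("P", c("O", "O", "O", "O"), 10, 3.60, 1.04, 1.00, 1.8000,
              c(2L, 2L, 4L, 6L, 8L), c("3,-2" = 0.10)),
    P_any = e("P", "ANY", 10, 5.00, 1.00, 1.00, 1.8000,
              c(2L, 2L, 4L, 6L, 8L)),
    S_CH  = e("S", c("C", "H"), 10, 6.05, 0.99, 1.00, 1.8273,
              c(6L, 6L, 6L, 6L, 6L), c("1,0" = 0.05, "2,0" = -0.05)),
    S_any = e("S", "ANY", 10, 6.00, 0.99, 1.00, 1.8273,
              c(6L, 6L, 6L, 6L, 6L)),
    MG_any = e("MG", "ANY", 10, 1.60, 1.10, 1.00, 1.1025, fr,
               frame = "NONE")
  )
  databank(db, version = "fixture-1")
}

#' A water molecule structure
#'
#' Gas-phase geometry (O-H 0.9572 angstrom, H-O-H 104.52 degrees), suitable
#' for transfer with the fixture databank.
#'
#' @param center Position of the oxygen (angstrom).
#' @param resno Residue number.
#' @param chain Chain identifier.
#' @return An [epmm_structure()].
#' @export
make_water_structure <- function(center = c(0, 0, 0), resno = 1,
                                 chain = "W") {
  a <- 104.52 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(0.9572, 0, 0),
               0.9572 * c(cos(a), sin(a), 0))
  xyz <- round(sweep(xyz, 2, center, `+`), 3)
  epmm_structure(data.frame(
    elety = c("O", "H1", "H2"), element = c("O", "H", "H"),
    resid = "HOH", chain = chain, resno = resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = TRUE))
}

#' Analytic Slater dimer
#'
#' Two single-atom models with pure 1s-Slater valence densities
#' \eqn{\rho(r) = P_{val}\, \zeta^3/\pi\, e^{-2\zeta r}} and unit nuclei,
#' the substrate for closed-form Coulomb oracles.
#'
#' @param zeta_a,zeta_b Slater orbital exponents (1/Bohr).
#' @param separation Distance in angstrom (along x).
#' @param q_a,q_b Net charges in e (electron count is `1 - q`).
#' @return List with `a` and `b`, each a [density_model()].
#' @export
make_slater_dimer <- function(zeta_a, zeta_b, separation, q_a = 0, q_b = 0) {
  if (separation <= 0) stop("separation must be positive")
  mk <- function(zeta, q, pos, lab) {
    wf <- wavefunction_table(list(H = data.frame(
      label = "1s", n = 1L, zeta = zeta, occ = 1, role = "valence")))
    p <- pseudoatom_parameters("H", P_core = 0, P_val = 1 - q, kappa = 1,
                               zeta = zeta)
    density_model(list(pseudoatom(p, pos, label = lab, wf = wf)),
                  meta = list(scaled = TRUE))
  }
  list(a = mk(zeta_a, q_a, c(0, 0, 0), "SLA/a"),
       b = mk(zeta_b, q_b, c(separation, 0, 0), "SLB/b"))
}

# --- toy complex ------------------------------------------------------------

# small deterministic LCG so generation is platform-independent and does not
# touch R's global RNG; returns integers in [0, 2^31)
.lcg_new <- function(seed) {
  env <- new.env()
  env$x <- as.numeric(seed %% 2^31)
  env
}
.lcg_int <- function(env, n = 1) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    env$x <- (1103515245 * env$x + 12345) %% 2^31
    out[i] <- env$x
  }
  out
}
# uniform on integer grid of `steps` values, mapped to [lo, hi]
.lcg_grid <- function(env, lo, hi, steps = 20000L) {
  k <- .lcg_int(env) %% steps
  lo + (hi - lo) * k / (steps - 1)
}

.unit <- function(v) v / sqrt(sum(v^2))

# k unit vectors at tetrahedral-like angle `ang` (deg) from the bond
# direction d (pointing from the atom toward its placed neighbor)
.sp3_dirs <- function(d, k, ang = 109.47, offset = 0) {
  d <- .unit(d)
  p <- .perp_vector(d)
  q <- c(d[2] * p[3] - d[3] * p[2], d[3] * p[1] - d[1] * p[3],
         d[1] * p[2] - d[2] * p[1])
  a <- ang * pi / 180
  phi <- 2 * pi * (seq_len(k) - 1) / k + offset
  t(vapply(phi, function(f) {
    cos(a) * d + sin(a) * (cos(f) * p + sin(f) * q)
  }, numeric(3)))
}

# rotation matrix from integer-degree Euler angles
.euler_rot <- function(a, b, c) {
  ra <- a * pi / 180; rb <- b * pi / 180; rc <- c * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3)
  Rz(ra) %*% Ry(rb) %*% Rz(rc)
}

# residue template geometries (local coordinates, angstrom); each is a list
# with elety, element, xyz
.toy_templates <- function() {
  t4 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  lys <- local({
    N <- c(0, 0, 0)
    C <- 1.49 * t4[1, ]
    H <- 1.033 * t4[2:4, ]
    HC <- rbind(C + 1.09 * -t4[2, ], C + 1.09 * -t4[3, ])
    list(elety = c("N", "H1", "H2", "H3", "C", "HC1", "HC2"),
         element = c("N", "H", "H", "H", "C", "H", "H"),
         xyz = rbind(N, H, C, HC), charge = +1, resid = "LYS")
  })
  glu <- local({
    CD <- c(0, 0, 0)
    CG <- c(-1.52, 0, 0)
    OE1 <- 1.251 * c(0.5, sqrt(3) / 2, 0)
    OE2 <- 1.256 * c(0.5, -sqrt(3) / 2, 0)
    HG <- sweep(1.09 * .sp3_dirs(c(1, 0, 0), 3, offset = 0.3), 2, CG, `+`)
    list(elety = c("CD", "CG", "OE1", "OE2", "HG1", "HG2", "HG3"),
         element = c("C", "C", "O", "O", "H", "H", "H"),
         xyz = rbind(CD, CG, OE1, OE2, HG), charge = -1, resid = "GLU")
  })
  ser <- local({
    CB <- c(0, 0, 0)
    OG <- c(1.42, 0, 0)
    HOG <- OG + 0.97 * c(1 / 3, sqrt(1 - 1 / 9), 0)
    HB <- 1.09 * .sp3_dirs(c(1, 0, 0), 2, offset = 2.0)
    list(elety = c("CB", "OG", "HOG", "HB1", "HB2"),
         element = c("C", "O", "H", "H", "H"),
         xyz = rbind(CB, OG, HOG, HB), charge = 0, resid = "SER")
  })
  ala <- local({
    CA <- c(0, 0, 0)
    CB <- c(1.53, 0, 0)
    HA <- 1.09 * .sp3_dirs(c(1, 0, 0), 3, offset = 0.5)
    HB <- sweep(1.09 * .sp3_dirs(c(-1, 0, 0), 3, offset = 1.0), 2, CB, `+`)
    list(elety = c("CA", "CB", "HA1", "HA2", "HA3", "HB1", "HB2", "HB3"),
         element = c("C", "C", "H", "H", "H", "H", "H", "H"),
         xyz = rbind(CA, CB, HA, HB), charge = 0, resid = "ALA")
  })
  list(plus = lys, minus = glu, neutral0 = ser, neutral1 = ala)
}

# one monophosphate "nucleotide" (formal -1): P(O-)(O-)(O)(O5')-C5'H2
.toy_nucleotide <- function() {
  t4 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  P <- c(0, 0, 0)
  OP1 <- 1.49 * t4[1, ]; OP2 <- 1.49 * t4[2, ]; OP3 <- 1.49 * t4[3, ]
  O5 <- 1.60 * t4[4, ]
  u <- .sp3_dirs(-t4[4, ], 1, ang = 120)[1, ]
  C5 <- O5 + 1.42 * u
  H5 <- rbind(C5 + 1.09 * .sp3_dirs(-u, 2, offset = 1.2)[1, ],
              C5 + 1.09 * .sp3_dirs(-u, 2, offset = 1.2)[2, ])
  list(elety = c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "H51", "H52"),
       element = c("P", "O", "O", "O", "O", "C", "H", "H"),
       xyz = rbind(P, OP1, OP2, OP3, O5, C5, H5), charge = -1, resid = "C")
}

# triphosphate first nucleotide (formal -4): PG-O3B-PB-O3A-PA-O5'-C5'H2
.toy_triphosphate <- function() {
  t4 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  PG <- c(0, 0, 0)
  O1G <- 1.49 * t4[1, ]; O2G <- 1.49 * t4[2, ]; O3G <- 1.49 * t4[3, ]
  O3B <- 1.60 * t4[4, ]
  uB <- .sp3_dirs(-t4[4, ], 1, ang = 130)[1, ]
  PB <- O3B + 1.60 * uB
  dPB <- .unit(O3B - PB)
  dirs <- .sp3_dirs(dPB, 3, offset = 0.4)
  O1B <- PB + 1.49 * dirs[1, ]; O2B <- PB + 1.49 * dirs[2, ]
  O3A <- PB + 1.60 * dirs[3, ]
  uA <- .sp3_dirs(.unit(PB - O3A), 1, ang = 130)[1, ]
  PA <- O3A + 1.60 * uA
  dPA <- .unit(O3A - PA)
  dirsA <- .sp3_dirs(dPA, 3, offset = 1.1)
  O1A <- PA + 1.49 * dirsA[1, ]; O2A <- PA + 1.49 * dirsA[2, ]
  O5 <- PA + 1.60 * dirsA[3, ]
  uC <- .sp3_dirs(.unit(PA - O5), 1, ang = 120)[1, ]
  C5 <- O5 + 1.42 * uC
  H5 <- sweep(1.09 * .sp3_dirs(-uC, 2, offset = 0.8), 2, C5, `+`)
  list(elety = c("PG", "O1G", "O2G", "O3G", "O3B", "PB", "O1B", "O2B",
                 "O3A", "PA", "O1A", "O2A", "O5'", "C5'", "H51", "H52"),
       element = c("P", "O", "O", "O", "O", "P", "O", "O", "O", "P", "O",
                   "O", "O", "C", "H", "H"),
       xyz = rbind(PG, O1G, O2G, O3G, O3B, PB, O1B, O2B, O3A, PA, O1A,
                   O2A, O5, C5, H5), charge = -4, resid = "CTP")
}

#' Toy protein-RNA complex specification
#'
#' @param n_protein_residues Number of protein residue blobs.
#' @param n_rna_nucleotides Number of RNA residues (first one triphosphate).
#' @param include_metal Place a +2 metal with three coordinating waters.
#' @param n_plus,n_minus Counts of +1 and -1 protein residues (the rest are
#'   neutral).
#' @param seed Integer geometry seed (deterministic placement).
#' @return Object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_protein_residues = 8, n_rna_nucleotides = 3,
                             include_metal = TRUE, n_plus = 3, n_minus = 2,
                             seed = 42) {
  if (n_plus + n_minus > n_protein_residues) {
    stop("impossible charge plan: more charged residues than residues")
  }
  if (n_rna_nucleotides < 1) stop("need at least one RNA nucleotide")
  structure(list(n_protein_residues = n_protein_residues,
                 n_rna_nucleotides = n_rna_nucleotides,
                 include_metal = include_metal, n_plus = n_plus,
                 n_minus = n_minus, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Generate a toy protein-RNA complex
#'
#' Builds a PDB-writable structure emulating the composition of a
#' triphosphate-RNA binding site: a first "nucleotide" bearing a
#' triphosphate-like fragment (formal charge -4 e), further -1 e
#' nucleotides, optionally a +2 e metal cation with three coordinating
#' waters at ~2.1 angstrom, and charged/neutral amino-acid-like residues
#' placed on a 3-12 angstrom shell around the first fragment. Placement is
#' drawn from integer grids through a small deterministic generator, so the
#' same seed always yields identical coordinates on any platform.
#'
#' The returned charge specifications scale each residue to its formal
#' charge, with the first nucleotide, the metal, its waters and the first
#' -1 e protein residue (when both are present) grouped as a single
#' fragment, mirroring the grouped-fragment treatment of a metal-bridged
#' binding site.
#'
#' @param spec A [toy_complex_spec()].
#' @return List with `structure` (an [epmm_structure()]), `charge_specs`
#'   (list of [fragment_charge_spec()]) and `formal_charges` (named per
#'   residue).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  rng <- .lcg_new(spec$seed)
  rows <- list()
  add_res <- function(tmpl, chain, resno, rot = diag(3), shift = c(0, 0, 0),
                      het = FALSE, resid = tmpl$resid) {
    xyz <- round(t(rot %*% t(tmpl$xyz)) +
                   matrix(shift, nrow(tmpl$xyz), 3, byrow = TRUE), 3)
    rows[[length(rows) + 1]] <<- data.frame(
      elety = tmpl$elety, element = tmpl$element, resid = resid,
      chain = chain, resno = resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      het = het)
  }

  # RNA chain R: triphosphate nucleotide at the origin, then monophosphates
  tp <- .toy_triphosphate()
  add_res(tp, "R", 1)
  if (spec$n_rna_nucleotides > 1) {
    nuc <- .toy_nucleotide()
    for (n in 2:spec$n_rna_nucleotides) {
      rot <- .euler_rot(40 * n, 25 * n, 10 * n)
      add_res(nuc, "R", n, rot = rot,
              shift = c(5.5 * (n - 1), 2.0 * (n - 1), 4.5 * (n - 1) + 3.5))
    }
  }

  # metal + three waters near the terminal gamma-phosphate oxygens
  if (spec$include_metal) {
    o1g <- tp$xyz[2, ]; o2g <- tp$xyz[3, ]
    mid <- .unit(.unit(o1g) + .unit(o2g))
    mg <- round(mid * (1.49 + 1.45), 3)   # ~2.09 A from O1G and O2G
    rows[[length(rows) + 1]] <- data.frame(
      elety = "MG", element = "MG", resid = "MG", chain = "M", resno = 91,
      x = mg[1], y = mg[2], z = mg[3], het = TRUE)
    wdirs <- .sp3_dirs(-mid, 3, ang = 95, offset = 0.6)
    for (w in 1:3) {
      ow <- mg + 2.08 * wdirs[w, ]
      # hydrogens point away from the metal and the phosphates
      hd <- .sp3_dirs(wdirs[w, ], 2, ang = 52.26, offset = 0.4)
      tmpl <- list(elety = c("O", "H1", "H2"), element = c("O", "H", "H"),
                   xyz = rbind(ow, ow + 0.957 * hd[1, ], ow + 0.957 * hd[2, ]),
                   resid = "HOH")
      add_res(tmpl, "M", 91 + w, het = TRUE)
    }
  }

  # protein chain A on a shell around the triphosphate fragment
  tmpls <- .toy_templates()
  kinds <- c(rep("plus", spec$n_plus), rep("minus", spec$n_minus),
             rep(c("neutral0", "neutral1"),
                 length.out = spec$n_protein_residues - spec$n_plus -
                   spec$n_minus))
  placed <- do.call(rbind, rows)
  for (k in seq_along(kinds)) {
    tmpl <- tmpls[[kinds[k]]]
    for (try in 0:40) {
      rad <- .lcg_grid(rng, 3, 12) + 0.25 * try
      u <- .unit(c(.lcg_grid(rng, -1, 1), .lcg_grid(rng, -1, 1),
                   .lcg_grid(rng, -1, 1)))
      rot <- .euler_rot(round(.lcg_grid(rng, 0, 359)),
                        round(.lcg_grid(rng, 0, 179)),
                        round(.lcg_grid(rng, 0, 359)))
      cand <- round(t(rot %*% t(tmpl$xyz)) +
                      matrix(u * rad, nrow(tmpl$xyz), 3, byrow = TRUE), 3)
      dmin <- min(sqrt(outer(rowSums(cand^2),
                             rowSums(as.matrix(placed[, c("x", "y", "z")])^2),
                             `+`) -
                         2 * cand %*% t(as.matrix(placed[, c("x", "y", "z")]))))
      if (dmin > 2.5) break
    }
    add_res(tmpl, "A", k, rot = rot, shift = u * rad)
    placed <- do.call(rbind, rows)
  }

  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  struct <- epmm_structure(df)
  rid <- .residue_ids(struct)

  # per-residue formal charges
  res_tab <- unique(data.frame(rid = rid, resid = struct$resid,
                               stringsAsFactors = FALSE))
  fc <- vapply(seq_len(nrow(res_tab)), function(i) {
    switch(res_tab$resid[i], CTP = -4, C = -1, MG = +2, HOH = 0,
           LYS = +1, GLU = -1, SER = 0, ALA = 0, 0)
  }, numeric(1))
  names(fc) <- res_tab$rid

  # grouped fragment: first nucleotide + metal + waters (+ first GLU)
  group <- res_tab$rid[res_tab$resid %in% c("CTP", "MG", "HOH")]
  glu_rid <- res_tab$rid[res_tab$resid == "GLU"]
  if (spec$include_metal && length(glu_rid)) group <- c(group, glu_rid[1])
  specs <- list(fragment_charge_spec(group, sum(fc[group])))
  for (r in res_tab$rid[!res_tab$rid %in% group]) {
    specs[[length(specs) + 1]] <- fragment_charge_spec(r, unname(fc[r]))
  }

  list(structure = struct, charge_specs = specs, formal_charges = fc)
}

# --- brute-force Coulomb oracle ---------------------------------------------

# numeric (cumulative-trapezoid) radial potential tables for one atom:
# returns function(points_bohr) -> electron potential, independent of the
# incomplete-gamma closed forms used by the production code
.numeric_atom_potential <- function(atom, r_max = 40, n_r = 4000) {
  r <- seq(1e-6, r_max, length.out = n_r)
  cumtz <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(r)))
  make_vl <- function(f, l) {
    inner <- cumtz(f(r) * r^(l + 2))
    outer_all <- cumtz(f(r) * r^(1 - l))
    outer <- outer_all[length(outer_all)] - outer_all
    v <- 4 * pi / (2 * l + 1) * (inner / r^(l + 1) + r^l * outer)
    stats::splinefun(r, v)
  }
  sph_f <- function(s) .prim_density(s, atom$sph_prims)
  v_sph <- make_vl(sph_f, 0)
  defs <- lapply(atom$def_terms, function(d) {
    f <- function(s) d$prim$c0 * s^d$prim$m * exp(-d$prim$a * s)
    list(d = d, vl = make_vl(f, d$l))
  })
  function(points_bohr) {
    g <- .atom_geometry(atom, points_bohr)
    rr <- pmin(g$r, r_max)
    v <- v_sph(rr)
    for (dd in defs) {
      ang <- numeric(length(rr))
      for (i in seq_along(dd$d$m)) {
        ang <- ang + dd$d$P[i] * dd$d$clm[i] *
          real_sph_harm(dd$d$l, dd$d$m[i], g$u_loc)
      }
      v <- v + dd$vl(rr) * ang
    }
    v
  }
}

#' Brute-force Coulomb energy oracle
#'
#' Independent check of the exact-potential energies: electron potentials
#' are built by cumulative-trapezoid integration of the density on dense
#' uniform radial tables (no closed-form incomplete gamma functions), and
#' the electron-electron integral is done on uniform spherical-coordinate
#' grids (midpoint polar, trapezoid azimuthal, uniform radial) around each
#' atom of `model_b`. Nucleus-electron terms use the numeric potential
#' tables at the nuclei; nucleus-nucleus terms are direct Coulomb sums.
#'
#' @param model_a,model_b Small [density_model()] objects (<= 10 atoms
#'   each).
#' @param resolution Named list: `n_r` radial points, `r_max` radial extent
#'   (Bohr), `n_theta`, `n_phi` angular points.
#' @param convergence If TRUE, also evaluates at double resolution and
#'   attaches the difference as attribute `"convergence"`.
#' @return Energy in kcal/mol.
#' @export
brute_force_coulomb_oracle <- function(model_a, model_b,
                                       resolution = list(n_r = 300,
                                                         r_max = 18,
                                                         n_theta = 40,
                                                         n_phi = 80),
                                       convergence = FALSE) {
  stopifnot(inherits(model_a, "density_model"),
            inherits(model_b, "density_model"))
  if (length(model_a$atoms) > 10 || length(model_b$atoms) > 10) {
    stop("oracle limited to models with at most 10 atoms")
  }
  npts <- resolution$n_r * resolution$n_theta * resolution$n_phi *
    length(model_b$atoms)
  if (npts > 5e7) stop("oracle grid too large (resource guard)")

  run <- function(res) {
    va <- lapply(model_a$atoms, .numeric_atom_potential)
    vb <- lapply(model_b$atoms, .numeric_atom_potential)
    pa <- t(vapply(model_a$atoms, function(x) .A2B(x$position), numeric(3)))
    pb <- t(vapply(model_b$atoms, function(x) .A2B(x$position), numeric(3)))
    za <- vapply(model_a$atoms, function(x) x$Z, numeric(1))
    zb <- vapply(model_b$atoms, function(x) x$Z, numeric(1))
    # nucleus-nucleus
    d <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb))
    e <- sum(outer(za, zb) / d)
    # nucleus-electron (numeric potentials at the nuclei)
    for (i in seq_along(za)) {
      e <- e - za[i] * sum(vapply(vb, function(f) f(pa[i, , drop = FALSE]),
                                  numeric(1)))
    }
    for (j in seq_along(zb)) {
      e <- e - zb[j] * sum(vapply(va, function(f) f(pb[j, , drop = FALSE]),
                                  numeric(1)))
    }
    # electron-electron on uniform grids around each b atom: composite
    # Simpson radial rule on the substitution r = t^2 (resolves the steep
    # core density near the nucleus), midpoint polar, trapezoid azimuthal
    nr <- res$n_r + res$n_r %% 2      # even interval count
    dt <- sqrt(res$r_max) / nr
    tt <- dt * seq_len(nr)            # t = 0 contributes nothing
    wt <- dt / 3 * ifelse(seq_len(nr) %% 2 == 1, 4, 2)
    wt[nr] <- dt / 3
    rr <- tt^2
    wr <- wt * 2 * tt                 # dr = 2 t dt
    dth <- pi / res$n_theta
    th <- (seq_len(res$n_theta) - 0.5) * dth
    ph <- 2 * pi * (seq_len(res$n_phi) - 1) / res$n_phi
    dph <- 2 * pi / res$n_phi
    # exact bin masses of the sin(theta) Jacobian on the uniform theta grid
    wth <- cos(th - dth / 2) - cos(th + dth / 2)
    u <- cbind(as.vector(outer(sin(th), cos(ph))),
               as.vector(outer(sin(th), sin(ph))),
               rep(cos(th), times = res$n_phi))
    wang <- rep(wth, times = res$n_phi) * dph
    for (j in seq_along(model_b$atoms)) {
      bat <- model_b$atoms[[j]]
      for (ir in seq_along(rr)) {
        pts <- sweep(u * rr[ir], 2, .A2B(bat$position), `+`)
        rho <- evaluate_density(bat, .B2A(pts))
        vtot <- numeric(nrow(pts))
        for (f in va) vtot <- vtot + f(pts)
        e <- e + rr[ir]^2 * wr[ir] * sum(wang * rho * vtot)
      }
    }
    .H2KCAL(e)
  }
  out <- run(resolution)
  if (convergence) {
    res2 <- resolution
    res2$n_r <- resolution$n_r * 2
    res2$n_theta <- resolution$n_theta * 2
    res2$n_phi <- resolution$n_phi * 2
    attr(out, "convergence") <- run(res2) - out
  }
  out
}
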