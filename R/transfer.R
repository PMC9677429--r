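# Databank transfer: the two-pass procedure (hydrogen extension with metal
# bonds suppressed, then atom typing with the default metal radius), model
# construction and fragment charge scaling.

#' Transfer pseudoatom parameters onto a structure
#'
#' Runs the two-pass transfer protocol: first bonds are detected with the
#' Mg radius overridden to 0.01 angstrom (so metal coordination does not
#' interfere with X-H bond assignment) and hydrogens are extended to neutron
#' distances; second, bonds are re-detected with the default Mg radius
#' (1.36 angstrom), atom types are assigned and a continuous density model
#' is built.
#'
#' @param struct An [epmm_structure()].
#' @param db A [databank()].
#' @param wf Wavefunction table (defaults to the packaged one).
#' @param extend_h Extend hydrogens to neutron distances (default TRUE).
#' @param xh_distances Neutron X-H distance table.
#' @param tolerance Bond detection tolerance in angstrom.
#' @param metal_override Named vector of first-pass radius overrides
#'   (default `c(MG = 0.01)`).
#' @return A [density_model()]; metadata records the assignment and the
#'   possibly repositioned structure.
#' @export
transfer_parameters <- function(struct, db, wf = default_wavefunctions(),
                                extend_h = TRUE,
                                xh_distances = neutron_distances(),
                                tolerance = 0.4,
                                metal_override = c(MG = 0.01)) {
  # pass 1: suppress metal bonds, extend hydrogens
  if (extend_h && any(struct$element == "H")) {
    b1 <- detect_bonds(struct, covalent_radii(metal_override), tolerance)
    struct <- extend_hydrogens(struct, b1, xh_distances)
  }
  # pass 2: default radii, type assignment, model build
  b2 <- detect_bonds(struct, covalent_radii(), tolerance)
  types <- assign_atom_types(struct, b2, db)
  nb <- .neighbor_list(nrow(struct), b2)
  rid <- .residue_ids(struct)
  atoms <- vector("list", nrow(struct))
  for (i in seq_len(nrow(struct))) {
    e <- db$entries[[types[i]]]
    frame <- .resolve_frame(struct, nb, i, e$params$frame_rule)
    atoms[[i]] <- pseudoatom(
      e$params, c(struct$x[i], struct$y[i], struct$z[i]),
      label = paste0(struct$elety[i], "/", rid[i]),
      frame = frame, wf = wf)
  }
  density_model(atoms, meta = list(
    structure = struct, types = types, residue_ids = rid,
    databank_version = db$version, scaled = FALSE, wf = wf))
}

#' Fragment formal-charge specification
#'
#' @param residues Character vector of residue identifiers
#'   (`"<chain><resno>"`, e.g. `"A12"`), or `NULL` when `atoms` gives an
#'   explicit atom index set.
#' @param formal_charge Target formal charge in e.
#' @param atoms Optional explicit atom (row) indices.
#' @return Object of class `fragment_charge_spec`.
#' @export
fragment_charge_spec <- function(residues, formal_charge, atoms = NULL) {
  structure(list(residues = residues, formal_charge = formal_charge,
                 atoms = atoms),
            class = "fragment_charge_spec")
}

# resolve a list of fragment specs into disjoint atom index sets that
# partition the model
.resolve_fragments <- function(model, specs) {
  rid <- model$meta$residue_ids
  if (is.null(rid)) stop("model lacks residue metadata")
  n <- length(model$atoms)
  sets <- lapply(specs, function(s) {
    idx <- if (!is.null(s$atoms)) as.integer(s$atoms) else which(rid %in% s$residues)
    sort(idx)
  })
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) stop("fragment specs overlap")
  if (length(all_idx) != n || !setequal(all_idx, seq_len(n))) {
    stop("fragment specs must partition the model (",
         n - length(all_idx), " atoms unassigned)")
  }
  sets
}

#' Scale fragment charges to formal values
#'
#' Within each fragment the valence populations are scaled so that the
#' summed monopole charge \eqn{\sum_i (Z_i - P_{core,i} - P_{val,i})}
#' equals the fragment's formal charge exactly. The charge defect is
#' distributed proportionally to each atom's current valence population
#' (multiplicative scaling); multipole populations and the
#' expansion-contraction parameters are untouched.
#'
#' @param model A [density_model()] from [transfer_parameters()].
#' @param specs List of [fragment_charge_spec()] objects partitioning the
#'   model.
#' @param mode `"proportional"` (default) or `"uniform"` (equal per-atom
#'   additive shifts).
#' @return The model with adjusted valence populations; fragment membership
#'   and formal charges are recorded in the metadata.
#' @export
scale_fragment_charges <- function(model, specs, mode = "proportional") {
  sets <- .resolve_fragments(model, specs)
  wf <- model$meta$wf
  if (is.null(wf)) wf <- default_wavefunctions()
  for (k in seq_along(sets)) {
    idx <- sets[[k]]
    target <- specs[[k]]$formal_charge
    q <- sum(vapply(model$atoms[idx], .atom_charge, numeric(1)))
    delta <- q - target          # electrons to add to the fragment
    if (abs(delta) < 1e-12) next
    pv <- vapply(model$atoms[idx], function(a) a$params$P_val, numeric(1))
    if (sum(pv) == 0) {
      stop("fragment ", k, " has zero total valence population; cannot ",
           "scale to its formal charge")
    }
    shift <- if (identical(mode, "proportional")) {
      pv / sum(pv) * delta
    } else if (identical(mode, "uniform")) {
      rep(delta / length(idx), length(idx))
    } else stop("mode must be 'proportional' or 'uniform'")
    for (ii in seq_along(idx)) {
      at <- model$atoms[[idx[ii]]]
      p <- at$params
      p$P_val <- p$P_val + shift[ii]
      model$atoms[[idx[ii]]] <- pseudoatom(p, at$position, label = at$label,
                                           frame = at$frame, wf = wf)
    }
  }
  model$meta$scaled <- TRUE
  model$meta$fragments <- sets
  model$meta$formal_charges <- vapply(specs, function(s) s$formal_charge,
                                      numeric(1))
  model
}
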