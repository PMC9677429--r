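# Protein-RNA analysis pipeline: fragment partition, binding-site selection,
# per-residue interaction energy tables and cross-complex comparison.

.nucleotide_names <- c("A", "C", "G", "U", "ATP", "CTP", "GTP", "UTP",
                       "UTP1", "CTP1", "ATP1")
.water_names <- c("HOH", "WAT")

#' Partition a protein-RNA complex into interaction fragments
#'
#' The first `n_rna_residues` residues of the RNA chain become the RNA
#' fragments; the metal cation and the waters in its first coordination
#' shell (O within `water_shell` of the metal) are assigned to the first
#' fragment. Every protein residue is its own fragment.
#'
#' @param struct An [epmm_structure()].
#' @param metal_element Element symbol of the mediating cation (default Mg).
#' @param n_rna_residues Number of RNA residues analyzed (default 3).
#' @param rna_chain,protein_chain Chain identifiers; autodetected when NULL
#'   (the RNA chain is the one holding nucleotide residue names).
#' @param water_shell Metal-oxygen first-shell cutoff in angstrom
#'   (default 2.6).
#' @return Object of class `fragment_partition` with atom index sets
#'   `rna_fragments` (list, fragment 1 first) and `protein_residues`
#'   (named list).
#' @export
partition_fragments <- function(struct, metal_element = "MG",
                                n_rna_residues = 3, rna_chain = NULL,
                                protein_chain = NULL, water_shell = 2.6) {
  rid <- .residue_ids(struct)
  is_water <- struct$resid %in% .water_names
  is_metal <- struct$element == toupper(metal_element) & struct$het
  if (is.null(rna_chain)) {
    cand <- unique(struct$chain[struct$resid %in% .nucleotide_names])
    if (!length(cand)) stop("no RNA chain found (nucleotide residue names)")
    rna_chain <- cand[1]
  }
  if (!any(struct$chain == rna_chain)) stop("missing RNA chain ", rna_chain)
  if (is.null(protein_chain)) {
    cand <- setdiff(unique(struct$chain[!is_water & !is_metal]), rna_chain)
    if (!length(cand)) stop("no protein chain found")
    protein_chain <- cand[1]
  }

  rna_res <- unique(rid[struct$chain == rna_chain])
  if (length(rna_res) < n_rna_residues) {
    stop("RNA chain has only ", length(rna_res), " residues")
  }
  rna_res <- rna_res[seq_len(n_rna_residues)]
  frags <- lapply(rna_res, function(r) which(rid == r))

  metal_idx <- which(is_metal)
  water_idx <- integer(0)
  if (length(metal_idx)) {
    if (length(metal_idx) > 1) {
      stop("multiple ", metal_element, " cations; pass an explicit subset")
    }
    mpos <- as.numeric(struct[metal_idx, c("x", "y", "z")])
    wo <- which(is_water & struct$element == "O")
    do <- sqrt((struct$x[wo] - mpos[1])^2 + (struct$y[wo] - mpos[2])^2 +
                 (struct$z[wo] - mpos[3])^2)
    shell <- wo[do <= water_shell]
    if (length(shell) > 3) {
      stop("more than 3 metal-coordinating waters: residues ",
           paste(unique(rid[shell]), collapse = ", "))
    }
    water_idx <- which(rid %in% rid[shell])
    frags[[1]] <- c(frags[[1]], metal_idx, water_idx)
  } else {
    warning("no ", metal_element, " cation present; fragment 1 is the ",
            "first nucleotide only")
  }

  prot_res <- unique(rid[struct$chain == protein_chain])
  prot <- lapply(prot_res, function(r) which(rid == r))
  names(prot) <- prot_res
  names(frags) <- paste0("fragment", seq_along(frags))

  structure(list(rna_fragments = frags, protein_residues = prot,
                 metal_atoms = metal_idx, metal_waters = water_idx,
                 rna_chain = rna_chain, protein_chain = protein_chain),
            class = "fragment_partition")
}

#' @export
print.fragment_partition <- function(x, ...) {
  cat("Fragment partition:", length(x$rna_fragments), "RNA fragments (",
      paste(lengths(x$rna_fragments), collapse = "/"), "atoms ),",
      length(x$protein_residues), "protein residues\n")
  invisible(x)
}

#' Select the geometric binding site
#'
#' Protein residues with any atom (hydrogens included) within `cutoff` of
#' any atom of the RNA fragments (metal and coordinating waters included);
#' closed interval at the cutoff.
#'
#' @param struct An [epmm_structure()].
#' @param partition A [partition_fragments()] result.
#' @param cutoff Distance cutoff in angstrom (default 5).
#' @return Character vector of residue identifiers.
#' @export
select_binding_site <- function(struct, partition, cutoff = 5) {
  xyz <- .coords(struct)
  rna_idx <- unlist(partition$rna_fragments)
  rxyz <- xyz[rna_idx, , drop = FALSE]
  sel <- vapply(partition$protein_residues, function(idx) {
    p <- xyz[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(rxyz^2), `+`) - 2 * p %*% t(rxyz)
    min(d2) <= cutoff^2 + 1e-12
  }, logical(1))
  names(partition$protein_residues)[sel]
}

#' Per-residue interaction energy table and binding-site report
#'
#' Computes, for every protein residue against every RNA fragment, the
#' multipole-moment, hybrid EPMM and penetration energies, then applies the
#' three binding-site filters: geometric distance, significant interaction
#' energy (|E| above `energy_filter` against any fragment) and strong
#' penetration (|Epen| at or above `penetration_filter`, within the
#' geometric site).
#'
#' @param model Scaled [density_model()] from [scale_fragment_charges()].
#' @param partition A [partition_fragments()] result.
#' @param quad A [quadrature_spec()].
#' @param max_l Multipole truncation order.
#' @param cutoff Geometric binding-site cutoff in angstrom.
#' @param energy_filter Significance threshold in kcal/mol (strictly
#'   greater-than, default 5).
#' @param penetration_filter Strong-penetration threshold in kcal/mol
#'   (greater-or-equal, default 2).
#' @return Object of class `binding_site_report`: `per_residue` energy table
#'   (one row per residue x fragment), `totals`, `within_5A`, `significant`,
#'   `strong_penetration` and the run settings.
#' @export
residue_energy_table <- function(model, partition, quad = quadrature_spec(),
                                 max_l = 4, cutoff = 5, energy_filter = 5,
                                 penetration_filter = 2) {
  if (!isTRUE(model$meta$scaled)) {
    stop("model must be charge-scaled first (scale_fragment_charges)")
  }
  struct <- model$meta$structure
  rows <- list()
  for (rn in names(partition$protein_residues)) {
    ridx <- partition$protein_residues[[rn]]
    mres <- .model_subset(model, ridx)
    for (fi in seq_along(partition$rna_fragments)) {
      mfrag <- .model_subset(model, partition$rna_fragments[[fi]])
      e <- epmm_energy(mres, mfrag, quad = quad, max_l = max_l,
                       breakdown = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        residue = rn, fragment = names(partition$rna_fragments)[fi],
        e_mm = e$e_mm, e_epmm = e$e_epmm, e_pen = e$e_pen)
    }
  }
  tab <- do.call(rbind, rows)

  within <- select_binding_site(struct, partition, cutoff)
  agg <- function(sub) {
    stats::aggregate(cbind(e_mm, e_epmm, e_pen) ~ fragment, sub, sum)
  }
  by_res <- stats::aggregate(cbind(e_epmm, e_pen) ~ residue, tab,
                             function(v) max(abs(v)))
  significant <- by_res$residue[by_res$e_epmm > energy_filter]
  strong_pen <- intersect(
    by_res$residue[by_res$e_pen >= penetration_filter], within)

  totals <- list(
    whole = agg(tab),
    binding_site = agg(tab[tab$residue %in% within, , drop = FALSE]),
    grand_whole = sum(tab$e_epmm),
    grand_binding_site = sum(tab$e_epmm[tab$residue %in% within]),
    pen_whole = sum(tab$e_pen),
    pen_binding_site = sum(tab$e_pen[tab$residue %in% within])
  )
  structure(list(per_residue = tab, totals = totals, within_5A = within,
                 significant = significant, strong_penetration = strong_pen,
                 settings = list(quad = quad, max_l = max_l, cutoff = cutoff,
                                 energy_filter = energy_filter,
                                 penetration_filter = penetration_filter)),
            class = "binding_site_report")
}

#' @export
print.binding_site_report <- function(x, ...) {
  cat("Binding-site report\n")
  cat("  residues within", x$settings$cutoff, "A:", length(x$within_5A), "\n")
  cat("  significant (|E| >", x$settings$energy_filter, "kcal/mol):",
      length(x$significant), "\n")
  cat("  strong penetration (|Epen| >=", x$settings$penetration_filter,
      "kcal/mol):", length(x$strong_penetration), "\n")
  cat(sprintf("  grand totals: whole %.2f / site %.2f kcal/mol (Epen %.2f / %.2f)\n",
              x$totals$grand_whole, x$totals$grand_binding_site,
              x$totals$pen_whole, x$totals$pen_binding_site))
  invisible(x)
}

#' Compare reports across complexes
#'
#' Pairwise comparison of the per-fragment and grand interaction energy
#' totals of two or more binding-site reports (e.g. the same protein bound
#' to different RNA sequences). The headline statistic is the maximum
#' pairwise discrepancy of grand totals relative to the mean magnitude,
#' in percent.
#'
#' @param reports List of >= 2 [residue_energy_table()] reports with
#'   identical fragment schemas.
#' @param scope `"binding_site"` (default) or `"whole"`.
#' @return Object of class `sequence_comparison`: `totals` matrix (complex x
#'   fragment), `grand_totals` and `max_relative_discrepancy` (percent).
#' @export
compare_sequences <- function(reports, scope = "binding_site") {
  if (length(reports) < 2) stop("need at least two reports to compare")
  schemas <- lapply(reports, function(r) sort(unique(r$per_residue$fragment)))
  if (!all(vapply(schemas, identical, logical(1), schemas[[1]]))) {
    stop("reports have mismatched fragment schemas")
  }
  key <- if (identical(scope, "whole")) "whole" else "binding_site"
  tot <- t(vapply(reports, function(r) {
    tt <- r$totals[[key]]
    stats::setNames(tt$e_epmm, tt$fragment)[schemas[[1]]]
  }, numeric(length(schemas[[1]]))))
  grand <- rowSums(tot)
  if (is.null(names(reports))) {
    rownames(tot) <- paste0("complex", seq_along(reports))
  } else rownames(tot) <- names(reports)
  disc <- max(stats::dist(grand)) / mean(abs(grand)) * 100
  structure(list(totals = tot, grand_totals = grand,
                 max_relative_discrepancy = disc, scope = key),
            class = "sequence_comparison")
}

#' @export
print.sequence_comparison <- function(x, ...) {
  cat("Sequence comparison (", x$scope, " totals, kcal/mol):\n", sep = "")
  print(round(cbind(x$totals, grand = x$grand_totals), 2))
  cat(sprintf("  max relative discrepancy: %.1f%%\n",
              x$max_relative_discrepancy))
  invisible(x)
}

#' Write the per-residue energy table as CSV
#'
#' Columns `residue_id`, `fragment_id`, `e_mm`, `e_epmm`, `e_pen`
#' (kcal/mol).
#'
#' @param report A [residue_energy_table()] result.
#' @param path Output CSV path.
#' @export
write_energy_csv <- function(report, path) {
  tab <- report$per_residue
  names(tab) <- c("residue_id", "fragment_id", "e_mm", "e_epmm", "e_pen")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the quadrature settings, filters, databank version and physical
#' constants of a pipeline run as JSON.
#'
#' @param report A [residue_energy_table()] result.
#' @param path Output JSON path.
#' @param databank_version Databank version string (from the model
#'   metadata, if available).
#' @export
write_run_manifest <- function(report, path, databank_version = NA) {
  manifest <- list(
    quadrature = unclass(report$settings$quad),
    max_l = report$settings$max_l,
    filters = list(cutoff_A = report$settings$cutoff,
                   energy_kcal = report$settings$energy_filter,
                   penetration_kcal = report$settings$penetration_filter),
    databank_version = databank_version,
    constants = epmm_constants,
    counts = list(within = length(report$within_5A),
                  significant = length(report$significant),
                  strong_penetration = length(report$strong_penetration))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
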