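# Pseudoatom parameter databanks: atom-type keys, the plain-text databank
# file format, and covalent radii tables for bond detection.
#
# Atom types use a simplified topological key: element plus the sorted
# multiset of bonded neighbor elements, with a specificity-ordered fallback
# (full key > element + neighbor count > element alone). This is a fidelity
# limitation relative to databanks built on richer connectivity trees;
# numerical agreement with energies published from such databanks is not
# claimed.

#' Canonical atom-type key
#'
#' @param element Element symbol of the central atom.
#' @param neighbors Character vector of bonded neighbor elements (any order;
#'   stored sorted so equal environments compare equal), or `"ANY"` for an
#'   element-level fallback entry, or `c("COUNT", n)` for an
#'   element-plus-coordination-number entry.
#' @return Object of class `atom_type_key`.
#' @export
atom_type_key <- function(element, neighbors = character(0)) {
  element <- toupper(element)
  if (length(neighbors) && identical(toupper(neighbors[1]), "ANY")) {
    return(structure(list(element = element, level = "element",
                          neighbors = NULL, n_neighbors = NA_integer_),
                     class = "atom_type_key"))
  }
  if (length(neighbors) && identical(toupper(neighbors[1]), "COUNT")) {
    return(structure(list(element = element, level = "count",
                          neighbors = NULL,
                          n_neighbors = as.integer(neighbors[2])),
                     class = "atom_type_key"))
  }
  nb <- sort(toupper(neighbors))
  structure(list(element = element, level = "full", neighbors = nb,
                 n_neighbors = length(nb)),
            class = "atom_type_key")
}

#' @export
format.atom_type_key <- function(x, ...) {
  switch(x$level,
         element = paste0(x$element, "|ANY"),
         count = paste0(x$element, "|#", x$n_neighbors),
         full = paste0(x$element, "|", paste(x$neighbors, collapse = ",")))
}

#' @export
print.atom_type_key <- function(x, ...) {
  cat("Atom type key:", format(x), "\n")
  invisible(x)
}

#' Assemble a databank
#'
#' @param entries Named list of entries, each a list with fields `key`
#'   ([atom_type_key()]), `params` ([pseudoatom_parameters()]) and optional
#'   `provenance`.
#' @param version Version string recorded in file headers and manifests.
#' @return Object of class `databank`.
#' @export
databank <- function(entries, version = "1") {
  for (nm in names(entries)) {
    e <- entries[[nm]]
    stopifnot(inherits(e$key, "atom_type_key"),
              inherits(e$params, "pseudoatom_params"))
    if (e$key$element != e$params$element) {
      stop("key/parameter element mismatch in entry ", nm)
    }
  }
  structure(list(entries = entries, version = version), class = "databank")
}

#' @export
print.databank <- function(x, ...) {
  cat("Pseudoatom databank v", x$version, ": ", length(x$entries),
      " entries\n", sep = "")
  for (nm in names(x$entries)) {
    cat("  ", format(x$entries[[nm]]$key), "  (", nm, ")\n", sep = "")
  }
  invisible(x)
}

#' Read and write databank files
#'
#' Plain-text, one block per entry:
#' \preformatted{
#' ENTRY <name>
#' KEY <element> [<neighbor> ... | ANY | COUNT <n>]
#' PARAM <P_core> <P_val> <kappa> <kappa_prime>
#' PLM <l> <m> <value>        # zero or more
#' RADIAL <zeta> <n0> <n1> <n2> <n3> <n4>
#' FRAME <ZX|BISECT_Z|NONE>
#' PROVENANCE <free text>     # optional
#' }
#' with a `VERSION <v>` header line; `#` starts a comment.
#'
#' @param path File path.
#' @return [read_databank()] returns a `databank`.
#' @export
read_databank <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  version <- "1"
  entries <- list()
  cur <- NULL
  acc <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    plm <- acc$plm
    p <- pseudoatom_parameters(
      element = acc$key$element, P_core = acc$param[1], P_val = acc$param[2],
      kappa = acc$param[3], kappa_prime = acc$param[4],
      P_lm = plm, zeta = acc$radial[1], n_l = acc$radial[-1],
      frame_rule = if (is.null(acc$frame)) "ZX" else acc$frame)
    entries[[cur]] <<- list(key = acc$key, params = p,
                            provenance = acc$provenance)
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    switch(tok[1],
      VERSION = { version <- tok[2] },
      ENTRY = {
        flush()
        cur <- tok[2]
        acc <- list(plm = stats::setNames(numeric(0), character(0)))
      },
      KEY = { acc$key <- atom_type_key(tok[2], tok[-(1:2)]) },
      PARAM = { acc$param <- as.numeric(tok[-1]) },
      PLM = {
        v <- stats::setNames(as.numeric(tok[4]),
                             paste(tok[2], tok[3], sep = ","))
        acc$plm <- c(acc$plm, v)
      },
      RADIAL = { acc$radial <- as.numeric(tok[-1]) },
      FRAME = { acc$frame <- tok[2] },
      PROVENANCE = { acc$provenance <- paste(tok[-1], collapse = " ") },
      stop("unrecognized databank line: ", ln)
    )
  }
  flush()
  databank(entries, version = version)
}

#' @rdname read_databank
#' @param db A `databank`.
#' @export
write_databank <- function(db, path) {
  out <- c("# epmm pseudoatom databank", paste("VERSION", db$version))
  for (nm in names(db$entries)) {
    e <- db$entries[[nm]]
    p <- e$params
    key_txt <- switch(e$key$level,
                      element = paste(e$key$element, "ANY"),
                      count = paste(e$key$element, "COUNT", e$key$n_neighbors),
                      full = paste(c(e$key$element, e$key$neighbors),
                                   collapse = " "))
    out <- c(out, paste("ENTRY", nm), paste("KEY", key_txt),
             sprintf("PARAM %.6f %.6f %.6f %.6f",
                     p$P_core, p$P_val, p$kappa, p$kappa_prime))
    if (length(p$P_lm)) {
      lm <- .parse_lm_names(names(p$P_lm))
      for (i in seq_along(p$P_lm)) {
        out <- c(out, sprintf("PLM %d %d %.6f", lm[i, 1], lm[i, 2],
                              unname(p$P_lm[i])))
      }
    }
    out <- c(out, sprintf("RADIAL %.6f %s", p$zeta,
                          paste(p$n_l, collapse = " ")),
             paste("FRAME", p$frame_rule))
    if (!is.null(e$provenance)) {
      out <- c(out, paste("PROVENANCE", e$provenance))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Covalent radii table for bond detection
#'
#' @param overrides Named numeric vector of per-element radius overrides in
#'   angstrom (e.g. `c(MG = 0.01)` to suppress all Mg bonds during hydrogen
#'   extension).
#' @return Object of class `covalent_radii`.
#' @export
covalent_radii <- function(overrides = numeric(0)) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
             S = 1.05, CL = 1.02, MG = 1.36, "NA" = 1.66, K = 2.03,
             CA = 1.76, FE = 1.32, ZN = 1.22, MN = 1.39)
  if (length(overrides)) {
    if (any(overrides <= 0)) stop("radii must be positive")
    radii[toupper(names(overrides))] <- overrides
  }
  structure(list(radii = radii, overrides = overrides),
            class = "covalent_radii")
}

.radius_for <- function(tab, element) {
  r <- tab$radii[toupper(element)]
  if (any(is.na(r))) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
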