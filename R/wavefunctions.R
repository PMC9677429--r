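# Atomic wavefunction tables: per-element Slater-type shells from which the
# spherically averaged core and valence densities of the pseudoatom model are
# built. The packaged table uses synthetic single-zeta shells with effective
# exponents in the Clementi-Raimondi style; the plain-text format accepts
# multi-primitive shells so other wavefunctions can be swapped in.

#' Construct an atomic wavefunction table
#'
#' @param elements Named list; each element is a data.frame with columns
#'   `label` (shell name), `n` (principal quantum number of the Slater
#'   primitive), `zeta` (exponent, 1/Bohr), `occ` (electron occupancy) and
#'   `role` ("core" or "valence").
#' @return Object of class `wavefunction_table`.
#' @export
wavefunction_table <- function(elements) {
  for (el in names(elements)) {
    sh <- elements[[el]]
    stopifnot(all(c("label", "n", "zeta", "occ", "role") %in% names(sh)))
    if (any(sh$zeta <= 0)) stop("non-positive Slater exponent for ", el)
    if (!all(sh$role %in% c("core", "valence"))) {
      stop("shell role must be 'core' or 'valence' for ", el)
    }
  }
  structure(list(elements = elements), class = "wavefunction_table")
}

#' @export
print.wavefunction_table <- function(x, ...) {
  cat("Wavefunction table:", length(x$elements), "elements (",
      paste(names(x$elements), collapse = ", "), ")\n")
  invisible(x)
}

# number of core/valence electrons for an element
.wf_electrons <- function(wf, element, role) {
  sh <- wf$elements[[toupper(element)]]
  if (is.null(sh)) stop("element ", element, " not in wavefunction table")
  sum(sh$occ[sh$role == role])
}

# Per-electron spherical density of one role as a primitive table
# (c0, m, a in atomic units). Shell orbital R(r) = N r^(n-1) e^(-zeta r);
# shell density occ * R^2 / (4 pi); normalized per electron.
.wf_density_prims <- function(wf, element, role) {
  sh <- wf$elements[[toupper(element)]]
  if (is.null(sh)) stop("element ", element, " not in wavefunction table")
  sh <- sh[sh$role == role, , drop = FALSE]
  nel <- sum(sh$occ)
  if (nel == 0) return(data.frame(c0 = numeric(), m = numeric(), a = numeric()))
  data.frame(
    c0 = sh$occ * .sto_norm(sh$n, sh$zeta)^2 / (4 * pi * nel),
    m = 2 * sh$n - 2,
    a = 2 * sh$zeta
  )
}

#' Read or write a wavefunction table file
#'
#' Plain-text format, one `ELEMENT <symbol>` line followed by
#' `SHELL <label> <n> <zeta> <occ> <role>` lines. Lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @return [read_wavefunctions()] returns a `wavefunction_table`.
#' @export
read_wavefunctions <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  elements <- list()
  cur <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(cur)) elements[[cur]] <<- do.call(rbind, rows)
  }
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "ELEMENT") {
      flush()
      cur <- toupper(tok[2])
      rows <- list()
    } else if (tok[1] == "SHELL") {
      rows[[length(rows) + 1]] <- data.frame(
        label = tok[2], n = as.integer(tok[3]), zeta = as.numeric(tok[4]),
        occ = as.numeric(tok[5]), role = tok[6])
    } else stop("unrecognized line in wavefunction file: ", ln)
  }
  flush()
  wavefunction_table(elements)
}

#' @rdname read_wavefunctions
#' @param wf A `wavefunction_table`.
#' @export
write_wavefunctions <- function(wf, path) {
  out <- c("# epmm wavefunction table v1",
           "# SHELL <label> <n> <zeta 1/Bohr> <occupancy> <core|valence>")
  for (el in names(wf$elements)) {
    out <- c(out, paste("ELEMENT", el))
    sh <- wf$elements[[el]]
    for (i in seq_len(nrow(sh))) {
      out <- c(out, sprintf("SHELL %s %d %.6f %g %s", sh$label[i], sh$n[i],
                            sh$zeta[i], sh$occ[i], sh$role[i]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Built-in synthetic wavefunction table
#'
#' Single-zeta Slater shells for H, C, N, O, P, S and Mg with effective
#' exponents in the Clementi-Raimondi style. These are synthetic fixture
#' values adequate for physically sane densities; they are not a published
#' multi-zeta atomic wavefunction set.
#'
#' @return A `wavefunction_table`.
#' @export
default_wavefunctions <- function() {
  if (!is.null(.epmm_cache$default_wf)) return(.epmm_cache$default_wf)
  sh <- function(...) {
    m <- matrix(c(...), ncol = 5, byrow = TRUE)
    data.frame(label = m[, 1], n = as.integer(m[, 2]),
               zeta = as.numeric(m[, 3]), occ = as.numeric(m[, 4]),
               role = m[, 5])
  }
  wf <- wavefunction_table(list(
    H = sh("1s", 1, 1.0000, 1, "valence"),
    C = sh("1s", 1, 5.6727, 2, "core",
           "2s", 2, 1.6083, 2, "valence",
           "2p", 2, 1.5679, 2, "valence"),
    N = sh("1s", 1, 6.6651, 2, "core",
           "2s", 2, 1.9237, 2, "valence",
           "2p", 2, 1.9170, 3, "valence"),
    O = sh("1s", 1, 7.6579, 2, "core",
           "2s", 2, 2.2458, 2, "valence",
           "2p", 2, 2.2266, 4, "valence"),
    P = sh("1s", 1, 14.5578, 2, "core",
           "2s", 2, 4.5100, 2, "core",
           "2p", 2, 4.9125, 6, "core",
           "3s", 3, 1.8806, 2, "valence",
           "3p", 3, 1.6288, 3, "valence"),
    S = sh("1s", 1, 15.5409, 2, "core",
           "2s", 2, 4.8802, 2, "core",
           "2p", 2, 5.3144, 6, "core",
           "3s", 3, 2.0364, 2, "valence",
           "3p", 3, 1.8273, 4, "valence"),
    MG = sh("1s", 1, 11.6089, 2, "core",
            "2s", 2, 3.6960, 2, "core",
            "2p", 2, 3.6810, 6, "core",
            "3s", 3, 1.1025, 2, "valence")
  ))
  .epmm_cache$default_wf <- wf
  wf
}

# nuclear charge by element symbol
.element_Z <- c(H = 1, HE = 2, LI = 3, BE = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, NE = 10, "NA" = 11, MG = 12, AL = 13, SI = 14, P = 15,
                S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26, ZN = 30)

.Z_for <- function(element) {
  z <- .element_Z[toupper(element)]
  if (is.na(z)) stop("unknown element: ", element)
  unname(z)
}
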