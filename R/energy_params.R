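# Embedded Turner-2004-style nearest-neighbor parameter set (kcal/mol, 37 C).
# The backend contract is three quantities -- structure energy, duplex energy,
# pair probabilities -- so an external folding engine can be swapped in by
# supplying the same interface.

.PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

# Stack free-energy increments, rows = outer pair (5' side of the helix),
# cols = directly stacked inner pair. Symmetrized on construction so that
# reading a helix from either strand gives the same energy.
.default_stack <- function() {
  m <- matrix(c(
    # inner:  AU     UA     GC     CG     GU     UG
    -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # outer AU
    -1.33, -0.93, -2.35, -2.11, -1.00, -1.27,  # outer UA
    -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,  # outer CG
    -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,  # outer GC
    -1.27, -1.36, -2.51, -2.11, -0.50,  1.29,  # outer GU
    -1.00, -0.55, -1.53, -1.41,  0.30, -0.50   # outer UG
  ), nrow = 6, byrow = TRUE,
  dimnames = list(.PAIR_NAMES[c(1, 2, 4, 3, 5, 6)], .PAIR_NAMES))
  m <- m[.PAIR_NAMES, ]  # reorder rows to AU UA GC CG GU UG
  # physical symmetry: stack(outer, inner) == stack(rev(inner), rev(outer))
  rev_idx <- c(2, 1, 4, 3, 6, 5)
  ms <- m
  for (o in 1:6) for (i in 1:6) ms[o, i] <- (m[o, i] + m[rev_idx[i], rev_idx[o]]) / 2
  ms
}

.extrapolate_loop <- function(base, lxc, max_len = 30) {
  n0 <- length(base)
  lens <- seq_len(max_len)
  vals <- numeric(max_len)
  vals[seq_len(n0)] <- base
  if (max_len > n0)
    vals[(n0 + 1):max_len] <- base[n0] + lxc * log(lens[(n0 + 1):max_len] / n0)
  vals
}

#' Nearest-neighbor energy parameters
#'
#' Builds the thermodynamic parameter set used by all energy computations:
#' stacking increments for the six allowed pair types (AU, UA, GC, CG, GU,
#' UG), length-indexed hairpin/bulge/interior-loop penalties with logarithmic
#' extrapolation, affine multiloop terms, a terminal AU/GU penalty, and the
#' duplex initiation term for the intermolecular (duplex-only) model.
#'
#' The shipped values are a Turner-2004-style set evaluated at 37 C. Terminal
#' AU/GU penalties are charged at every helix end adjacent to a non-stack loop
#' (hairpin closing pairs, both pairs of bulges/interior loops, multiloop
#' closing and branch pairs, exterior and duplex helix ends); this uniform rule
#' keeps the structure evaluator, the partition function and the duplex
#' dynamic program mutually consistent.
#'
#' @param temperature Temperature in kelvin (default 310.15, i.e. 37 C).
#' @param duplex_init Initiation term (kcal/mol) of the duplex-only model.
#'   Defaults to 0 because the interaction initiation cost enters the total
#'   energy once, as `dG_initiation` (4.1 kcal/mol) in [total_energy()].
#' @param max_loop_span Maximum total unpaired length of a bulge/interior loop
#'   considered by the folding recursions (default 30).
#' @return An object of class `energy_params` (a named list).
#' @examples
#' p <- energy_params()
#' p$stack["GC", "GC"]
#' @export
energy_params <- function(temperature = 310.15, duplex_init = 0,
                          max_loop_span = 30L) {
  stopifnot(temperature > 0)
  rt <- 0.0019872 * temperature
  lxc <- 1.75 * rt
  hairpin <- .extrapolate_loop(
    c(99, 99, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4, 6.5), lxc)
  bulge <- .extrapolate_loop(c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4), lxc)
  internal <- .extrapolate_loop(
    c(99, 1.5, 1.6, 1.7, 2.0, 2.0, 2.2, 2.3, 2.4, 2.5), lxc)
  structure(list(
    temperature = temperature,
    rt = rt,
    stack = .default_stack(),
    hairpin = hairpin,
    bulge = bulge,
    internal = internal,
    lxc = lxc,
    ml_close = 3.4,
    ml_branch = 0.4,
    ml_unpaired = 0.0,
    terminal_au = 0.5,
    duplex_init = duplex_init,
    max_loop = as.integer(max_loop_span)
  ), class = "energy_params")
}

.check_params <- function(params) {
  if (!inherits(params, "energy_params")) stop("`params` must be energy_params")
  stopifnot(
    is.matrix(params$stack), all(dim(params$stack) == c(6, 6)),
    all(is.finite(params$stack)), all(is.finite(params$hairpin[-(1:2)])),
    params$temperature > 0
  )
  invisible(params)
}

# plain list consumed by the C++ backend
.cpp_params <- function(params) {
  list(rt = params$rt, stack = unname(params$stack),
       hairpin = params$hairpin, bulge = params$bulge,
       internal = params$internal, lxc = params$lxc,
       ml_close = params$ml_close, ml_branch = params$ml_branch,
       ml_unpaired = params$ml_unpaired, terminal_au = params$terminal_au,
       duplex_init = params$duplex_init, max_loop = params$max_loop)
}

#' Write energy parameters to a plain-text file
#'
#' The format is line-oriented: `key value` scalars, a `stack` section with a
#' 6x6 whitespace-separated matrix (rows/cols ordered AU UA GC CG GU UG), and
#' `hairpin`/`bulge`/`internal` sections with one penalty per length.
#'
#' @param params An `energy_params` object.
#' @param path Output file path.
#' @export
write_energy_params <- function(params, path) {
  .check_params(params)
  con <- file(path, "w")
  on.exit(close(con))
  scalars <- c("temperature", "ml_close", "ml_branch", "ml_unpaired",
               "terminal_au", "duplex_init", "max_loop")
  for (s in scalars)
    writeLines(paste(s, format(params[[s]], digits = 12)), con)
  writeLines("stack", con)
  for (i in 1:6)
    writeLines(paste(format(params$stack[i, ], digits = 12), collapse = " "), con)
  for (tab in c("hairpin", "bulge", "internal")) {
    writeLines(tab, con)
    writeLines(paste(format(params[[tab]], digits = 12), collapse = " "), con)
  }
  invisible(path)
}

#' Read energy parameters from the plain-text format
#'
#' @param path File written by [write_energy_params()].
#' @return An `energy_params` object.
#' @export
read_energy_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  params <- energy_params()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tok[1]
    if (key == "stack") {
      m <- matrix(NA_real_, 6, 6, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))
      for (r in 1:6)
        m[r, ] <- as.numeric(strsplit(trimws(lines[i + r]), "\\s+")[[1]])
      params$stack <- m
      i <- i + 7
    } else if (key %in% c("hairpin", "bulge", "internal")) {
      params[[key]] <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
      i <- i + 2
    } else {
      val <- as.numeric(tok[2])
      if (key == "temperature") {
        params$temperature <- val
        params$rt <- 0.0019872 * val
        params$lxc <- 1.75 * params$rt
      } else if (key == "max_loop") {
        params$max_loop <- as.integer(val)
      } else {
        params[[key]] <- val
      }
      i <- i + 1
    }
  }
  .check_params(params)
  params
}

# ---- internal pair-type helpers shared across modules ----

.ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# pair type index 1..6 (order AU UA GC CG GU UG) or NA
.pair_type_chr <- function(a, b) {
  match(paste0(a, b), .ALLOWED_PAIRS)
}

.is_au_gu <- function(type_idx) type_idx %in% c(1L, 2L, 5L, 6L)

.au_penalty <- function(params, type_idx) {
  ifelse(.is_au_gu(type_idx), params$terminal_au, 0)
}

.loop_tab <- function(tab, len, lxc) {
  m <- length(tab)
  ifelse(len <= m, tab[pmax(len, 1L)], tab[m] + lxc * log(len / m))
}

# loop between outer pair (t_out) and enclosed pair (t_in); gaps g1, g2
.interior_loop_r <- function(params, t_out, t_in, g1, g2) {
  if (g1 == 0 && g2 == 0) return(params$stack[t_out, t_in])
  e <- if (g1 == 0 || g2 == 0) .loop_tab(params$bulge, g1 + g2, params$lxc)
       else .loop_tab(params$internal, g1 + g2, params$lxc)
  e + .au_penalty(params, t_out) + .au_penalty(params, t_in)
}
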