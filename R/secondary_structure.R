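#' Intramolecular secondary structure (base-pair set)
#'
#' A non-crossing set of base pairs over one RNA sequence. Invariants enforced:
#' each position in at most one pair, every pair one of AU/UA/GC/CG/GU/UG,
#' hairpin loops enclose at least three unpaired nucleotides (j - i >= 4), and
#' no two pairs cross (pseudoknot-free).
#'
#' @param pairs Two-column matrix of 1-based positions (i, j); zero rows give
#'   the open structure.
#' @param seq The `rna_sequence` (or string) the pairs refer to.
#' @return An object of class `secondary_structure`.
#' @examples
#' s <- rna_sequence("GGGAAAUCCC")
#' secondary_structure(cbind(1:3, 10:8), s)
#' @export
secondary_structure <- function(pairs, seq) {
  seq <- .as_rna_sequence(seq)
  n <- length(seq)
  if (is.null(pairs) || length(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0) {
    ij <- t(apply(pairs, 1, sort))
    pairs <- ij[order(ij[, 1]), , drop = FALSE]
    if (any(pairs < 1) || any(pairs > n))
      stop("pair index outside the sequence (length ", n, ")")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("position ", idx[duplicated(idx)][1], " appears in more than one pair")
    types <- .pair_type_chr(seq$residues[pairs[, 1]], seq$residues[pairs[, 2]])
    if (anyNA(types)) {
      k <- which(is.na(types))[1]
      stop("disallowed pair ", seq$residues[pairs[k, 1]], "-",
           seq$residues[pairs[k, 2]], " at (", pairs[k, 1], ",", pairs[k, 2], ")")
    }
    if (any(pairs[, 2] - pairs[, 1] < 4)) {
      k <- which(pairs[, 2] - pairs[, 1] < 4)[1]
      stop("hairpin loop with fewer than 3 unpaired nucleotides at (",
           pairs[k, 1], ",", pairs[k, 2], ")")
    }
    if (nrow(pairs) > 1) {
      for (a in seq_len(nrow(pairs) - 1)) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        b <- (a + 1):nrow(pairs)
        k <- pairs[b, 1]; l <- pairs[b, 2]
        if (any(i < k & k < j & j < l))
          stop("crossing base pairs (pseudoknot) detected")
      }
    }
  }
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, n = n, seq_id = seq$id),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> ", x$seq_id, ": ", nrow(x$pairs), " pairs over ",
      x$n, " nt\n", sep = "")
  invisible(x)
}

# mate vector: mate[i] = j if (i,j) paired, else 0
.mate_vector <- function(structure) {
  mate <- integer(structure$n)
  p <- structure$pairs
  if (nrow(p) > 0) {
    mate[p[, 1]] <- p[, 2]
    mate[p[, 2]] <- p[, 1]
  }
  mate
}

#' Parse a dot-bracket string into a secondary structure
#'
#' @param text Dot-bracket string using `.`, `(` and `)`, same length as the
#'   sequence.
#' @param seq The `rna_sequence` (or string) it annotates.
#' @return A `secondary_structure`.
#' @examples
#' parse_dotbracket("(((....)))", "GGGAAAUCCC")
#' @export
parse_dotbracket <- function(text, seq) {
  seq <- .as_rna_sequence(seq)
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  if (length(chars) != length(seq))
    stop("dot-bracket length ", length(chars), " != sequence length ",
         length(seq))
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0)
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1])
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0)
        stop("unbalanced ')' at position ", k)
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop("unbalanced '(' at position ", stack[length(stack)])
  secondary_structure(pairs, seq)
}

#' Render a secondary structure as a dot-bracket string
#' @param structure A `secondary_structure`.
#' @return Character scalar.
#' @export
format_dotbracket <- function(structure) {
  chars <- rep(".", structure$n)
  p <- structure$pairs
  if (nrow(p) > 0) {
    chars[p[, 1]] <- "("
    chars[p[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Write a structure in CT (connect) format
#' @param structure A `secondary_structure`.
#' @param seq The underlying `rna_sequence`.
#' @param path Output path.
#' @param energy Optional energy annotation for the header line.
#' @export
write_ct <- function(structure, seq, path, energy = NA_real_) {
  seq <- .as_rna_sequence(seq)
  mate <- .mate_vector(structure)
  n <- structure$n
  hdr <- if (is.na(energy)) sprintf("%d %s", n, seq$id)
         else sprintf("%d ENERGY = %.2f %s", n, energy, seq$id)
  lines <- sprintf("%d %s %d %d %d %d", seq_len(n), seq$residues,
                   seq_len(n) - 1L, c(seq_len(n)[-1], 0L), mate, seq_len(n))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a structure from CT (connect) format
#' @param path CT file path.
#' @return A list with elements `seq` (`rna_sequence`) and `structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- do.call(rbind, strsplit(trimws(lines[2:(n + 1)]), "\\s+"))
  seq <- rna_sequence(paste(body[, 2], collapse = ""),
                      id = sub("^\\s*\\d+\\s+", "", lines[1]))
  mate <- as.integer(body[, 5])
  keep <- which(mate > seq_len(n))
  list(seq = seq,
       structure = secondary_structure(cbind(keep, mate[keep]), seq))
}
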