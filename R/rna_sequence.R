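#' RNA sequence with an optional translation-start anchor
#'
#' Validates and stores an RNA sequence over the alphabet A, C, G, U.
#' Thymine is converted to uracil on input (with a message, so DNA-style
#' records read cleanly). An optional 0-based `start_codon_offset` marks the A
#' of the AUG start codon and enables start-codon-relative display coordinates:
#' positions count ..., -2, -1, +1, +2, ... with +1 = A of AUG and no
#' position 0, the convention used for sRNA target sites in 5' UTRs.
#'
#' @param seq Character scalar, the sequence (case-insensitive; T allowed).
#' @param id Sequence identifier.
#' @param start_codon_offset Optional 0-based index of the A of the start
#'   codon; must lie within the sequence.
#' @return An object of class `rna_sequence`.
#' @examples
#' rna_sequence("GGGAAAUCCC", id = "hp")
#' @export
rna_sequence <- function(seq, id = "seq", start_codon_offset = NULL) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  s <- toupper(gsub("\\s", "", seq))
  if (grepl("T", s, fixed = TRUE)) {
    message("sequence '", id, "': T converted to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0)
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "'")
  if (!is.null(start_codon_offset)) {
    start_codon_offset <- as.integer(start_codon_offset)
    if (start_codon_offset < 0 || start_codon_offset >= length(chars))
      stop("start_codon_offset outside the sequence")
  }
  structure(list(
    id = id,
    seq = s,
    residues = chars,
    codes = match(chars, c("A", "C", "G", "U")) - 1L,
    start_codon_offset = start_codon_offset
  ), class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("<rna_sequence> ", x$id, " (", length(x$residues), " nt)\n", sep = "")
  cat(x$seq, "\n")
  if (!is.null(x$start_codon_offset))
    cat("start codon at 0-based offset ", x$start_codon_offset, "\n", sep = "")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) length(x$residues)

.as_rna_sequence <- function(x, arg = "seq") {
  if (inherits(x, "rna_sequence")) return(x)
  if (is.character(x) && length(x) == 1) return(rna_sequence(x))
  stop("`", arg, "` must be an rna_sequence or a single sequence string")
}

#' Convert 1-based sequence positions to start-codon-relative coordinates
#'
#' With the anchor at the A of AUG, position anchors to +1; upstream positions
#' are negative with no position 0 (..., -2, -1, +1, +2, ...).
#'
#' @param seq An `rna_sequence` with `start_codon_offset` set.
#' @param pos Integer vector of 1-based sequence positions.
#' @return Integer vector of signed display coordinates (NA if no anchor).
#' @examples
#' m <- rna_sequence("CCCCCAUGGC", start_codon_offset = 5)
#' codon_relative(m, c(4, 5, 6, 8))  # -2 -1 +1 +3
#' @export
codon_relative <- function(seq, pos) {
  seq <- .as_rna_sequence(seq)
  if (is.null(seq$start_codon_offset)) return(rep(NA_integer_, length(pos)))
  rel0 <- (pos - 1L) - seq$start_codon_offset
  ifelse(rel0 >= 0, rel0 + 1L, rel0)
}

#' Reverse complement of an RNA sequence string
#' @param seq Character scalar over A/C/G/U.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-record, U/T tolerant. Parsing is delegated to Biostrings.
#'
#' @param path FASTA file path.
#' @return A named list of `rna_sequence` objects.
#' @export
read_rna_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    rna_sequence(as.character(set[[i]]), id = names(set)[i])
  })
  names(out) <- names(set)
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs A list of `rna_sequence` objects (or one object).
#' @param path Output path.
#' @export
write_rna_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  set <- Biostrings::RNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
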