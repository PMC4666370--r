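#' Free energy of an intramolecular secondary structure
#'
#' Nearest-neighbor evaluation by loop decomposition: helical stack
#' increments, hairpin/bulge/interior-loop penalties, affine multiloop terms
#' and terminal AU/GU penalties. The open structure scores 0 and the sum is
#' additive over independent exterior-loop substructures.
#'
#' @param seq An `rna_sequence` (or string).
#' @param structure A `secondary_structure` valid for `seq`.
#' @param params An [energy_params()] set.
#' @return Free energy in kcal/mol.
#' @examples
#' s <- rna_sequence("GGGAAAUCCC")
#' structure_energy(s, parse_dotbracket("(((....)))", s))
#' @export
structure_energy <- function(seq, structure, params = energy_params()) {
  seq <- .as_rna_sequence(seq)
  .check_params(params)
  if (!inherits(structure, "secondary_structure"))
    stop("`structure` must be a secondary_structure")
  if (structure$n != length(seq))
    stop("structure was built for a sequence of length ", structure$n,
         ", not ", length(seq))
  if (nrow(structure$pairs) == 0) return(0)
  eval_structure_cpp(seq$codes, .mate_vector(structure), .cpp_params(params))
}

.validate_duplex_pairs <- function(srna, mrna, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) return(pairs)
  if (any(pairs[, 1] < 1) || any(pairs[, 1] > length(srna)) ||
      any(pairs[, 2] < 1) || any(pairs[, 2] > length(mrna)))
    stop("duplex pair index outside a sequence")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("a position participates in more than one duplex pair")
  if (nrow(pairs) > 1 && any(diff(pairs[, 2]) >= 0))
    stop("duplex pairing must be antiparallel monotone (crossing pairs)")
  types <- .pair_type_chr(srna$residues[pairs[, 1]], mrna$residues[pairs[, 2]])
  if (anyNA(types)) {
    k <- which(is.na(types))[1]
    stop("disallowed duplex pair ", srna$residues[pairs[k, 1]], "-",
         mrna$residues[pairs[k, 2]])
  }
  pairs
}

#' Free energy of an intermolecular duplex
#'
#' Evaluates a monotone (non-crossing, antiparallel) intermolecular pairing
#' under the duplex-only model: `duplex_init` + stacks + bulge/interior-loop
#' penalties + terminal AU/GU penalties at both duplex ends and at both pairs
#' flanking each non-stack loop. No multiloops exist in a duplex.
#'
#' @param srna_seq,mrna_seq `rna_sequence` objects (or strings).
#' @param duplex_pairs Two-column matrix: sRNA position, mRNA position. The
#'   sRNA positions must increase while mRNA positions decrease.
#' @param params An [energy_params()] set.
#' @return Free energy in kcal/mol (`duplex_init` alone for an empty pairing).
#' @export
duplex_energy <- function(srna_seq, mrna_seq, duplex_pairs,
                          params = energy_params()) {
  srna <- .as_rna_sequence(srna_seq, "srna_seq")
  mrna <- .as_rna_sequence(mrna_seq, "mrna_seq")
  .check_params(params)
  pairs <- .validate_duplex_pairs(srna, mrna, duplex_pairs)
  if (nrow(pairs) == 0) return(params$duplex_init)
  types <- .pair_type_chr(srna$residues[pairs[, 1]], mrna$residues[pairs[, 2]])
  e <- params$duplex_init +
    .au_penalty(params, types[1]) +
    .au_penalty(params, types[nrow(pairs)])
  if (nrow(pairs) > 1) {
    for (k in seq_len(nrow(pairs) - 1)) {
      g1 <- pairs[k + 1, 1] - pairs[k, 1] - 1L
      g2 <- pairs[k, 2] - pairs[k + 1, 2] - 1L
      if (g1 > params$max_loop || g2 > params$max_loop)
        stop("duplex interior loop exceeds max_loop_span")
      e <- e + .interior_loop_r(params, types[k], types[k + 1], g1, g2)
    }
  }
  e
}
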