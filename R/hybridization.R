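.render_alignment <- function(srna, mrna, pairs) {
  # three-line rendering: sRNA 5'->3' on top, mRNA 3'->5' below
  np <- nrow(pairs)
  top <- character(0); mid <- character(0); bot <- character(0)
  for (k in seq_len(np)) {
    if (k > 1) {
      g1 <- pairs[k, 1] - pairs[k - 1, 1] - 1L
      g2 <- pairs[k - 1, 2] - pairs[k, 2] - 1L
      g <- max(g1, g2)
      if (g > 0) {
        sgap <- if (g1 > 0) srna$residues[(pairs[k - 1, 1] + 1):(pairs[k, 1] - 1)] else character(0)
        mgap <- if (g2 > 0) mrna$residues[(pairs[k, 2] + 1):(pairs[k - 1, 2] - 1)] else character(0)
        top <- c(top, c(sgap, rep("-", g - g1)))
        mid <- c(mid, rep(" ", g))
        bot <- c(bot, c(rev(mgap), rep("-", g - g2)))
      }
    }
    a <- srna$residues[pairs[k, 1]]
    b <- mrna$residues[pairs[k, 2]]
    top <- c(top, a)
    mid <- c(mid, if (paste0(a, b) %in% c("GU", "UG")) ":" else "|")
    bot <- c(bot, b)
  }
  paste0("5' ", paste(top, collapse = ""), " 3'\n",
         "   ", paste(mid, collapse = ""), "   \n",
         "3' ", paste(bot, collapse = ""), " 5'")
}

#' Predict intermolecular hybrids between an sRNA window and an mRNA
#'
#' Dynamic program over duplex states only (stacks, bulges and interior loops
#' with per-side spans at most `max_loop`; no intramolecular pairs, no
#' branching). Returns the minimum-free-energy hybrid plus up to
#' `n_suboptimal` non-redundant alternatives (mRNA-interval overlap with any
#' better hybrid below 50%), sorted by `dG_hybrid` ascending. Only
#' energetically favorable duplexes (`dG_hybrid < 0`) are reported; an empty
#' result is not an error. Equal-energy ties break deterministically: smaller
#' mRNA start, then smaller sRNA start, then fewer pairs.
#'
#' @param srna An `rna_sequence` (or string); the sRNA.
#' @param mrna An `rna_sequence` (or string); the target mRNA (typically the
#'   5' UTR plus early ORF). If its `start_codon_offset` is set, coordinates
#'   are also reported start-codon-relative.
#' @param window Optional `c(start, end)` 1-based interval restricting the
#'   sRNA to its accessible search window (default: whole sRNA).
#' @param params An [energy_params()] set.
#' @param max_loop Per-side bulge/interior-loop cap in the duplex (default 15).
#' @param n_suboptimal Maximum number of suboptimal hybrids (default 10).
#' @param seed_region Optional `c(start, end)` on the sRNA (the unextended
#'   seed); retained hybrids must pair at least `min_overlap_with_seed`
#'   nucleotides inside it.
#' @param min_overlap_with_seed Minimum seed overlap in nt (default 1;
#'   ignored when `seed_region` is NULL).
#' @param overlap_frac Redundancy threshold on mRNA intervals (default 0.5).
#' @return A tibble, one row per hybrid: sRNA/mRNA intervals (plus
#'   start-codon-relative mRNA coordinates when anchored), `dG_hybrid`,
#'   `n_pairs`, a `pairs` list-column of 2-column matrices and an `alignment`
#'   text rendering.
#' @export
hybridize <- function(srna, mrna, window = NULL, params = energy_params(),
                      max_loop = 15L, n_suboptimal = 10L, seed_region = NULL,
                      min_overlap_with_seed = 1L, overlap_frac = 0.5) {
  srna <- .as_rna_sequence(srna, "srna")
  mrna <- .as_rna_sequence(mrna, "mrna")
  .check_params(params)
  if (is.null(window)) window <- c(1L, length(srna))
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 1 || window[2] > length(srna))
    stop("`window` must be a non-empty interval within the sRNA")
  offset <- window[1] - 1L
  codes <- srna$codes[window[1]:window[2]]
  if (is.null(seed_region)) {
    seed_lo <- 0L; seed_hi <- 0L; min_seed <- 0L
  } else {
    seed_lo <- as.integer(seed_region[1]) - offset
    seed_hi <- as.integer(seed_region[2]) - offset
    min_seed <- as.integer(min_overlap_with_seed)
  }
  hits <- hybrid_cpp(codes, mrna$codes, .cpp_params(params),
                     as.integer(max_loop), as.integer(n_suboptimal),
                     overlap_frac, seed_lo, seed_hi, min_seed)
  if (length(hits) == 0) {
    return(tibble(srna_start = integer(0), srna_end = integer(0),
                  mrna_start = integer(0), mrna_end = integer(0),
                  mrna_start_rel = integer(0), mrna_end_rel = integer(0),
                  dG_hybrid = numeric(0), n_pairs = integer(0),
                  pairs = list(), alignment = character(0)))
  }
  rows <- lapply(hits, function(h) {
    pairs <- h$pairs
    pairs[, 1] <- pairs[, 1] + offset
    alignment_txt <- .render_alignment(srna, mrna, pairs)
    tibble(
      srna_start = min(pairs[, 1]), srna_end = max(pairs[, 1]),
      mrna_start = min(pairs[, 2]), mrna_end = max(pairs[, 2]),
      mrna_start_rel = codon_relative(mrna, min(pairs[, 2])),
      mrna_end_rel = codon_relative(mrna, max(pairs[, 2])),
      dG_hybrid = h$dG_hybrid,
      n_pairs = nrow(pairs),
      pairs = list(pairs),
      alignment = alignment_txt
    )
  })
  bind_rows(rows)
}

#' Compensatory-mutation pairing analysis
#'
#' Recomputes the hybrid at a fixed mRNA site for all four wild-type/mutant
#' combinations. The interaction is called compensatory when both matched
#' combinations (wt:wt and mut:mut) hybridize below the favorability cutoff
#' while both mismatched combinations do not -- the in-silico analogue of a
#' reporter assay in which swapping both partners restores regulation.
#'
#' @param srna_wt,srna_mut,mrna_wt,mrna_mut `rna_sequence` objects (or
#'   strings); mutants must be equal-length substitutions of the wild types.
#' @param site `c(start, end)` 1-based interval on the mRNA to evaluate.
#' @param params An [energy_params()] set.
#' @param cutoff Favorability cutoff on `dG_hybrid` in kcal/mol (default -5).
#' @param max_loop Duplex loop cap (default 15).
#' @return A list with `table` (a 4-row tibble: srna, mrna, dG_hybrid and the
#'   best duplex per combination) and the logical `compensatory`.
#' @export
evaluate_mutant_pairing <- function(srna_wt, srna_mut, mrna_wt, mrna_mut,
                                    site, params = energy_params(),
                                    cutoff = -5, max_loop = 15L) {
  srna_wt <- .as_rna_sequence(srna_wt, "srna_wt")
  srna_mut <- .as_rna_sequence(srna_mut, "srna_mut")
  mrna_wt <- .as_rna_sequence(mrna_wt, "mrna_wt")
  mrna_mut <- .as_rna_sequence(mrna_mut, "mrna_mut")
  if (length(srna_wt) != length(srna_mut))
    stop("length-changing sRNA mutations are unsupported")
  if (length(mrna_wt) != length(mrna_mut))
    stop("length-changing mRNA mutations are unsupported")
  site <- as.integer(site)
  stopifnot(length(site) == 2, site[1] >= 1, site[2] <= length(mrna_wt),
            site[1] <= site[2])
  combos <- expand.grid(srna = c("wt", "mut"), mrna = c("wt", "mut"),
                        stringsAsFactors = FALSE)
  srnas <- list(wt = srna_wt, mut = srna_mut)
  mrnas <- list(wt = mrna_wt, mut = mrna_mut)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    s <- srnas[[combos$srna[k]]]
    m <- mrnas[[combos$mrna[k]]]
    msite <- rna_sequence(paste(m$residues[site[1]:site[2]], collapse = ""),
                          id = paste0(m$id, "_site"))
    h <- hybridize(s, msite, params = params, max_loop = max_loop,
                   n_suboptimal = 0L)
    tibble(srna = combos$srna[k], mrna = combos$mrna[k],
           dG_hybrid = if (nrow(h) > 0) h$dG_hybrid[1] else 0,
           duplex = list(if (nrow(h) > 0) h[1, ] else NULL))
  })
  tab <- bind_rows(rows)
  g <- function(s, m) tab$dG_hybrid[tab$srna == s & tab$mrna == m]
  compensatory <- g("wt", "wt") < cutoff && g("mut", "mut") < cutoff &&
    g("wt", "mut") >= cutoff && g("mut", "wt") >= cutoff
  list(table = tab, compensatory = compensatory, cutoff = cutoff)
}

#' Write hybrids as TSV
#' @param hybrids Tibble from [hybridize()].
#' @param path Output path.
#' @export
write_hybrids_tsv <- function(hybrids, path) {
  out <- hybrids[, setdiff(names(hybrids), c("pairs", "alignment"))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
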