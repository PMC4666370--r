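#' Hairpin loops of a structure as accessible regions
#'
#' A hairpin loop is the maximal unpaired run closed by a single pair. Loops
#' seed the search for intermolecular hybridization because single-stranded
#' regions facilitate the nucleation step of RNA:RNA interaction.
#'
#' @param structure A `secondary_structure`.
#' @param profile Optional single-strandedness profile used to annotate
#'   `mean_ss_prob` (NA otherwise).
#' @param source Provenance label recorded in the result (default "centroid").
#' @return A tibble with columns `start`, `end` (1-based inclusive), `length`,
#'   `mean_ss_prob`, `kind`, `source`, sorted by length descending.
#' @examples
#' find_hairpin_loops(parse_dotbracket("((((....))))", "GGGGAAAACCCC"))
#' @export
find_hairpin_loops <- function(structure, profile = NULL, source = "centroid") {
  stopifnot(inherits(structure, "secondary_structure"))
  mate <- .mate_vector(structure)
  p <- structure$pairs
  rows <- list()
  if (nrow(p) > 0) {
    for (k in seq_len(nrow(p))) {
      i <- p[k, 1]; j <- p[k, 2]
      inner <- if (j - i > 1) mate[(i + 1):(j - 1)] else integer(0)
      if (length(inner) > 0 && all(inner == 0))
        rows[[length(rows) + 1]] <- c(start = unname(i) + 1L,
                                      end = unname(j) - 1L)
    }
  }
  if (length(rows) == 0) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0),
                  mean_ss_prob = numeric(0), kind = character(0),
                  source = character(0)))
  }
  m <- do.call(rbind, rows)
  out <- tibble(
    start = as.integer(m[, "start"]),
    end = as.integer(m[, "end"]),
    length = as.integer(m[, "end"] - m[, "start"] + 1L),
    mean_ss_prob = vapply(seq_len(nrow(m)), function(r) {
      if (is.null(profile)) NA_real_
      else mean(profile[m[r, "start"]:m[r, "end"]])
    }, numeric(1)),
    kind = "hairpin_loop",
    source = source
  )
  arrange(out, desc(.data$length), .data$start)
}

#' Maximal single-stranded runs above a probability threshold
#'
#' @param profile Numeric single-strandedness profile in `[0,1]`.
#' @param threshold Minimum per-position probability (default 0.5).
#' @param min_len Minimum run length (default 4).
#' @return A tibble of disjoint maximal regions (same columns as
#'   [find_hairpin_loops()], `kind = "free_run"`).
#' @export
find_free_runs <- function(profile, threshold = 0.5, min_len = 4L) {
  stopifnot(is.numeric(profile))
  ok <- profile >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length = as.integer(r$lengths[keep]),
    mean_ss_prob = vapply(keep, function(k) {
      mean(profile[starts[k]:ends[k]])
    }, numeric(1)),
    kind = "free_run",
    source = "profile"
  )
}

#' Extend an accessible region into a hybridization search window
#'
#' Hybridization can elongate beyond the site of nucleation, so the seed
#' region is widened by upstream/downstream flanks, clipped to the sequence.
#'
#' @param region One-row tibble (or list) with `start` and `end`.
#' @param upstream_flank,downstream_flank Non-negative flank sizes in nt.
#' @param seq_len Sequence length for clipping.
#' @return The region with widened coordinates and `source` suffixed with
#'   `"+extended"`; `kind` is preserved.
#' @examples
#' r <- tibble::tibble(start = 37L, end = 51L, kind = "hairpin_loop",
#'                     source = "centroid")
#' extend_region(r, 9, 17, 90)  # 28..68
#' @export
extend_region <- function(region, upstream_flank, downstream_flank, seq_len) {
  stopifnot(upstream_flank >= 0, downstream_flank >= 0)
  region <- as_tibble(as.list(region)[c("start", "end",
                                        intersect(names(region),
                                                  c("kind", "source")))])
  region$start <- max(1L, as.integer(region$start - upstream_flank))
  region$end <- min(as.integer(seq_len), as.integer(region$end + downstream_flank))
  region$length <- region$end - region$start + 1L
  if ("source" %in% names(region))
    region$source <- paste0(region$source, "+extended")
  region
}

#' Select the hybridization seed region of an sRNA
#'
#' Seed-source precedence: hairpin loops of the selected centroid first (the
#' largest loop wins); maximal single-stranded runs of the empirical profile
#' are the fallback when no centroid hairpin loop reaches `min_len`.
#'
#' @param ensemble A `structure_ensemble` of the sRNA.
#' @param centroid Optional pre-computed centroid structure.
#' @param threshold Single-strandedness threshold for the fallback (0.5).
#' @param min_len Minimum seed length (default 4).
#' @param params Energy parameters (for centroid annotation).
#' @return A one-row tibble region, or a zero-row tibble if nothing qualifies.
#' @export
select_seed_region <- function(ensemble, centroid = NULL, threshold = 0.5,
                               min_len = 4L, params = energy_params()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(centroid)) centroid <- centroid_structure(ensemble, params = params)
  loops <- find_hairpin_loops(centroid, profile = ensemble$ss_profile)
  loops <- loops[loops$length >= min_len, , drop = FALSE]
  if (nrow(loops) > 0) return(loops[1, ])
  runs <- find_free_runs(ensemble$ss_profile, threshold, min_len)
  if (nrow(runs) > 0) return(runs[order(-runs$length), ][1, ])
  runs
}

#' Write accessible regions as BED (0-based half-open)
#' @param regions Tibble from [find_hairpin_loops()] or [find_free_runs()].
#' @param seq_id Sequence identifier for the first BED column.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, seq_id, path) {
  bed <- data.frame(chrom = seq_id, start = regions$start - 1L,
                    end = regions$end, name = regions$kind,
                    score = ifelse(is.na(regions$mean_ss_prob), 0,
                                   round(1000 * regions$mean_ss_prob)),
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
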