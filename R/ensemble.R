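#' Partition function of the secondary-structure ensemble
#'
#' McCaskill-style O(n^3) inside recursion consistent with
#' [structure_energy()]: over all pseudoknot-free structures (bulge/interior
#' loops capped at `max_loop_span`), with the open chain as reference state
#' (weight 1), so Z >= 1.
#'
#' @param seq An `rna_sequence` (or string).
#' @param params An [energy_params()] set.
#' @param max_len Capacity guard on sequence length (default 2000).
#' @return A `partition_summary`: list with `Z` and `ensemble_free_energy`
#'   (-RT log Z, kcal/mol).
#' @examples
#' partition_function("AAAA")      # Z = 1
#' @export
partition_function <- function(seq, params = energy_params(), max_len = 2000L) {
  seq <- .as_rna_sequence(seq)
  .check_params(params)
  if (length(seq) > max_len)
    stop("sequence length ", length(seq), " exceeds capacity (", max_len, ")")
  out <- partition_cpp(seq$codes, .cpp_params(params))
  structure(out, class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("<partition_summary> Z = ", format(x$Z, digits = 6),
      ", ensemble free energy = ", sprintf("%.3f", x$ensemble_free_energy),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Sample a Boltzmann-weighted structure ensemble
#'
#' Draws `n` independent stochastic tracebacks from the partition function, so
#' empirical structure frequencies converge to exp(-E/RT)/Z. A sample of 1000
#' structures reproduces the major structural characteristics of the
#' ensemble; identical seeds give identical ensembles on any platform (the
#' traceback uses an integer-state RNG and branches on cumulative sums in a
#' fixed order, ties resolved toward smaller indices).
#'
#' @param seq An `rna_sequence` (or string).
#' @param params An [energy_params()] set.
#' @param n Sample size (default 1000).
#' @param seed Integer seed (required; no hidden global seed is consulted).
#' @param max_len Capacity guard on sequence length.
#' @return A `structure_ensemble`: sampled structures, per-structure energies,
#'   empirical pair-probability matrix and single-strandedness profile.
#' @export
sample_structures <- function(seq, params = energy_params(), n = 1000L, seed,
                              max_len = 2000L) {
  seq <- .as_rna_sequence(seq)
  .check_params(params)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be a positive integer")
  if (missing(seed)) stop("`seed` is required")
  if (length(seq) > max_len)
    stop("sequence length ", length(seq), " exceeds capacity (", max_len, ")")
  raw <- sample_cpp(seq$codes, .cpp_params(params), n, as.integer(seed))
  structures <- lapply(raw, secondary_structure, seq = seq)
  energies <- vapply(structures, function(st) structure_energy(seq, st, params),
                     numeric(1))
  nn <- length(seq)
  counts <- matrix(0, nn, nn)
  for (st in structures) {
    p <- st$pairs
    if (nrow(p) > 0) {
      counts[p] <- counts[p] + 1
      counts[p[, c(2, 1), drop = FALSE]] <- counts[p[, c(2, 1), drop = FALSE]] + 1
    }
  }
  pair_prob <- counts / n
  structure(list(
    seq = seq,
    structures = structures,
    ensemble_energies = energies,
    n = n,
    seed = as.integer(seed),
    pair_prob = pair_prob,
    ss_profile = 1 - rowSums(pair_prob)
  ), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble> ", x$seq$id, ": ", x$n, " structures (seed ",
      x$seed, "), mean energy ", sprintf("%.2f", mean(x$ensemble_energies)),
      " kcal/mol\n", sep = "")
  invisible(x)
}

#' Exact base-pair probabilities
#'
#' McCaskill outside recursion over the same energy model, giving P(i,j) for
#' every allowed pair. The multiloop outside term makes this O(n^4); it is
#' intended for sRNA-scale molecules and capped at `max_len` nucleotides
#' (empirical probabilities from [sample_structures()] serve longer RNAs).
#'
#' @param seq An `rna_sequence` (or string).
#' @param params An [energy_params()] set.
#' @param max_len Capacity guard (default 300).
#' @return Symmetric n x n matrix of pair probabilities.
#' @export
pair_probabilities <- function(seq, params = energy_params(), max_len = 300L) {
  seq <- .as_rna_sequence(seq)
  .check_params(params)
  if (length(seq) > max_len)
    stop("exact pair probabilities capped at ", max_len, " nt")
  pairprob_cpp(seq$codes, .cpp_params(params))
}

#' Per-position single-strandedness profile
#'
#' For an ensemble, position i's value is the fraction of sampled structures
#' in which i is unpaired; for an exact pair-probability matrix it is
#' 1 - sum_j P(i,j). Both lie in \[0,1\] and agree in the limit of large
#' samples.
#'
#' @param x A `structure_ensemble` or a square pair-probability matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
ss_profile <- function(x, ...) UseMethod("ss_profile")

#' @rdname ss_profile
#' @export
ss_profile.structure_ensemble <- function(x, ...) x$ss_profile

#' @rdname ss_profile
#' @export
ss_profile.matrix <- function(x, ...) {
  stopifnot(nrow(x) == ncol(x))
  pmin(pmax(1 - rowSums(x), 0), 1)
}

.centroid_pairs <- function(pair_prob, threshold) {
  idx <- which(pair_prob > threshold & upper.tri(pair_prob), arr.ind = TRUE)
  unname(idx)
}

#' Centroid structure of an ensemble
#'
#' The structure formed by every base pair sampled with empirical probability
#' above `threshold`. For thresholds >= 0.5 the result is guaranteed
#' non-crossing (two crossing pairs cannot both occur in a majority of
#' structures); lower thresholds are accepted but a crossing result is
#' reported as a validity error.
#'
#' @param ensemble A `structure_ensemble` (or a list of clusters member; see
#'   [cluster_ensemble()]).
#' @param threshold Pair-probability threshold (default 0.5).
#' @param params Parameters used to annotate the centroid energy.
#' @return A `secondary_structure` with an `energy` attribute.
#' @export
centroid_structure <- function(ensemble, threshold = 0.5,
                               params = energy_params()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  pairs <- .centroid_pairs(ensemble$pair_prob, threshold)
  st <- secondary_structure(pairs, ensemble$seq)
  attr(st, "energy") <- structure_energy(ensemble$seq, st, params)
  st
}

.pair_keys <- function(st) {
  p <- st$pairs
  if (nrow(p) == 0) return(integer(0))
  p[, 1] * (st$n + 1L) + p[, 2]
}

#' Cluster a structure ensemble by base-pair distance
#'
#' Agglomerative (average-linkage) clustering under the symmetric-difference
#' metric on base-pair sets. The number of clusters is chosen by the largest
#' mean silhouette width over 2..`max_clusters`; a degenerate ensemble (all
#' structures identical) collapses to a single cluster. Per-cluster centroids
#' use the majority rule within the cluster. Clusters are ordered by size,
#' largest first.
#'
#' @param ensemble A `structure_ensemble` with at least `max_clusters` members.
#' @param max_clusters Maximum number of clusters to consider (default 5).
#' @param threshold Centroid pair-probability threshold (default 0.5).
#' @param params Parameters used to annotate centroid energies.
#' @return A list of clusters, each a list with `members` (indices into the
#'   ensemble) and `centroid` (a `secondary_structure`).
#' @export
cluster_ensemble <- function(ensemble, max_clusters = 5L, threshold = 0.5,
                             params = energy_params()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n <- ensemble$n
  if (n < max_clusters)
    stop("ensemble size must be at least max_clusters")
  keys <- lapply(ensemble$structures, .pair_keys)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    ka <- keys[[a]]
    for (b in (a + 1):n) {
      kb <- keys[[b]]
      d[a, b] <- d[b, a] <-
        length(ka) + length(kb) - 2L * sum(ka %in% kb)
    }
  }
  assign_k <- rep(1L, n)
  if (max(d) > 0) {
    hc <- hclust(as.dist(d), method = "average")
    best_k <- 1L
    best_sil <- -Inf
    for (k in 2:max_clusters) {
      cl <- cutree(hc, k = k)
      if (length(unique(cl)) < 2) next
      sil <- cluster::silhouette(cl, dmatrix = d)
      msil <- mean(sil[, "sil_width"])
      if (msil > best_sil) { best_sil <- msil; best_k <- k }
    }
    if (best_k > 1L) assign_k <- cutree(hc, k = best_k)
  }
  clusters <- lapply(sort(unique(assign_k)), function(k) {
    members <- which(assign_k == k)
    counts <- matrix(0, length(ensemble$seq$residues), length(ensemble$seq$residues))
    for (m in members) {
      p <- ensemble$structures[[m]]$pairs
      if (nrow(p) > 0) counts[p] <- counts[p] + 1
    }
    cp <- which(counts / length(members) > threshold, arr.ind = TRUE)
    centroid <- secondary_structure(unname(cp), ensemble$seq)
    attr(centroid, "energy") <- structure_energy(ensemble$seq, centroid, params)
    list(members = members, centroid = centroid)
  })
  clusters[order(-vapply(clusters, function(cl) length(cl$members), numeric(1)))]
}

#' Write an ensemble as multi-record dot-bracket with energy comments
#' @param ensemble A `structure_ensemble`.
#' @param path Output path.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", ensemble$seq$id, " n=", ensemble$n,
                    " seed=", ensemble$seed), con)
  writeLines(ensemble$seq$seq, con)
  for (k in seq_len(ensemble$n))
    writeLines(sprintf("%s # %.4f", format_dotbracket(ensemble$structures[[k]]),
                       ensemble$ensemble_energies[k]), con)
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#' @param path File path.
#' @return A `structure_ensemble` (empirical profiles recomputed).
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^>", "", lines[1])
  toks <- strsplit(hdr, "\\s+")[[1]]
  id <- toks[1]
  seed <- as.integer(sub("seed=", "", grep("^seed=", toks, value = TRUE)[1]))
  seq <- rna_sequence(lines[2], id = id)
  body <- lines[-(1:2)]
  db <- sub("\\s*#.*$", "", body)
  en <- as.numeric(sub("^.*#\\s*", "", body))
  structures <- lapply(db, parse_dotbracket, seq = seq)
  nn <- length(seq)
  counts <- matrix(0, nn, nn)
  for (st in structures) {
    p <- st$pairs
    if (nrow(p) > 0) {
      counts[p] <- counts[p] + 1
      counts[p[, c(2, 1), drop = FALSE]] <- counts[p[, c(2, 1), drop = FALSE]] + 1
    }
  }
  pair_prob <- counts / length(structures)
  structure(list(seq = seq, structures = structures, ensemble_energies = en,
                 n = length(structures), seed = seed, pair_prob = pair_prob,
                 ss_profile = 1 - rowSums(pair_prob)),
            class = "structure_ensemble")
}

#' Write a pair-probability matrix as TSV
#' @param pair_prob Square matrix.
#' @param path Output path.
#' @export
write_pair_prob <- function(pair_prob, path) {
  write.table(pair_prob, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
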