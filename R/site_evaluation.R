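#' Locally alter a structure to permit duplex formation
#'
#' Removes exactly those intramolecular base pairs with at least one endpoint
#' among the duplex-paired nucleotides (the footprint); every other pair is
#' untouched. This encodes the assumption that sRNA binding causes a local
#' structural alteration at the site of hybridization and no longer-range
#' rearrangement. The result can contain isolated pairs and remains a valid
#' structure.
#'
#' @param structure A `secondary_structure`.
#' @param footprint Integer vector of 1-based nucleotide positions paired in
#'   the duplex.
#' @return A `secondary_structure`.
#' @export
locally_alter <- function(structure, footprint) {
  stopifnot(inherits(structure, "secondary_structure"))
  footprint <- as.integer(footprint)
  if (any(footprint < 1) || any(footprint > structure$n))
    stop("footprint outside the sequence")
  p <- structure$pairs
  if (nrow(p) == 0) return(structure)
  keep <- !(p[, 1] %in% footprint | p[, 2] %in% footprint)
  out <- structure
  out$pairs <- p[keep, , drop = FALSE]
  out
}

#' Ensemble-averaged disruption energy at a hybridization footprint
#'
#' `dG_before` is the mean free energy of the sampled structures; `dG_after`
#' the mean energy after applying [locally_alter()] to each; the disruption
#' energy is their difference `dG_before - dG_after`. With this sign
#' convention the disruption term is non-positive whenever the removed pairs
#' contributed net stabilization; the subtraction in [total_energy()] turns it
#' back into a penalty, so do not negate it yourself.
#'
#' @param ensemble A `structure_ensemble`.
#' @param footprint Integer vector of duplex-paired nucleotide positions.
#' @param params An [energy_params()] set.
#' @return A `disruption_result`: list with `dG_before`, `dG_after`,
#'   `dG_disruption`, `n_structures`, `n_altered`.
#' @export
disruption_energy <- function(ensemble, footprint, params = energy_params()) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (ensemble$n < 1) stop("empty ensemble")
  before <- ensemble$ensemble_energies
  altered <- lapply(ensemble$structures, locally_alter, footprint = footprint)
  changed <- mapply(function(a, b) nrow(a$pairs) < nrow(b$pairs),
                    altered, ensemble$structures)
  after <- vapply(altered, function(st) {
    structure_energy(ensemble$seq, st, params)
  }, numeric(1))
  structure(list(
    dG_before = mean(before),
    dG_after = mean(after),
    dG_disruption = mean(before) - mean(after),
    n_structures = ensemble$n,
    n_altered = sum(changed)
  ), class = "disruption_result")
}

#' @export
print.disruption_result <- function(x, ...) {
  cat(sprintf("<disruption_result> before %.3f, after %.3f, disruption %.3f kcal/mol (%d/%d altered)\n",
              x$dG_before, x$dG_after, x$dG_disruption, x$n_altered,
              x$n_structures))
  invisible(x)
}

#' Total free-energy change of hybridization
#'
#' `dG_total = dG_initiation + dG_hybrid - (dG_T_disruption +
#' dG_S_disruption)`; the site is predicted functional when `dG_total < 0`
#' (strict: exactly zero is not favorable). The initiation term defaults to
#' 4.1 kcal/mol, the cost of initiating an interaction between two RNA
#' molecules.
#'
#' @param dG_hybrid Duplex free energy, kcal/mol.
#' @param dG_T_disruption,dG_S_disruption Disruption energies (before - after)
#'   of target mRNA and sRNA.
#' @param dG_initiation Interaction initiation energy (default 4.1).
#' @return List with `dG_total` and logical `favorable`.
#' @examples
#' total_energy(-20, 0, 0)  # -15.9, favorable
#' @export
total_energy <- function(dG_hybrid, dG_T_disruption, dG_S_disruption,
                         dG_initiation = 4.1) {
  stopifnot(is.finite(dG_hybrid), is.finite(dG_T_disruption),
            is.finite(dG_S_disruption), is.finite(dG_initiation))
  dG_total <- dG_initiation + dG_hybrid - (dG_T_disruption + dG_S_disruption)
  list(dG_total = dG_total, favorable = dG_total < 0)
}

.derive_seed <- function(master, k) {
  # small multiplicative hash; stays exact in double precision and < 2^31
  as.integer((as.numeric(master) * 69069 + k) %% 2147483647)
}

#' End-to-end sRNA target-site prediction
#'
#' The full pipeline: Boltzmann-sample structure ensembles for both molecules
#' (independent seeds derived from one master seed), locate the sRNA seed
#' region (largest centroid hairpin loop, single-stranded-run fallback),
#' extend it into the search window, predict hybrids against the mRNA, then
#' evaluate every candidate by its duplex energy, the ensemble-averaged
#' disruption energies of both molecules, and the total energy change.
#' Candidates are ranked by `dG_total` ascending and flagged `favorable` when
#' `dG_total < 0`.
#'
#' @param srna,mrna `rna_sequence` objects (or strings). The mRNA record is
#'   folded as given -- supply the 5' UTR plus early ORF region, not a whole
#'   transcript (a capacity error is raised beyond `max_len`).
#' @param seed Master integer seed; per-molecule sampling seeds are derived as
#'   `(seed * 69069 + k) mod (2^31 - 1)` with k = 1 (sRNA), 2 (mRNA).
#' @param params An [energy_params()] set.
#' @param n Ensemble sample size per molecule (default 1000).
#' @param flank_up,flank_down Flanks (nt) extending the seed region into the
#'   search window (defaults 9 and 17).
#' @param max_loop Duplex loop cap (default 15).
#' @param n_suboptimal Suboptimal hybrids to evaluate (default 10).
#' @param min_overlap_with_seed Required duplex overlap with the unextended
#'   seed, in paired nt (default 1).
#' @param dG_initiation Interaction initiation energy (default 4.1).
#' @param centroid_source `"ensemble"` (overall centroid, default) or
#'   `"largest_cluster"` (centroid of the largest structure cluster).
#' @param max_len Capacity guard on either sequence (default 2000).
#' @return A `site_prediction` object; `tidy()` gives the ranked site table,
#'   `glance()` a one-row summary.
#' @export
predict_sites <- function(srna, mrna, seed, params = energy_params(),
                          n = 1000L, flank_up = 9L, flank_down = 17L,
                          max_loop = 15L, n_suboptimal = 10L,
                          min_overlap_with_seed = 1L, dG_initiation = 4.1,
                          centroid_source = c("ensemble", "largest_cluster"),
                          max_len = 2000L) {
  srna <- .as_rna_sequence(srna, "srna")
  mrna <- .as_rna_sequence(mrna, "mrna")
  centroid_source <- match.arg(centroid_source)
  if (missing(seed)) stop("`seed` is required")
  seed_s <- .derive_seed(seed, 1)
  seed_m <- .derive_seed(seed, 2)
  ens_s <- sample_structures(srna, params, n = n, seed = seed_s,
                             max_len = max_len)
  ens_m <- sample_structures(mrna, params, n = n, seed = seed_m,
                             max_len = max_len)
  centroid <- if (centroid_source == "ensemble") {
    centroid_structure(ens_s, params = params)
  } else {
    cluster_ensemble(ens_s, params = params)[[1]]$centroid
  }
  seed_reg <- select_seed_region(ens_s, centroid = centroid, params = params)
  empty <- tibble(
    srna_start = integer(0), srna_end = integer(0), mrna_start = integer(0),
    mrna_end = integer(0), mrna_start_rel = integer(0),
    mrna_end_rel = integer(0), dG_hybrid = numeric(0),
    dG_T_disruption = numeric(0), dG_S_disruption = numeric(0),
    dG_initiation = numeric(0), dG_total = numeric(0), favorable = logical(0),
    n_pairs = integer(0), pairs = list(), alignment = character(0))
  if (nrow(seed_reg) == 0) {
    sites <- empty
    window <- integer(0)
  } else {
    window <- c(
      max(1L, seed_reg$start[1] - as.integer(flank_up)),
      min(length(srna), seed_reg$end[1] + as.integer(flank_down))
    )
    hybrids <- hybridize(srna, mrna, window = window, params = params,
                         max_loop = max_loop, n_suboptimal = n_suboptimal,
                         seed_region = c(seed_reg$start[1], seed_reg$end[1]),
                         min_overlap_with_seed = min_overlap_with_seed)
    if (nrow(hybrids) == 0) {
      sites <- empty
    } else {
      evals <- lapply(seq_len(nrow(hybrids)), function(k) {
        pr <- hybrids$pairs[[k]]
        dis_m <- disruption_energy(ens_m, pr[, 2], params)
        dis_s <- disruption_energy(ens_s, pr[, 1], params)
        tot <- total_energy(hybrids$dG_hybrid[k], dis_m$dG_disruption,
                            dis_s$dG_disruption, dG_initiation)
        mutate(hybrids[k, ],
               dG_T_disruption = dis_m$dG_disruption,
               dG_S_disruption = dis_s$dG_disruption,
               dG_initiation = dG_initiation,
               dG_total = tot$dG_total,
               favorable = tot$favorable)
      })
      sites <- arrange(bind_rows(evals), .data$dG_total, .data$mrna_start)
      sites <- sites[, names(empty)]
    }
  }
  structure(list(
    sites = sites,
    srna = srna, mrna = mrna,
    srna_ensemble = ens_s, mrna_ensemble = ens_m,
    centroid = centroid, seed_region = seed_reg, window = window,
    seed = as.integer(seed), seed_srna = seed_s, seed_mrna = seed_m,
    n = as.integer(n), dG_initiation = dG_initiation,
    params = params
  ), class = "site_prediction")
}

#' @export
print.site_prediction <- function(x, ...) {
  cat("<site_prediction> ", x$srna$id, " vs ", x$mrna$id, " (seed ", x$seed,
      ", n = ", x$n, ")\n", sep = "")
  if (nrow(x$sites) == 0) {
    cat("no candidate sites\n")
  } else {
    cat(sum(x$sites$favorable), " favorable of ", nrow(x$sites),
        " candidate site(s); best dG_total = ",
        sprintf("%.2f", x$sites$dG_total[1]), " kcal/mol\n", sep = "")
  }
  invisible(x)
}

#' Write a site-prediction report as JSON
#'
#' All energy terms, coordinates in both conventions, and the favorable flag,
#' one record per candidate site.
#'
#' @param prediction A `site_prediction`.
#' @param path Output path.
#' @export
write_sites_json <- function(prediction, path) {
  stopifnot(inherits(prediction, "site_prediction"))
  sites <- prediction$sites
  sites$pairs <- lapply(sites$pairs, function(m) {
    list(srna = m[, 1], mrna = m[, 2])
  })
  payload <- list(
    srna = prediction$srna$id,
    mrna = prediction$mrna$id,
    seed = prediction$seed,
    n = prediction$n,
    seed_region = as.list(prediction$seed_region[1, c("start", "end")]),
    window = prediction$window,
    dG_initiation = prediction$dG_initiation,
    sites = sites
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
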