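#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a site prediction into its ranked candidate table
#'
#' @param x A `site_prediction` from [predict_sites()].
#' @param ... Unused.
#' @return A tibble, one row per candidate site, ranked by `dG_total`.
#' @method tidy site_prediction
#' @export
tidy.site_prediction <- function(x, ...) {
  x$sites
}

#' One-row summary of a site prediction
#'
#' @param x A `site_prediction`.
#' @param ... Unused.
#' @return A one-row tibble: sequence ids, ensemble size, seed, number of
#'   candidate and favorable sites, and the best `dG_total`.
#' @method glance site_prediction
#' @export
glance.site_prediction <- function(x, ...) {
  tibble(
    srna = x$srna$id,
    mrna = x$mrna$id,
    n_sample = x$n,
    seed = x$seed,
    n_sites = nrow(x$sites),
    n_favorable = sum(x$sites$favorable),
    best_dG_total = if (nrow(x$sites) > 0) min(x$sites$dG_total) else NA_real_
  )
}

#' Tidy a structure ensemble into a per-position profile table
#'
#' @param x A `structure_ensemble`.
#' @param ... Unused.
#' @return A tibble with `position`, `residue` and `ss_prob`.
#' @method tidy structure_ensemble
#' @export
tidy.structure_ensemble <- function(x, ...) {
  tibble(
    position = seq_along(x$ss_profile),
    residue = x$seq$residues,
    ss_prob = x$ss_profile
  )
}

#' One-row summary of a structure ensemble
#'
#' @param x A `structure_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble with sample size, seed, mean/min energy and mean
#'   single-strandedness.
#' @method glance structure_ensemble
#' @export
glance.structure_ensemble <- function(x, ...) {
  tibble(
    id = x$seq$id,
    n_sample = x$n,
    seed = x$seed,
    mean_energy = mean(x$ensemble_energies),
    min_energy = min(x$ensemble_energies),
    mean_ss = mean(x$ss_profile)
  )
}
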