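# Seeded generators so every pipeline stage runs without downloads. All
# generators are pure functions of (parameters, seed): sequence scenarios use
# a package-local integer congruential stream; count tables save and restore
# the global RNG state around a set.seed() call.

.lcg_stream <- function(seed, n) {
  # Lehmer generator modulo 2^31 - 1, exact in double precision
  x <- (as.numeric(seed) %% 2147483646) + 1
  out <- numeric(n)
  for (k in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[k] <- x / 2147483647
  }
  out
}

#' Synthetic sRNA/mRNA pair with a planted accessible target site
#'
#' Emulates the geometry of a loop-seeded sRNA:mRNA interaction: a 90-nt-scale
#' sRNA carrying a designed GC stem whose hairpin loop (positions 37 to
#' 36 + `loop_len` for the default loop length) is the seed, and an mRNA whose
#' planted site is the exact reverse complement of that loop. The loop is
#' drawn from purines (A/G) so the site is pyrimidine-only and, in the
#' `"unstructured"` context (C-rich flanks), the site cannot base-pair
#' intramolecularly at all. The `"hairpin_occluded"` context additionally
#' embeds the reverse complement of the site downstream, locking the site
#' into a designed stable hairpin so the same duplex must pay a disruption
#' cost. A start codon downstream of the site anchors start-codon-relative
#' coordinates, as for a 5' UTR target.
#'
#' @param loop_len Seed loop length in nt (>= 4; default 15).
#' @param site_context `"unstructured"` or `"hairpin_occluded"`.
#' @param seed Integer seed; the construction is deterministic given the seed.
#' @return A `sequence_scenario`: list with `srna`, `mrna` (`rna_sequence`),
#'   the planted `site_start`/`site_end` and seed `loop_start`/`loop_end`
#'   (1-based), `site_context` and `seed`.
#' @export
make_sequence_scenario <- function(loop_len = 15L,
                                   site_context = c("unstructured",
                                                    "hairpin_occluded"),
                                   seed) {
  site_context <- match.arg(site_context)
  loop_len <- as.integer(loop_len)
  if (is.na(loop_len) || loop_len < 4)
    stop("`loop_len` must be at least 4")
  if (missing(seed)) stop("`seed` is required")
  u <- .lcg_stream(seed, loop_len)
  loop <- ifelse(u < 0.5, "A", "G")
  # no homotrimer runs: keeps the planted site free of U-runs that could pair
  # the mRNA's A flanks, and makes the duplex register essentially unique
  for (k in 3:loop_len) {
    if (loop[k] == loop[k - 1] && loop[k] == loop[k - 2])
      loop[k] <- if (loop[k] == "A") "G" else "A"
  }
  need_g <- ceiling(loop_len / 3)
  if (sum(loop == "G") < need_g)
    loop[seq(2, loop_len, by = 3)[seq_len(need_g)]] <- "G"
  loop <- paste(loop, collapse = "")
  stem5 <- "GGCGGCCG"
  stem3 <- reverse_complement(stem5)
  srna_seq <- paste0(strrep("A", 28), stem5, loop, stem3, strrep("A", 31))
  loop_start <- 28L + nchar(stem5) + 1L         # 37 for the default stem
  loop_end <- loop_start + loop_len - 1L
  srna <- rna_sequence(srna_seq, id = sprintf("synth_sRNA_seed%d", seed))
  site <- reverse_complement(loop)              # pyrimidine-only
  # mRNA flanks are adenine runs: the sRNA search window contains no U, so
  # nothing outside the planted site can hybridize with it
  flank5 <- strrep("A", 40)
  orf <- paste0("AUG", strrep("A", 18))
  if (site_context == "unstructured") {
    utr <- paste0(flank5, site, strrep("A", 6))
  } else {
    # the occluding arm sits more than a duplex loop-span away from the site,
    # so the same hybrid forms in both contexts and only the disruption
    # cost differs
    utr <- paste0(flank5, site, strrep("A", 16), reverse_complement(site),
                  strrep("A", 6))
  }
  mrna <- rna_sequence(paste0(utr, orf),
                       id = sprintf("synth_mRNA_%s_seed%d", site_context, seed),
                       start_codon_offset = nchar(utr))
  structure(list(
    srna = srna, mrna = mrna,
    site_start = 41L, site_end = 40L + loop_len,
    loop_start = loop_start, loop_end = loop_end,
    site_context = site_context, seed = as.integer(seed)
  ), class = "sequence_scenario")
}

#' @export
print.sequence_scenario <- function(x, ...) {
  cat("<sequence_scenario> seed ", x$seed, ", ", x$site_context,
      ": site ", x$site_start, "-", x$site_end, " on ", x$mrna$id,
      ", loop ", x$loop_start, "-", x$loop_end, " on ", x$srna$id, "\n",
      sep = "")
  invisible(x)
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic two-condition, two-assay differential table
#'
#' Generates a gene-level count experiment shaped like a paired
#' RNA-seq/Ribo-seq comparison of sRNA-expressing versus control cells:
#' negative-binomial counts around per-gene baseline means (log-normal
#' variation around `baseline_mean`) in `n_reps` replicates per condition and
#' assay. Planted repressed-translational targets shift the Ribo-seq assay
#' only; repressed-stability targets shift both assays; activated targets
#' shift Ribo-seq upward. Fold changes are reported sRNA-minus / sRNA-plus, so
#' repression gives positive log2 values. P-values come from a moment-based
#' Wald test on the replicate means with negative-binomial variance -- a
#' documented stand-in that exists to exercise the downstream classifier, not
#' to replicate a production differential-expression pipeline. Ground-truth
#' columns (`true_class`, `true_direction`, `true_base_mean`) are emitted so
#' downstream checks never re-derive the truth.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_repressed_translational,n_repressed_stability,n_activated Planted
#'   class sizes (disjoint; their sum must not exceed `n_genes`).
#' @param effect_log2 Planted absolute log2 effect size (default 2).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param baseline_mean Median per-gene baseline read count (default 500).
#' @param n_reps Replicates per condition per assay (default 2).
#' @param seed Integer seed.
#' @return A tibble with measurement columns (`gene`, `rna_log2fc`, `rna_p`,
#'   `ribo_log2fc`, `ribo_p`, `rna_reads`, `ribo_reads`) and truth columns.
#' @export
make_table_scenario <- function(n_genes = 500L, n_repressed_translational = 0L,
                                n_repressed_stability = 0L, n_activated = 0L,
                                effect_log2 = 2, nb_dispersion = 0.05,
                                baseline_mean = 500, n_reps = 2L, seed) {
  if (missing(seed)) stop("`seed` is required")
  n_genes <- as.integer(n_genes)
  n_planted <- n_repressed_translational + n_repressed_stability + n_activated
  if (n_planted > n_genes)
    stop("planted class sizes exceed n_genes")
  .with_seed(seed, {
    true_class <- rep("null", n_genes)
    idx <- seq_len(n_planted)
    true_class[idx] <- rep(c("repressed_translational", "repressed_stability",
                             "activated"),
                           c(n_repressed_translational, n_repressed_stability,
                             n_activated))
    base <- baseline_mean * exp(rnorm(n_genes, 0, 0.5))
    eff <- 2 ^ effect_log2
    # condition means: minus = control (sRNA absent), plus = sRNA expressed
    rna_minus <- base
    ribo_minus <- base
    rna_plus <- ifelse(true_class == "repressed_stability", base / eff, base)
    ribo_plus <- dplyr::case_when(
      true_class == "repressed_translational" ~ base / eff,
      true_class == "repressed_stability" ~ base / eff,
      true_class == "activated" ~ base * eff,
      TRUE ~ base)
    size <- 1 / nb_dispersion
    draw <- function(mu) {
      matrix(rnbinom(n_genes * n_reps, mu = rep(mu, n_reps), size = size),
             nrow = n_genes)
    }
    cm <- list(rna_minus = draw(rna_minus), rna_plus = draw(rna_plus),
               ribo_minus = draw(ribo_minus), ribo_plus = draw(ribo_plus))
    lfc <- function(minus, plus) {
      log2((rowMeans(minus) + 0.5) / (rowMeans(plus) + 0.5))
    }
    wald_p <- function(minus, plus) {
      m1 <- rowMeans(minus); m2 <- rowMeans(plus)
      v1 <- m1 + nb_dispersion * m1 ^ 2
      v2 <- m2 + nb_dispersion * m2 ^ 2
      z <- (m1 - m2) / sqrt(v1 / n_reps + v2 / n_reps + 1e-9)
      2 * pnorm(-abs(z))
    }
    tibble(
      gene = sprintf("g%04d", seq_len(n_genes)),
      rna_log2fc = lfc(cm$rna_minus, cm$rna_plus),
      rna_p = wald_p(cm$rna_minus, cm$rna_plus),
      ribo_log2fc = lfc(cm$ribo_minus, cm$ribo_plus),
      ribo_p = wald_p(cm$ribo_minus, cm$ribo_plus),
      rna_reads = as.integer(rowSums(cm$rna_minus) + rowSums(cm$rna_plus)),
      ribo_reads = as.integer(rowSums(cm$ribo_minus) + rowSums(cm$ribo_plus)),
      true_class = true_class,
      true_direction = dplyr::case_when(
        true_class == "null" ~ "none",
        true_class == "activated" ~ "activated",
        TRUE ~ "repressed"),
      true_base_mean = base
    )
  })
}

#' Write a sequence scenario as FASTA plus a truth JSON
#' @param scenario A `sequence_scenario`.
#' @param fasta_path,truth_path Output paths.
#' @export
write_sequence_scenario <- function(scenario, fasta_path, truth_path) {
  stopifnot(inherits(scenario, "sequence_scenario"))
  write_rna_fasta(list(scenario$srna, scenario$mrna), fasta_path)
  jsonlite::write_json(
    scenario[c("site_start", "site_end", "loop_start", "loop_end",
               "site_context", "seed")],
    truth_path, auto_unbox = TRUE)
  invisible(fasta_path)
}
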