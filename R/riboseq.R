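#' Read a gene-level RNA-seq/Ribo-seq differential table
#'
#' Expects a TSV with header columns `gene`, `rna_log2fc`, `rna_p`,
#' `ribo_log2fc`, `ribo_p` and optionally `rna_reads`, `ribo_reads`. Fold
#' changes follow the sRNA-minus / sRNA-plus orientation, so positive log2
#' values mark genes repressed by the sRNA.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "rna_log2fc", "rna_p", "ribo_log2fc", "ribo_p")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  as_tibble(df)
}

#' The transcribed reference target table of the RyhB Ribo-seq study
#'
#' Gene-level log2 fold changes (sRNA-minus / sRNA-plus) and p-values for the
#' 80 putative RyhB targets called at the >2-fold threshold: 64 repressed and
#' 16 activated genes. The `note` column carries the published annotation
#' flags (R reported, P predicted, N novel, V verified, I indirect, F failed
#' verification). Ships in `inst/extdata/ryhb_riboseq_table1.tsv`.
#'
#' @return A tibble with one row per gene.
#' @export
ryhb_target_table <- function() {
  read_gene_table(system.file("extdata", "ryhb_riboseq_table1.tsv",
                              package = "srnatarget", mustWork = TRUE))
}

#' Exclude genes with low sequencing coverage
#'
#' A gene is retained only when both assays have at least `min_reads` mapped
#' reads (inclusive); excluded genes are logged with the reason and attached
#' as the `"excluded"` attribute.
#'
#' @param genes Tibble with `rna_reads` and `ribo_reads` columns.
#' @param min_reads Read floor (default 200).
#' @return The retained tibble, with attribute `excluded`.
#' @export
filter_low_coverage <- function(genes, min_reads = 200L) {
  stopifnot(all(c("rna_reads", "ribo_reads") %in% names(genes)))
  low <- genes$rna_reads < min_reads | genes$ribo_reads < min_reads
  excluded <- genes[low, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- ifelse(
      excluded$rna_reads < min_reads & excluded$ribo_reads < min_reads,
      "both assays below read floor",
      ifelse(excluded$rna_reads < min_reads, "rna_reads below read floor",
             "ribo_reads below read floor"))
  }
  out <- genes[!low, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Call sRNA targets by fold change
#'
#' A gene passes when either assay changes at least 2-fold, i.e.
#' `|log2fc| >= log2_threshold` (inclusive, so a printed 1.00 qualifies).
#' Direction follows the sign of the qualifying change under the
#' sRNA-minus / sRNA-plus convention: positive means repressed by the sRNA.
#' When both assays qualify with conflicting signs, the larger-magnitude
#' assay decides and the row is flagged in `sign_conflict`.
#'
#' @param genes Tibble with `rna_log2fc` and `ribo_log2fc` (typically after
#'   [filter_low_coverage()]).
#' @param log2_threshold Absolute log2 fold-change threshold (default 1).
#' @return The input with columns `passes`, `direction` (repressed /
#'   activated / none), `qualifying_assay` (rna / ribo / both / none) and
#'   `sign_conflict` added.
#' @export
call_targets <- function(genes, log2_threshold = 1.0) {
  stopifnot(all(c("rna_log2fc", "ribo_log2fc") %in% names(genes)))
  rna_q <- abs(genes$rna_log2fc) >= log2_threshold
  ribo_q <- abs(genes$ribo_log2fc) >= log2_threshold
  passes <- rna_q | ribo_q
  qualifying <- dplyr::case_when(
    rna_q & ribo_q ~ "both",
    rna_q ~ "rna",
    ribo_q ~ "ribo",
    TRUE ~ "none")
  conflict <- rna_q & ribo_q &
    sign(genes$rna_log2fc) != sign(genes$ribo_log2fc)
  deciding <- ifelse(qualifying == "ribo", genes$ribo_log2fc,
              ifelse(qualifying == "rna", genes$rna_log2fc,
                     ifelse(abs(genes$ribo_log2fc) >= abs(genes$rna_log2fc),
                            genes$ribo_log2fc, genes$rna_log2fc)))
  direction <- ifelse(!passes, "none",
                      ifelse(deciding > 0, "repressed", "activated"))
  if (any(conflict))
    message(sum(conflict), " gene(s) with conflicting signs across assays; ",
            "direction taken from the larger-magnitude assay")
  mutate(genes, passes = passes, direction = direction,
         qualifying_assay = qualifying, sign_conflict = conflict)
}

#' Classify the regulatory mode of called targets
#'
#' Targets whose ribosome-footprint change substantially exceeds the total-RNA
#' change (|ribo - rna| >= `delta_threshold`) while the RNA-seq change is not
#' significant are classified as regulated at the translational level;
#' concordant changes (small delta) with a significant RNA-seq change indicate
#' regulation of mRNA stability; everything else is mixed. Genes that do not
#' pass the fold-change filter are undetermined.
#'
#' @param calls Tibble from [call_targets()] (needs `passes`, `rna_log2fc`,
#'   `ribo_log2fc`, `rna_p`).
#' @param sig_alpha RNA-seq significance level (default 0.05).
#' @param delta_threshold Log2 difference separating translational from
#'   stability regulation (default 0.5).
#' @return The input with a `mode` column (translational / stability / mixed /
#'   undetermined) added.
#' @export
classify_mode <- function(calls, sig_alpha = 0.05, delta_threshold = 0.5) {
  stopifnot(all(c("passes", "rna_log2fc", "ribo_log2fc", "rna_p") %in%
                  names(calls)))
  delta <- abs(calls$ribo_log2fc - calls$rna_log2fc)
  mode <- dplyr::case_when(
    !calls$passes ~ "undetermined",
    delta >= delta_threshold & calls$rna_p >= sig_alpha ~ "translational",
    delta < delta_threshold & calls$rna_p < sig_alpha ~ "stability",
    TRUE ~ "mixed")
  mutate(calls, mode = mode)
}

#' Linear fold change from a log2 fold change
#'
#' Returns `2^|log2fc|` rounded to one decimal, half away from zero, the form
#' in which fold changes are quoted in prose (e.g. a log2 change of 1.18 is a
#' 2.3-fold change).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Numeric vector of one-decimal linear fold changes.
#' @examples
#' fold_linear(1.18)  # 2.3
#' @export
fold_linear <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  floor(2 ^ abs(log2fc) * 10 + 0.5) / 10
}

#' Tally target calls
#'
#' @param calls Tibble from [call_targets()] (optionally after
#'   [classify_mode()]).
#' @return A list with `repressed`, `activated`, `total` and (when a `mode`
#'   column is present) `by_mode` counts.
#' @export
summarize_targets <- function(calls) {
  repressed <- sum(calls$passes & calls$direction == "repressed")
  activated <- sum(calls$passes & calls$direction == "activated")
  out <- list(repressed = repressed, activated = activated,
              total = repressed + activated)
  if ("mode" %in% names(calls)) {
    passing <- calls[calls$passes, , drop = FALSE]
    out$by_mode <- as.list(table(passing$mode))
  }
  out
}
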