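# End-to-end orchestration: annotate -> filter -> collapse -> test.

#' Run the gene-level burden analysis end to end
#'
#' Annotates the cohort's variants against the transcript models, applies the
#' ultra-rare filter at the main threshold plus any sensitivity thresholds,
#' collapses carriers per gene and category, and runs exact burden inference.
#' Categories analysed are `synonymous`, `LOF_all` and - for multi-exon genes
#' only - the `NMD_triggering` / `NMD_escape` split (for single-exon genes
#' every LOF variant escapes NMD, so a separate split is not informative and
#' is skipped). Missing gene x category combinations are completed with zero
#' carriers so the output schema is stable, including for an empty cohort.
#'
#' @param cohort A list with `variants`, `carriers`, `samples` (as returned
#'   by [sim_cohort()] or [read_cohort_vcf()] plus [read_sample_sheet()]),
#'   or a config list of file paths: `vcf`, `samples`, and optionally `af`,
#'   `transcripts` (JSON dialect).
#' @param txs Named list of [transcript_model()] objects (default the
#'   bundled toy models); ignored when the config supplies `transcripts`.
#' @param af_reference Optional reference AF tibble.
#' @param maf_threshold Main ultra-rare threshold (default 1e-4).
#' @param sensitivity_thresholds Additional thresholds swept for sensitivity
#'   (default 5e-5 and 2e-4).
#' @param alpha,n_tests Multiple-testing parameters for [burden_test()].
#' @param case_n Optional named per-gene case cohort sizes.
#' @param outdir Optional directory; when given, annotation, count and
#'   result TSVs are written there.
#' @return A list: `results` (a [burden_test()] tibble at the main
#'   threshold), `sensitivity` (tibble over all thresholds, with a
#'   `maf_threshold` column), `counts`, `annotations`, `threshold`.
#' @examples
#' sim <- sim_cohort(n_case = 300, n_control = 3000, seed = 7)
#' out <- run_burden(sim)
#' head(tidy(out$results))
#' @export
run_burden <- function(cohort, txs = toy_transcripts(), af_reference = NULL,
                       maf_threshold = 1e-4,
                       sensitivity_thresholds = c(5e-5, 2e-4),
                       alpha = 0.05, n_tests = 20, case_n = NULL,
                       outdir = NULL) {
  if (!is.null(cohort$vcf)) {
    for (p in c(cohort$vcf, cohort$samples)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
    vc <- read_cohort_vcf(cohort$vcf)
    samples <- read_sample_sheet(cohort$samples)
    if (!is.null(cohort$af)) af_reference <- read_af_table(cohort$af)
    if (!is.null(cohort$transcripts)) {
      txs <- read_transcripts_json(cohort$transcripts)
    }
    cohort <- list(variants = vc$variants, carriers = vc$carriers,
                   samples = samples)
  }
  if (is.null(af_reference) && !is.null(cohort$af_reference)) {
    af_reference <- cohort$af_reference
  }
  annotations <- annotate_variants(cohort$variants, txs)
  unmatched <- filter(annotations, is.na(.data$gene))
  if (nrow(unmatched) > 0) {
    warn(sprintf("%d variant(s) overlap no transcript model; ignored",
                 nrow(unmatched)))
  }

  all_counts <- purrr::map(
    sort(unique(c(maf_threshold, sensitivity_thresholds))),
    function(thr) {
      qual <- ultra_rare_filter(cohort$variants, cohort$carriers,
                                cohort$samples, af_reference, thr)
      collapse_carriers(qual, annotations, cohort$carriers, cohort$samples,
                        case_n) |>
        complete_count_grid(txs, cohort$samples, case_n) |>
        mutate(maf_threshold = thr, .before = 1)
    }) |> bind_rows()

  counts_main <- filter(all_counts, .data$maf_threshold == !!maf_threshold) |>
    select(-"maf_threshold")
  results <- burden_test(counts_main, alpha = alpha, n_tests = n_tests)
  sensitivity <- burden_test(all_counts, alpha = alpha, n_tests = n_tests)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_annotations_tsv(annotations, file.path(outdir, "annotations.tsv"))
    write_counts_tsv(counts_main, file.path(outdir, "counts.tsv"))
    write_burden_tsv(results, file.path(outdir, "burden_results.tsv"))
    write_burden_tsv(sensitivity, file.path(outdir, "sensitivity.tsv"))
  }
  list(results = results, sensitivity = as_tibble(sensitivity),
       counts = counts_main, annotations = annotations,
       threshold = maf_threshold)
}

# complete the gene x category grid with zero-carrier rows; drop the NMD
# split for single-exon genes
#' @keywords internal
complete_count_grid <- function(counts, txs, samples, case_n = NULL) {
  n_cases <- sum(samples$group == "case")
  n_controls <- sum(samples$group == "control")
  grid <- purrr::map(txs, function(tx) {
    cats <- if (nrow(tx$exons) == 1) {
      c("synonymous", "LOF_all")
    } else {
      c("synonymous", "LOF_all", "NMD_triggering", "NMD_escape")
    }
    tibble(gene = tx$gene, category = cats)
  }) |> bind_rows()
  grid |>
    left_join(counts, by = c("gene", "category")) |>
    mutate(
      case_total = if (is.null(case_n)) n_cases
                   else dplyr::coalesce(unname(case_n[.data$gene]), n_cases),
      a = dplyr::coalesce(.data$a, 0L),
      c = dplyr::coalesce(.data$c, 0L),
      b = dplyr::coalesce(.data$b, .data$case_total),
      d = dplyr::coalesce(.data$d, n_controls)) |>
    select("gene", "category", "a", "b", "c", "d") |>
    arrange(.data$gene, .data$category)
}
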