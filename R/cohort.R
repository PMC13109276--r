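# Ultra-rare frequency filtering and carrier collapsing.
#
# The burden unit is the carrier: an individual with >= 1 qualifying variant
# of a category in a gene counts once, whatever the number of alleles
# (dominant-model collapse; at ultra-rare frequencies carriers and alleles
# coincide in practice). MAF is assessed against the control cohort and an
# external reference table, never against cases, which are enriched by
# hypothesis.

#' Read a cohort VCF into variant and carrier tables
#'
#' Reads a VCF 4.2 file with vcfR and extracts, per variant, the set of
#' samples carrying at least one alternate allele. Multi-allelic records are
#' an error: decompose upstream.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A list: `variants` (tibble `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`) and `carriers` (tibble `variant_id`, `sample_id`, `dose` with
#'   dose = number of alternate alleles).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic VCF records found; decompose before loading")
  }
  variants <- tibble(
    variant_id = paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ">", fix$ALT),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  dose[gt %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  idx <- which(dose > 0, arr.ind = TRUE)
  carriers <- tibble(
    variant_id = variants$variant_id[idx[, 1]],
    sample_id = colnames(dose)[idx[, 2]],
    dose = dose[idx])
  list(variants = variants, carriers = carriers)
}

#' Read a sample sheet (id, group)
#'
#' @param path TSV with header columns `id` and `group`
#'   (`case` / `control`).
#' @return Tibble `id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  stopifnot(all(c("id", "group") %in% names(s)))
  if (!all(s$group %in% c("case", "control"))) {
    abort("sample groups must be 'case' or 'control'")
  }
  if (anyDuplicated(s$id)) abort("duplicate sample ids in sheet")
  s[, c("id", "group")]
}

#' Read a reference allele-frequency table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return Tibble with a `variant_id` key column added.
#' @export
read_af_table <- function(path) {
  af <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = "c", pos = "i", ref = "c", alt = "c",
                          af = "d"))
  mutate(af, variant_id = paste0(.data$chrom, ":", .data$pos, ":",
                                 .data$ref, ">", .data$alt))
}

#' Ultra-rare frequency filter
#'
#' Keeps variants whose minor allele frequency is strictly below `threshold`
#' both in the control cohort (computed from control genotypes: alternate
#' alleles over 2 x control n) and in the supplied external reference table.
#' Variants missing from the reference are treated as frequency 0 with a
#' warning. Frequency is never assessed against cases.
#'
#' @param variants Variant tibble (needs `variant_id`).
#' @param carriers Carrier tibble (`variant_id`, `sample_id`, `dose`).
#' @param samples Sample sheet tibble (`id`, `group`).
#' @param af_reference Optional reference AF tibble (see [read_af_table()]).
#' @param threshold Strict MAF upper bound, in (0, 1] (default 1e-4; the
#'   sensitivity thresholds are 5e-5 and 2e-4).
#' @return The filtered variant tibble with columns `af_control`, `af_ref`
#'   added.
#' @export
ultra_rare_filter <- function(variants, carriers, samples,
                              af_reference = NULL, threshold = 1e-4) {
  stopifnot(threshold > 0, threshold <= 1)
  n_control <- sum(samples$group == "control")
  ctrl_ids <- samples$id[samples$group == "control"]
  ctrl_alleles <- carriers |>
    filter(.data$sample_id %in% ctrl_ids) |>
    group_by(.data$variant_id) |>
    summarise(n_alt = sum(.data$dose))
  out <- variants |>
    left_join(ctrl_alleles, by = "variant_id") |>
    mutate(af_control = dplyr::coalesce(.data$n_alt, 0L) /
             pmax(2 * n_control, 1)) |>
    select(-"n_alt")
  if (!is.null(af_reference)) {
    missing <- setdiff(out$variant_id, af_reference$variant_id)
    if (length(missing)) {
      warn(sprintf(
        "%d variant(s) missing from the AF reference; treated as frequency 0",
        length(missing)))
    }
    out <- out |>
      left_join(select(af_reference, "variant_id", "af"), by = "variant_id") |>
      mutate(af_ref = dplyr::coalesce(.data$af, 0)) |>
      select(-"af")
  } else {
    out$af_ref <- 0
  }
  filter(out, .data$af_control < threshold, .data$af_ref < threshold)
}

#' @keywords internal
variant_categories <- function(annotations) {
  lof <- c("stop_gain", "frameshift", "essential_splice")
  annotations |>
    mutate(category = dplyr::case_when(
      .data$consequence == "synonymous" ~ "synonymous",
      .data$consequence %in% lof & .data$nmd_class == "triggering" ~
        "NMD_triggering",
      .data$consequence %in% lof & .data$nmd_class == "escape" ~ "NMD_escape",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$category), !is.na(.data$gene))
}

#' Collapse qualifying variants to per-gene, per-category carrier tables
#'
#' An individual carrying one or more qualifying variants of a category in a
#' gene counts once. `NMD_triggering` and `NMD_escape` partition `LOF_all`:
#' the LOF_all carrier set is the union of the two (a sample carrying both a
#' triggering and an escape variant counts once in LOF_all).
#'
#' @param qualifying Filtered variant tibble (from [ultra_rare_filter()]).
#' @param annotations Annotation tibble (from [annotate_variants()]); every
#'   qualifying variant must be annotated, otherwise an error is raised.
#' @param carriers Carrier tibble.
#' @param samples Sample sheet tibble.
#' @param case_n Optional named vector of per-gene case cohort sizes (genes
#'   analysed in combined sub-cohorts may have larger n than the genotyped
#'   set); defaults to the number of case samples in `samples`.
#' @return A carrier-count tibble: `gene`, `category`, `a`, `b`, `c`, `d`.
#' @export
collapse_carriers <- function(qualifying, annotations, carriers, samples,
                              case_n = NULL) {
  miss <- setdiff(qualifying$variant_id, annotations$variant_id)
  if (length(miss)) {
    abort(paste0("qualifying variant(s) without annotation: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  carried_unknown <- setdiff(carriers$sample_id, samples$id)
  if (length(carried_unknown)) {
    abort("carrier sample id(s) absent from the sample sheet")
  }
  ann <- variant_categories(annotations) |>
    filter(.data$variant_id %in% qualifying$variant_id) |>
    select("variant_id", "gene", "category")
  long <- carriers |>
    dplyr::inner_join(ann, by = "variant_id",
                      relationship = "many-to-many") |>
    left_join(samples, by = c(sample_id = "id"))
  lof <- filter(long, .data$category != "synonymous") |>
    mutate(category = "LOF_all")
  long <- bind_rows(long, lof)
  n_cases <- sum(samples$group == "case")
  n_controls <- sum(samples$group == "control")
  counts <- long |>
    distinct(.data$gene, .data$category, .data$sample_id, .data$group) |>
    count(.data$gene, .data$category, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  for (col in c("case", "control")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts |>
    mutate(
      case_total = if (is.null(case_n)) n_cases
                   else unname(case_n[.data$gene]) %||% n_cases,
      case_total = dplyr::coalesce(.data$case_total, n_cases),
      a = .data$case, b = .data$case_total - .data$case,
      c = .data$control, d = n_controls - .data$control) |>
    select("gene", "category", "a", "b", "c", "d") |>
    arrange(.data$gene, .data$category)
}

#' Write per-gene carrier counts as TSV
#'
#' @param counts Output of [collapse_carriers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
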