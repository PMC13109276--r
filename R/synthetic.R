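# Seeded synthetic-data generators with truth ledgers.
#
# The generators emulate the study design the package analyses: a suspected-
# MODY case cohort genotyped for ten genes against a large unfiltered
# population control cohort; ultra-rare variants planted per gene and NMD
# category at specified control carrier frequencies, with case carrier
# status drawn at the frequency implied by a true odds ratio; dominant
# fully-penetrant pedigrees. Every random draw is recorded in a truth ledger
# sufficient to predict all downstream counts without re-reading the files.

#' Default simulation design
#'
#' One row per gene x variant category with the control carrier frequency
#' and the planted true odds ratio. Defaults emulate the published regime:
#' control carrier frequencies of a few per hundred thousand, strong
#' enrichment for the established haploinsufficiency genes, NMD-status-
#' specific enrichment for INS/PDX1 (escape) and HNF1B/RFX6 (triggering),
#' none for ABCC8/KCNJ11, and odds ratio 1 for synonymous variants in every
#' gene. Categories without carriers in either cohort are encoded with a
#' near-zero odds ratio. Frequencies are per carrier, not per allele.
#'
#' @param n_control Control cohort size the frequencies are scaled to.
#' @return Tibble: `gene`, `category`, `control_freq`, `true_or`.
#' @export
mody_sim_spec <- function(n_control = 155501) {
  f <- function(k) k / n_control
  lof <- tibble::tribble(
    ~gene,     ~category,        ~control_freq, ~true_or,
    "GCK",     "NMD_triggering", f(17),  341,
    "GCK",     "NMD_escape",     f(1),   502,
    "HNF1A",   "NMD_triggering", f(7),   441,
    "HNF1A",   "NMD_escape",     f(5),   99,
    "HNF4A",   "NMD_triggering", f(2),   584,
    "HNF4A",   "NMD_escape",     f(1),   101,
    "ABCC8",   "NMD_triggering", f(131), 2.8,
    "ABCC8",   "NMD_escape",     f(6),   0.01,
    "HNF1B",   "NMD_triggering", f(0.5), 500,
    "HNF1B",   "NMD_escape",     f(1),   0.01,
    "INS",     "NMD_triggering", f(2),   0.01,
    "INS",     "NMD_escape",     f(1),   181,
    "KCNJ11",  "NMD_escape",     f(3),   0.01,
    "NEUROD1", "NMD_escape",     f(23),  21,
    "PDX1",    "NMD_triggering", f(1),   63,
    "PDX1",    "NMD_escape",     f(37),  10,
    "RFX6",    "NMD_triggering", f(38),  17,
    "RFX6",    "NMD_escape",     f(5),   1.9)
  syn <- tibble(gene = unique(lof$gene), category = "synonymous",
                control_freq = f(10), true_or = 1)
  bind_rows(lof, syn) |> arrange(.data$gene, .data$category)
}

#' Generate toy transcript files plus an NMD-boundary truth ledger
#'
#' Writes the bundled transcript models ([toy_transcripts()]) as JSON, GFF3
#' and spliced-sequence FASTA, and returns a truth ledger with each gene's
#' exon count and the spliced/cDNA coordinate from which a PTC escapes NMD.
#'
#' @param dir Output directory (created if needed).
#' @return A list: `txs` (the models), `paths`, `truth` (tibble: `gene`,
#'   `n_exons`, `escape_from_cdna` - the smallest cDNA position of a PTC
#'   first base classified escape; 1 for single-exon genes).
#' @export
sim_transcripts <- function(dir = tempfile("txs")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txs <- toy_transcripts()
  paths <- list(json = file.path(dir, "transcripts.json"),
                gff3 = file.path(dir, "transcripts.gff3"),
                fasta = file.path(dir, "transcripts.fa"))
  write_transcripts_json(txs, paths$json)
  write_transcripts_gff3(txs, paths$gff3, paths$fasta)
  truth <- purrr::map(txs, function(tx) {
    n_ex <- nrow(tx$exons)
    esc <- if (n_ex == 1) 1L else {
      off <- exon_offsets(tx)
      as.integer(off[n_ex] - 50L - utr5_length(tx))
    }
    tibble(gene = tx$gene, n_exons = n_ex, escape_from_cdna = esc)
  }) |> bind_rows()
  list(txs = txs, paths = paths, truth = truth)
}

# single-base-substitution candidate sites of a given category on a toy
# transcript, as plus-strand VCF-style records
#' @keywords internal
candidate_sites <- function(tx, category, n_max = 60) {
  cds <- cds_span_spliced(tx)
  n_codons <- (cds[2] - cds[1] + 1) / 3 - 1    # excluding the stop codon
  u5 <- utr5_length(tx)
  single_exon <- nrow(tx$exons) == 1
  rows <- list()
  for (i in 2:n_codons) {
    cstart <- 3 * i - 2
    codon <- substr(tx$spliced_seq, u5 + cstart, u5 + cstart + 2)
    for (k in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (substr(codon, k, k) == nt) next
        new <- codon
        substr(new, k, k) <- nt
        is_stop <- new %in% STOP_CODONS
        same_aa <- !is_stop &&
          translate_frame(new, to_stop = FALSE)$aa ==
          translate_frame(codon, to_stop = FALSE)$aa
        want <-
          if (category == "synonymous") same_aa
          else if (!is_stop) FALSE
          else {
            cls <- classify_nmd(tx, ptc_cdna_pos = cstart,
                                consequence = "stop_gain")$nmd_class
            (category == "NMD_escape" && cls == "escape") ||
              (category == "NMD_triggering" && cls == "triggering")
          }
        if (!want) next
        cdna <- cstart + k - 1
        gpos <- cdna_to_genomic(cdna, tx)
        ref <- substr(codon, k, k)
        alt <- nt
        if (tx$strand == "-") {
          ref <- revcomp(ref)
          alt <- revcomp(alt)
        }
        rows[[length(rows) + 1]] <-
          tibble(chrom = tx$chrom, pos = gpos, ref = ref, alt = alt)
        if (length(rows) >= n_max) {
          return(distinct(bind_rows(rows), .data$chrom, .data$pos,
                          .data$ref, .data$alt))
        }
      }
    }
  }
  if (!length(rows)) return(tibble(chrom = character(), pos = integer(),
                                   ref = character(), alt = character()))
  distinct(bind_rows(rows), .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Simulate a case/control cohort with planted carrier enrichment
#'
#' For each gene x category design row, plants ultra-rare single-nucleotide
#' variant sites on the bundled toy transcripts (stop-gains for the NMD
#' categories, synonymous changes for the negative-control category), draws
#' control carriers Binomial(`n_control`, control frequency) and case
#' carriers Binomial(`n_case`, p1) with odds(p1) = OR x odds(p0), and
#' assigns carriers to sites so every site stays below the ultra-rare
#' threshold. The truth ledger records the realised 2x2 table per cell.
#'
#' @param spec Design tibble (see [mody_sim_spec()]).
#' @param n_case,n_control Cohort sizes.
#' @param seed Integer seed; identical inputs give byte-identical outputs.
#' @param maf_threshold Ultra-rare threshold the planted sites must respect.
#' @return A list: `variants`, `carriers`, `samples`, `af_reference`
#'   (in-memory tibbles as read by the cohort loaders), `truth` (tibble:
#'   `gene`, `category`, `case_carriers`, `control_carriers`,
#'   `expected_a`, `expected_c`, `n_sites`), and `txs`.
#' @examples
#' sim <- sim_cohort(n_case = 200, n_control = 2000, seed = 1)
#' sim$truth
#' @export
sim_cohort <- function(spec = mody_sim_spec(), n_case = 2571,
                       n_control = 155501, seed = 1,
                       maf_threshold = 1e-4) {
  txs <- toy_transcripts()
  samples <- tibble(
    id = c(sprintf("case_%05d", seq_len(n_case)),
           sprintf("ctrl_%06d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)))
  case_ids <- samples$id[samples$group == "case"]
  ctrl_ids <- samples$id[samples$group == "control"]
  with_seed_if(seed, {
    all_variants <- list()
    all_carriers <- list()
    truth <- list()
    for (r in seq_len(nrow(spec))) {
      gene <- spec$gene[r]
      category <- spec$category[r]
      p0 <- spec$control_freq[r]
      p1 <- implied_p1(spec$true_or[r], p0)
      n_ctrl_carr <- rbinom(1, n_control, p0)
      n_case_carr <- rbinom(1, n_case, p1)
      # enough sites that each stays ultra-rare in controls
      max_per_site <- max(1, floor(maf_threshold * 2 * n_control / 2) - 1)
      n_sites <- max(1, ceiling(n_ctrl_carr / max_per_site),
                     ceiling(n_ctrl_carr / 5))
      sites <- candidate_sites(txs[[gene]], category,
                               n_max = max(n_sites, 12))
      if (nrow(sites) < n_sites) {
        abort(sprintf("not enough candidate %s sites in toy %s",
                      category, gene))
      }
      sites <- sites[seq_len(n_sites), ]
      sites$variant_id <- paste0(sites$chrom, ":", sites$pos, ":",
                                 sites$ref, ">", sites$alt)
      carr_ids <- c(sample(case_ids, n_case_carr),
                    sample(ctrl_ids, n_ctrl_carr))
      # balanced site assignment keeps every site below the ultra-rare
      # threshold deterministically
      site_of <- rep_len(seq_len(n_sites), length(carr_ids))
      all_variants[[r]] <- sites
      all_carriers[[r]] <- tibble(
        variant_id = sites$variant_id[site_of],
        sample_id = carr_ids, dose = 1L)
      truth[[r]] <- tibble(
        gene = gene, category = category,
        case_carriers = n_case_carr, control_carriers = n_ctrl_carr,
        expected_a = n_case * p1, expected_c = n_control * p0,
        n_sites = n_sites)
    }
    variants <- bind_rows(all_variants) |>
      distinct(.data$variant_id, .keep_all = TRUE)
    carriers <- bind_rows(all_carriers)
    # external reference AF consistent with the realised control frequencies
    af_reference <- carriers |>
      filter(.data$sample_id %in% ctrl_ids) |>
      count(.data$variant_id, name = "n_alt") |>
      dplyr::right_join(variants, by = "variant_id") |>
      mutate(af = dplyr::coalesce(.data$n_alt, 0L) / (2 * n_control)) |>
      select("chrom", "pos", "ref", "alt", "af", "variant_id")
    list(variants = variants, carriers = carriers, samples = samples,
         af_reference = af_reference,
         truth = bind_rows(truth), txs = txs)
  })
}

#' Simulate dominant fully-penetrant pedigrees
#'
#' Builds one family per entry of `meioses_per_family`, each containing the
#' requested number of informative concordant meioses (genotyped non-proband
#' relatives: affected carriers and unaffected non-carriers), plus an
#' optional de novo family in which both parents are genotyped non-carriers.
#'
#' @param meioses_per_family Integer vector; default five families with two
#'   informative meioses each (combined LOD 10 log10 2 ~ 3.0).
#' @param de_novo Add a de-novo family (labelled last).
#' @param seed Integer seed (affects the mix of relative types).
#' @return A list: `ped` (pedigree tibble), `truth` (tibble: `family`,
#'   `informative_meioses`, `de_novo`).
#' @export
sim_pedigrees <- function(meioses_per_family = c(2, 2, 2, 2, 2),
                          de_novo = TRUE, seed = 1) {
  stopifnot(all(meioses_per_family >= 0))
  with_seed_if(seed, {
    fams <- purrr::imap(meioses_per_family, function(m, fi) {
      fam <- sprintf("F%02d", fi)
      rows <- list(tibble(
        family = fam, id = paste0(fam, "_p"), father = paste0(fam, "_f"),
        mother = paste0(fam, "_m"), sex = "2", affected = "yes",
        genotype = "carrier", proband = TRUE))
      # parents present as founders; genotyped only if used as meioses
      par_geno <- c("untested", "untested")
      m_left <- m
      if (m_left >= 1) { par_geno[2] <- "carrier"; m_left <- m_left - 1 }
      if (m_left >= 1) { par_geno[1] <- "non_carrier"; m_left <- m_left - 1 }
      rows[[2]] <- tibble(
        family = fam, id = paste0(fam, "_f"), father = NA_character_,
        mother = NA_character_, sex = "1",
        affected = if (par_geno[1] == "non_carrier") "no" else "unknown",
        genotype = par_geno[1], proband = FALSE)
      rows[[3]] <- tibble(
        family = fam, id = paste0(fam, "_m"), father = NA_character_,
        mother = NA_character_, sex = "2",
        affected = if (par_geno[2] == "carrier") "yes" else "unknown",
        genotype = par_geno[2], proband = FALSE)
      if (m_left > 0) {
        sib_carrier <- sample(c(TRUE, FALSE), m_left, replace = TRUE)
        for (sj in seq_len(m_left)) {
          rows[[3 + sj]] <- tibble(
            family = fam, id = sprintf("%s_s%d", fam, sj),
            father = paste0(fam, "_f"), mother = paste0(fam, "_m"),
            sex = sample(c("1", "2"), 1),
            affected = if (sib_carrier[sj]) "yes" else "no",
            genotype = if (sib_carrier[sj]) "carrier" else "non_carrier",
            proband = FALSE)
        }
      }
      bind_rows(rows)
    })
    truth <- tibble(family = sprintf("F%02d", seq_along(meioses_per_family)),
                    informative_meioses = as.integer(meioses_per_family),
                    de_novo = FALSE)
    if (de_novo) {
      fam <- sprintf("F%02d", length(meioses_per_family) + 1)
      fams[[length(fams) + 1]] <- tibble(
        family = fam,
        id = paste0(fam, c("_p", "_f", "_m")),
        father = c(paste0(fam, "_f"), NA, NA),
        mother = c(paste0(fam, "_m"), NA, NA),
        sex = c("2", "1", "2"),
        affected = c("yes", "no", "no"),
        genotype = c("carrier", "non_carrier", "non_carrier"),
        proband = c(TRUE, FALSE, FALSE))
      truth <- bind_rows(truth, tibble(family = fam,
                                       informative_meioses = 2L,
                                       de_novo = TRUE))
    }
    list(ped = bind_rows(fams), truth = truth)
  })
}

# ---- plain-text writers -----------------------------------------------------

#' Write a cohort as a VCF 4.2 file (plus sample sheet and AF table)
#'
#' Emits an uncompressed VCF with one GT column per sample. Intended for
#' moderate cohort sizes (file width grows with sample count); the in-memory
#' tibbles are the native interchange format.
#'
#' @param sim A [sim_cohort()] result (or any list with `variants`,
#'   `carriers`, `samples`, `af_reference`).
#' @param dir Output directory.
#' @return Named list of written paths.
#' @export
write_cohort_files <- function(sim, dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                samples = file.path(dir, "samples.tsv"),
                af = file.path(dir, "af_reference.tsv"))
  v <- arrange(sim$variants, .data$chrom, .data$pos, .data$alt)
  ids <- sim$samples$id
  gt <- matrix("0/0", nrow = nrow(v), ncol = length(ids),
               dimnames = list(NULL, ids))
  cr <- sim$carriers
  gt[cbind(match(cr$variant_id, v$variant_id),
           match(cr$sample_id, ids))] <- ifelse(cr$dose >= 2, "1/1", "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=modyburden_simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, body), paths$vcf)
  readr::write_tsv(sim$samples, paths$samples)
  readr::write_tsv(select(sim$af_reference, "chrom", "pos", "ref", "alt",
                          "af"), paths$af)
  paths
}

#' Write a pedigree tibble as a PED file (6 columns + genotype + proband)
#'
#' @param ped Pedigree tibble (see [read_pedigree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    family = ped$family, id = ped$id,
    father = dplyr::coalesce(ped$father, "0"),
    mother = dplyr::coalesce(ped$mother, "0"),
    sex = ped$sex,
    aff = dplyr::case_match(ped$affected, "yes" ~ "2", "no" ~ "1",
                            .default = "0"),
    geno = ped$genotype,
    proband = as.integer(ped$proband))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
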