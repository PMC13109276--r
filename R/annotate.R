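# Consequence classification, truncated-protein prediction and NMD status.
#
# Loss-of-function (LOF) variants are stop-gains, frameshifts and essential
# splice-site variants. A premature termination codon (PTC) is predicted to
# escape nonsense-mediated decay when its first base lies in the final exon
# or within the last 50 bp of the penultimate exon (the "50-bp rule"); a
# transcript carrying an NMD-triggering PTC is degraded (haploinsufficiency),
# an NMD-escape transcript is translated into a truncated protein.

# ---- edit machinery ---------------------------------------------------------

# map a VCF-style anchored edit to spliced-transcript coordinates.
# Returns NULL when the edited bases are not fully exonic.
#' @keywords internal
edit_in_spliced <- function(pos, ref, alt, tx) {
  len <- nchar(ref)
  span <- pos:(pos + len - 1)
  sp <- genomic_to_spliced(span, tx)
  if (any(is.na(sp))) return(NULL)
  if (tx$strand == "+") {
    list(start = sp[1], end = sp[len], ref_tx = ref, alt_tx = alt)
  } else {
    list(start = sp[len], end = sp[1], ref_tx = revcomp(ref),
         alt_tx = revcomp(alt))
  }
}

#' @keywords internal
apply_edit_spliced <- function(tx, ed) {
  paste0(substr(tx$spliced_seq, 1, ed$start - 1), ed$alt_tx,
         substr(tx$spliced_seq, ed$end + 1, nchar(tx$spliced_seq)))
}

#' @keywords internal
check_ref_allele <- function(pos, ref, tx) {
  for (k in seq_len(nchar(ref))) {
    obs <- genomic_ref_base(pos + k - 1, tx)
    if (!is.na(obs) && obs != substr(ref, k, k)) {
      abort(sprintf(
        "REF allele mismatch at %s:%d (have %s, reference is %s)",
        tx$chrom, pos + k - 1, substr(ref, k, k), obs))
    }
  }
  invisible(TRUE)
}

# ---- consequence classification --------------------------------------------

#' Classify the molecular consequence of variants on a transcript
#'
#' SNVs creating a stop codon are `stop_gain`; coding indels whose length
#' change is not a multiple of 3 are `frameshift`; positions in the first or
#' last two intronic bases are `essential_splice`; protein-identical coding
#' SNVs are `synonymous`; amino-acid substitutions are `missense`; everything
#' else (UTR, deep intronic, in-frame indels, start/stop-loss) is `other`.
#'
#' @param pos,ref,alt Parallel vectors: 1-based genomic position and VCF-style
#'   REF/ALT alleles (plus-strand; indels anchored on the preceding base).
#'   Multi-allelic ALT values (containing `,`) are an error - decompose first.
#' @param tx A [transcript_model()].
#' @return Character vector of consequence classes.
#' @examples
#' tx <- toy_transcripts()[["INS"]]
#' panel <- ins_variant_panel()
#' classify_consequence(panel$pos, panel$ref, panel$alt, tx)
#' @export
classify_consequence <- function(pos, ref, alt, tx) {
  purrr::pmap_chr(list(pos, ref, alt), function(p, r, a) {
    classify_one(p, r, a, tx)$consequence
  })
}

# full single-variant classification; returns consequence plus the pieces
# predict_mutant_protein() and classify_nmd() need
#' @keywords internal
classify_one <- function(pos, ref, alt, tx) {
  if (grepl(",", alt, fixed = TRUE)) {
    abort("multi-allelic ALT: decompose the record before annotation")
  }
  if (ref == alt) abort("REF and ALT are identical")
  check_ref_allele(pos, ref, tx)
  out <- list(consequence = "other", intron_index = NA_integer_)

  # essential splice: any edited/affected base in the canonical 2-bp windows
  probe <- pos:(pos + max(nchar(ref), 2) - 1)
  probe <- probe[probe <= max(tx$exons$end)]
  spl <- splice_region_class(probe, tx)
  if (any(spl == "essential_splice")) {
    hit <- probe[which(spl == "essential_splice")[1]]
    out$consequence <- "essential_splice"
    out$intron_index <- locate_intron(hit, tx)$intron_index
    return(out)
  }

  ed <- edit_in_spliced(pos, ref, alt, tx)
  if (is.null(ed)) return(out)   # intronic / boundary-crossing, not essential
  cds <- cds_span_spliced(tx)
  overlaps_cds <- ed$end >= cds[1] && ed$start <= cds[2] - 3  # excl. stop codon
  len_change <- nchar(alt) - nchar(ref)
  if (len_change != 0) {
    if (!overlaps_cds) return(out)
    out$consequence <- if (len_change %% 3 != 0) "frameshift" else "other"
    return(out)
  }
  # SNV (or MNV of equal length)
  if (ed$start < cds[1] || ed$start > cds[2]) return(out)  # UTR
  cmp <- compare_proteins(tx, ed)
  out$consequence <- cmp$consequence
  out
}

# translate reference and edited transcript, locate the first difference
#' @keywords internal
compare_proteins <- function(tx, ed) {
  cds <- cds_span_spliced(tx)
  s_ref <- tx$spliced_seq
  s_mut <- apply_edit_spliced(tx, ed)
  ref_tr <- translate_frame(substr(s_ref, cds[1], cds[2]))
  mut_tr <- translate_frame(substr(s_mut, cds[1], nchar(s_mut)))
  p_ref <- ref_tr$aa
  p_mut <- mut_tr$aa
  len_change <- nchar(ed$alt_tx) - nchar(ed$ref_tx)

  if (identical(p_ref, p_mut) && mut_tr$hit_stop && len_change == 0) {
    return(list(consequence = "synonymous", p_ref = p_ref, p_mut = p_mut,
                diff_at = NA_integer_, hit_stop = TRUE))
  }
  # first differing residue
  n <- min(nchar(p_ref), nchar(p_mut))
  i <- 1
  while (i <= n && substr(p_ref, i, i) == substr(p_mut, i, i)) i <- i + 1
  cons <-
    if (len_change != 0) {
      if (len_change %% 3 != 0) "frameshift" else "other"
    } else if (i > nchar(p_mut) && mut_tr$hit_stop) {
      "stop_gain"
    } else if (i > nchar(p_ref)) {
      "other"          # stop-loss / extension
    } else if (nchar(p_ref) == nchar(p_mut) &&
               substr(p_ref, i + 1, nchar(p_ref)) ==
               substr(p_mut, i + 1, nchar(p_mut))) {
      "missense"
    } else {
      "other"
    }
  list(consequence = cons, p_ref = p_ref, p_mut = p_mut, diff_at = i,
       hit_stop = mut_tr$hit_stop)
}

# ---- mutant protein / HGVS p. ----------------------------------------------

#' Predict the truncated protein produced by a stop-gain or frameshift
#'
#' Stop-gains truncate at the substituted codon. Frameshifts are translated in
#' the shifted frame past the native stop and into the 3'UTR until the first
#' stop codon in the new frame; the HGVS consequence is
#' `p.<Ref><Pos><New>fsTer<K>` where `K` counts new-frame residues from the
#' first changed residue (= 1) to the new termination codon inclusive.
#' A frameshift that never reaches a stop before the transcript end is
#' returned with `nonstop = TRUE` (no Ter count).
#'
#' @inheritParams classify_consequence
#' @param pos,ref,alt A single variant (length-1 vectors).
#' @return A list: `hgvs_p`, `mutant_protein` (no stop symbol),
#'   `ptc_protein_pos` (1-based residue index of the termination codon, NA if
#'   nonstop), `ptc_cdna_pos` (cDNA position of the stop codon's first base,
#'   mapped back to *reference* transcript coordinates), `nonstop`.
#' @examples
#' tx <- toy_transcripts()[["INS"]]
#' v <- ins_variant_panel()
#' predict_mutant_protein(v$pos[2], v$ref[2], v$alt[2], tx)$hgvs_p
#' @export
predict_mutant_protein <- function(pos, ref, alt, tx) {
  cls <- classify_one(pos, ref, alt, tx)
  if (!cls$consequence %in% c("stop_gain", "frameshift")) {
    abort(sprintf("variant consequence is %s; need stop_gain or frameshift",
                  cls$consequence))
  }
  ed <- edit_in_spliced(pos, ref, alt, tx)
  cmp <- compare_proteins(tx, ed)
  cds <- cds_span_spliced(tx)
  u5 <- utr5_length(tx)
  i <- cmp$diff_at
  p_mut <- cmp$p_mut
  ref_aa <- substr(cmp$p_ref, i, i)
  nonstop <- !cmp$hit_stop

  if (cls$consequence == "stop_gain" ||
      (i > nchar(p_mut) && cmp$hit_stop)) {
    hgvs <- paste0("p.", aa_three(ref_aa), i, "*")
    ptc_protein <- i
  } else {
    new_aa <- substr(p_mut, i, i)
    ptc_protein <- if (nonstop) NA_integer_ else nchar(p_mut) + 1L
    hgvs <- if (nonstop) {
      paste0("p.", aa_three(ref_aa), i, aa_three(new_aa), "fs")
    } else if (ptc_protein == i + 1L && new_aa != ref_aa) {
      paste0("p.", aa_three(ref_aa), i, aa_three(new_aa), "fsTer2")
    } else {
      paste0("p.", aa_three(ref_aa), i, aa_three(new_aa), "fsTer",
             ptc_protein - i + 1L)
    }
  }

  ptc_cdna <- NA_integer_
  if (!nonstop || cls$consequence == "stop_gain") {
    # stop codon first base in mutant spliced coordinates
    ptc_mut_sp <- cds[1] + 3L * nchar(p_mut)
    delta <- nchar(ed$ref_tx) - nchar(ed$alt_tx)
    ptc_ref_sp <- if (ptc_mut_sp > ed$start) ptc_mut_sp + delta else ptc_mut_sp
    ptc_cdna <- as.integer(ptc_ref_sp - u5)
  }
  list(hgvs_p = hgvs, mutant_protein = p_mut, ptc_protein_pos = ptc_protein,
       ptc_cdna_pos = ptc_cdna, nonstop = nonstop)
}

# ---- NMD classification -----------------------------------------------------

#' Apply the 50-bp NMD rule to a located PTC
#'
#' A PTC escapes NMD when its first base lies in the final exon or no more
#' than 50 bp upstream of the penultimate exon's 3' end (so a PTC exactly
#' 50 bp before the junction escapes, 51 bp triggers). Single-exon transcripts
#' always escape. Essential splice variants have no directly observable PTC;
#' they are assigned by intron position (last intron escapes, any other
#' intron triggers) and flagged `"splice-inferred"`. A frameshift that never
#' terminates (`nonstop`) cannot trigger NMD and escapes, with a note.
#'
#' @param tx A [transcript_model()].
#' @param ptc_cdna_pos cDNA position (reference coordinates) of the PTC's
#'   first base, for stop-gain/frameshift; NA for nonstop frameshifts.
#' @param consequence One of `"stop_gain"`, `"frameshift"`,
#'   `"essential_splice"`; others return `"not_applicable"`.
#' @param intron_index 1-based intron index (transcript orientation), required
#'   for essential splice variants.
#' @return A list: `nmd_class` (`"triggering"`, `"escape"`,
#'   `"not_applicable"`) and `note`.
#' @export
classify_nmd <- function(tx, ptc_cdna_pos = NULL, consequence = "stop_gain",
                         intron_index = NULL) {
  if (!consequence %in% c("stop_gain", "frameshift", "essential_splice")) {
    return(list(nmd_class = "not_applicable", note = ""))
  }
  n_exons <- nrow(tx$exons)
  if (n_exons == 1) {
    return(list(nmd_class = "escape", note = "single-exon transcript"))
  }
  if (consequence == "essential_splice") {
    if (is.null(intron_index) || is.na(intron_index)) {
      abort("essential_splice NMD assignment needs intron_index")
    }
    cls <- if (intron_index == n_exons - 1) "escape" else "triggering"
    return(list(nmd_class = cls, note = "splice-inferred"))
  }
  if (is.null(ptc_cdna_pos) || is.na(ptc_cdna_pos)) {
    return(list(nmd_class = "escape", note = "nonstop: no PTC, cannot trigger NMD"))
  }
  off <- exon_offsets(tx)
  penult_end <- off[n_exons]                 # spliced coord of penultimate 3' end
  ptc_sp <- ptc_cdna_pos + utr5_length(tx)
  cls <- if (ptc_sp >= penult_end - 50) "escape" else "triggering"
  list(nmd_class = cls, note = "")
}

# ---- table-level annotation -------------------------------------------------

#' Annotate a variant table against a set of transcript models
#'
#' The tibble-first entry point of the annotation stage: classifies each
#' variant, predicts truncated proteins for stop-gains and frameshifts, and
#' applies the 50-bp NMD rule.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF conventions, decomposed bi-allelic records); an optional
#'   `variant_id` column is carried through.
#' @param txs Named list of [transcript_model()] objects; variants are matched
#'   to transcripts by `chrom` and span overlap.
#' @return A tibble: input columns plus `gene`, `tx_id`, `consequence`,
#'   `hgvs_p`, `ptc_cdna_pos`, `ptc_protein_pos`, `nmd_class`, `nmd_note`,
#'   `mutant_protein`. Variants overlapping no transcript get
#'   `gene = NA` and `consequence = "other"`.
#' @examples
#' annotate_variants(ins_variant_panel(), toy_transcripts())
#' @export
annotate_variants <- function(variants, txs) {
  variants <- as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- paste0(variants$chrom, ":", variants$pos, ":",
                                  variants$ref, ">", variants$alt)
  }
  if (nrow(variants) == 0) {
    return(dplyr::bind_cols(variants, tibble(
      gene = character(), tx_id = character(), consequence = character(),
      hgvs_p = character(), ptc_cdna_pos = integer(),
      ptc_protein_pos = integer(), nmd_class = character(),
      nmd_note = character(), mutant_protein = character())))
  }
  spans <- purrr::map(txs, function(tx) {
    list(chrom = tx$chrom, lo = min(tx$exons$start), hi = max(tx$exons$end))
  })
  rows <- purrr::pmap(
    list(variants$chrom, variants$pos, variants$ref, variants$alt),
    function(chrom, pos, ref, alt) {
      hit <- purrr::detect_index(spans, function(s) {
        s$chrom == chrom && pos >= s$lo && pos <= s$hi
      })
      base <- tibble(gene = NA_character_, tx_id = NA_character_,
                     consequence = "other", hgvs_p = NA_character_,
                     ptc_cdna_pos = NA_integer_, ptc_protein_pos = NA_integer_,
                     nmd_class = "not_applicable", nmd_note = "",
                     mutant_protein = NA_character_)
      if (hit == 0) return(base)
      tx <- txs[[hit]]
      cls <- classify_one(pos, ref, alt, tx)
      base$gene <- tx$gene
      base$tx_id <- tx$tx_id
      base$consequence <- cls$consequence
      if (cls$consequence %in% c("stop_gain", "frameshift")) {
        pr <- predict_mutant_protein(pos, ref, alt, tx)
        nmd <- classify_nmd(tx, pr$ptc_cdna_pos, cls$consequence)
        base$hgvs_p <- pr$hgvs_p
        base$ptc_cdna_pos <- pr$ptc_cdna_pos
        base$ptc_protein_pos <- pr$ptc_protein_pos
        base$mutant_protein <- pr$mutant_protein
        base$nmd_class <- nmd$nmd_class
        base$nmd_note <- nmd$note
      } else if (cls$consequence == "essential_splice") {
        nmd <- classify_nmd(tx, consequence = "essential_splice",
                            intron_index = cls$intron_index)
        base$nmd_class <- nmd$nmd_class
        base$nmd_note <- nmd$note
      }
      base
    })
  dplyr::bind_cols(variants, bind_rows(rows))
}

#' Write an annotated variant table as TSV
#'
#' @param annotations Output of [annotate_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- select(annotations, "gene", "variant_id", "chrom", "pos", "ref",
                "alt", "consequence", "hgvs_p", "ptc_protein_pos",
                "nmd_class", "nmd_note")
  readr::write_tsv(out, path)
  invisible(path)
}
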