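tx_ins <- toy_transcripts()[["INS"]]
panel <- ins_variant_panel()

test_that("the published INS truncating variants annotate to their clinical names", {
  ann <- annotate_variants(panel, list(INS = tx_ins))
  expect_equal(ann$hgvs_p, panel$name)
  expect_equal(ann$consequence,
               c("stop_gain", "frameshift", "frameshift", "stop_gain",
                 "stop_gain", "stop_gain"))
  # truncated-protein lengths: Gln78* keeps 77 residues; Leu82GlyfsTer52
  # keeps 81 + 51 novel residues
  expect_equal(nchar(ann$mutant_protein),
               c(77L, 132L, 139L, 94L, 102L, 107L))
  # all PTCs sit in the final exon of the 3-exon model: NMD escape
  expect_true(all(ann$nmd_class == "escape"))
  expect_false(any(grepl("\\*", ann$mutant_protein)))
})

test_that("non-LOF classes are recognised", {
  # third-position change preserving the residue: codon 10 CTG -> CTC (Leu)
  u5 <- modyburden:::utr5_length(tx_ins)
  pos_syn <- cdna_to_genomic(30, tx_ins)
  expect_equal(classify_consequence(pos_syn, "G", "C", tx_ins), "synonymous")
  # 3-bp in-frame deletion inside the CDS is not LOF
  p <- cdna_to_genomic(100, tx_ins)
  ref4 <- substr(tx_ins$spliced_seq, u5 + 100, u5 + 103)
  expect_equal(classify_consequence(p, ref4, substr(ref4, 1, 1), tx_ins),
               "other")
  # missense
  pos_mis <- cdna_to_genomic(4, tx_ins)   # codon 2 GCC -> ACC (Ala -> Thr)
  expect_equal(classify_consequence(pos_mis, "G", "A", tx_ins), "missense")
  # multi-allelic records must be decomposed upstream
  expect_error(classify_consequence(pos_mis, "G", "A,C", tx_ins),
               "multi-allelic")
  # REF mismatch is caught when a reference is available
  expect_error(classify_consequence(pos_mis, "T", "A", tx_ins), "mismatch")
})

test_that("a frameshift whose shifted frame stops immediately gives fsTer2", {
  # CDS ATG GCA ATA AGG TAA; deleting c.4 gives codon2 CAA (Gln), codon3 TAA
  tx <- transcript_model(
    "MINI", "MINI.1", "chrM", "+",
    tibble::tibble(start = 11, end = 34),
    cds_start = 14, cds_end = 28,
    spliced_seq = paste0("AAA", "ATGGCAATAAGGTAA", "CCCCCC"),
    genome_seq = paste0(strrep("T", 10), "AAA", "ATGGCAATAAGGTAA", "CCCCCC"))
  pos <- cdna_to_genomic(3, tx)     # anchor G, delete c.4 (G)
  out <- predict_mutant_protein(pos, "GG", "G", tx)
  expect_equal(out$hgvs_p, "p.Ala2GlnfsTer2")
  expect_equal(nchar(out$mutant_protein), 2)
  expect_false(out$nonstop)
})

test_that("frameshifts without a downstream stop are flagged nonstop and escape NMD", {
  # 3'UTR free of stops in every frame (no T at all); 2 exons so the
  # single-exon rule does not pre-empt the nonstop note
  S <- paste0("AAA", "ATGGCAAGGGCATAA", "CCCACCACCACCACC")
  tx <- modyburden:::build_tx_from_chunks(
    "NS", "NS.1", "+", "AAA", "ATGGCAAGGGCATAA", "CCCACCACCACCACC",
    exon_chunks = c(substr(S, 1, 20), substr(S, 21, 33)))
  pos <- cdna_to_genomic(6, tx)     # delete c.7 -> shifted frame, stop lost
  out <- predict_mutant_protein(pos, "AA", "A", tx)
  expect_true(out$nonstop)
  expect_match(out$hgvs_p, "fs$")
  nmd <- classify_nmd(tx, out$ptc_cdna_pos, "frameshift")
  expect_equal(nmd$nmd_class, "escape")
  expect_match(nmd$note, "nonstop")
})

test_that("the 50-bp rule boundary is exact on both sides", {
  tx <- toy_transcripts()[["GCK"]]          # 5 exons
  off <- modyburden:::exon_offsets(tx)
  penult_end_sp <- off[nrow(tx$exons)]
  u5 <- modyburden:::utr5_length(tx)
  at <- function(d) classify_nmd(tx, (penult_end_sp - d) - u5,
                                 "stop_gain")$nmd_class
  expect_equal(at(50), "escape")
  expect_equal(at(51), "triggering")
  expect_equal(at(0), "escape")             # at the junction itself
  # PTC in the final exon
  expect_equal(classify_nmd(tx, penult_end_sp + 10 - u5,
                            "stop_gain")$nmd_class, "escape")
})

test_that("single-exon transcripts always escape NMD", {
  for (g in c("KCNJ11", "NEUROD1")) {
    tx <- toy_transcripts()[[g]]
    sites <- modyburden:::candidate_sites(tx, "NMD_escape", n_max = 5)
    expect_gt(nrow(sites), 0)
    ann <- annotate_variants(sites, toy_transcripts())
    expect_true(all(ann$consequence == "stop_gain"))
    expect_true(all(ann$nmd_class == "escape"))
    expect_true(all(ann$nmd_note == "single-exon transcript"))
  }
})

test_that("essential splice variants are assigned NMD status by intron, flagged splice-inferred", {
  tx <- toy_transcripts()[["GCK"]]          # 5 exons, 4 introns
  don1 <- tx$exons$end[1] + 1
  ann1 <- annotate_variants(
    tibble::tibble(chrom = tx$chrom, pos = don1,
                   ref = substr(tx$genome_seq, don1, don1), alt = "C"),
    toy_transcripts())
  expect_equal(ann1$consequence, "essential_splice")
  expect_equal(ann1$nmd_class, "triggering")
  expect_equal(ann1$nmd_note, "splice-inferred")
  last_acc <- tx$exons$start[5] - 1
  ann2 <- annotate_variants(
    tibble::tibble(chrom = tx$chrom, pos = last_acc,
                   ref = substr(tx$genome_seq, last_acc, last_acc), alt = "T"),
    toy_transcripts())
  expect_equal(ann2$consequence, "essential_splice")
  expect_equal(ann2$nmd_class, "escape")
})

test_that("NMD classification depends only on PTC position and exon structure", {
  tx <- toy_transcripts()[["GCK"]]
  base <- classify_nmd(tx, 100, "stop_gain")$nmd_class
  tx2 <- tx
  tx2$gene <- "RENAMED"; tx2$tx_id <- "OTHER.9"; tx2$chrom <- "chrZ"
  expect_equal(classify_nmd(tx2, 100, "stop_gain")$nmd_class, base)
})

test_that("frameshift prediction matches an independent full-translation oracle", {
  # 1000 random engineered frameshifts across random toy transcripts
  set.seed(20260921)
  n_checked <- 0
  k <- 0
  while (n_checked < 1000 && k < 200) {
    k <- k + 1
    tx <- modyburden:::make_toy_tx("FZ", "FZ.1", n_exons = sample(1:3, 1),
                                   n_codons = sample(25:60, 1),
                                   strand = sample(c("+", "-"), 1),
                                   seed = 5000 + k)
    cds <- modyburden:::cds_span_spliced(tx)
    u5 <- modyburden:::utr5_length(tx)
    S <- tx$spliced_seq
    tries <- 0
    while (tries < 25 && n_checked < 1000) {
      tries <- tries + 1
      cdna <- sample(seq(2, cds[2] - cds[1] - 6), 1)
      sp <- cdna + u5
      width <- sample(1:2, 1)               # delete 1 or 2 bases
      if (sp + width > nchar(S)) next
      ref_tx <- substr(S, sp, sp + width)   # transcript-space anchor + deleted
      # express as a left-anchored plus-strand VCF record
      if (tx$strand == "+") {
        pos <- cdna_to_genomic(cdna, tx)
        ref <- ref_tx; alt <- substr(ref_tx, 1, 1)
        # deletes spliced sp+1 .. sp+width
        mut_mrna <- paste0(substr(S, 1, sp), substr(S, sp + width + 1,
                                                    nchar(S)))
      } else {
        pos <- cdna_to_genomic(cdna + width, tx)
        ref <- modyburden:::revcomp(ref_tx); alt <- substr(ref, 1, 1)
        # genomic left anchor keeps spliced sp+width: deletes sp .. sp+width-1
        mut_mrna <- paste0(substr(S, 1, sp - 1), substr(S, sp + width,
                                                        nchar(S)))
      }
      cons <- tryCatch(classify_consequence(pos, ref, alt, tx),
                       error = function(e) "error")
      if (cons != "frameshift") next
      out <- predict_mutant_protein(pos, ref, alt, tx)
      # oracle: hand-edited spliced mRNA, translated with Biostrings
      expected <- oracle_translate_to_stop(mut_mrna, cds[1])
      expect_identical(out$mutant_protein, expected)
      if (!out$nonstop && grepl("fsTer", out$hgvs_p)) {
        k_count <- as.integer(sub(".*fsTer(\\d+)$", "\\1", out$hgvs_p))
        first_changed <- as.integer(sub("^p\\.[A-Za-z]{3}(\\d+).*$", "\\1",
                                        out$hgvs_p))
        expect_equal(k_count, nchar(expected) + 2L - first_changed)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})
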