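# Bundled synthetic transcript models for the ten MODY genes.
#
# These are toy models with realistic exon-count structure (single-exon
# KCNJ11/NEUROD1 analogues, a 3-exon INS analogue whose final exon carries the
# B/C/A-chain boundary region), not real RefSeq records. The INS analogue
# encodes the true 110-aa human preproinsulin protein on an engineered
# synthetic CDS, so residue numbering (signal 1-24, B chain 25-54, C-peptide
# 57-87, A chain 90-110, cysteines 31/43/95/96/100/109) matches the clinical
# literature, and the bundled variant panel reproduces the published HGVS
# names (p.Gln78*, p.Leu82GlyfsTer52, p.Glu83ValfsTer58, p.Cys95*, p.Tyr103*,
# p.Tyr108*) from concrete nucleotide edits.

# engineered INS-analogue sequences (see the methods vignette):
# the CDS encodes preproinsulin; the 3'UTR is stop-free in the two frameshift
# frames except at the positions that give fsTer52 (from codon 82, frame +2)
# and fsTer58 (from codon 83, frame +1).
INS_TOY_CDS <- paste0(
  "ATGGCCCTGTGGATGAGGCTGCTGCCCCTGCTGGCCCTGCTGGCCCTGTGGGGCCCCGACCCCGCCGCC",
  "GCCTTCGTGAACCAGCACCTGTGCGGCAGCCACCTGGTGGAGGCCCTGTACCTGGTGTGCGGCGAGAGG",
  "GGCTTCTTCTACACCCCCAAGACCAGGAGGGAGGCCGAGGACCTGCAGGTGGGCCAGGTGGAGCTGGGC",
  "GGCGGCCCCGGCGCCGGCAGCCTGCAGCCCCTGGCCCTGGAAGGCAGCCTGCAGAAGAGGGGCATCGTG",
  "GAGCAGTGCTGCACCAGCATCTGCAGCCTGTACCAGCTGGAGAACTACTGCAACTAA")
INS_TOY_UTR3 <- paste0(
  "CAACGACCACAACGACCACAACGACCACAACGACCACAACGACCACAACGACCACAACGACCACATAA",
  "ACCACAACGACCACTAAGACCACAACGACCACAACGACCACAACGACCA")
INS_TOY_UTR5 <- strrep("AGCACC", 10)

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0)),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

# assemble a transcript_model from spliced-chunk exons + intron filler
#' @keywords internal
build_tx_from_chunks <- function(gene, tx_id, strand, utr5, cds, utr3,
                                 exon_chunks, intron_len = 120, flank = 10) {
  spliced <- paste0(utr5, cds, utr3)
  stopifnot(sum(nchar(exon_chunks)) == nchar(spliced))
  intron <- paste0("GT", strrep("C", intron_len - 4), "AG")
  n <- length(exon_chunks)
  # sense-orientation genome and exon coordinates
  genome_sense <- strrep("A", flank)
  starts <- ends <- integer(n)
  for (i in seq_len(n)) {
    starts[i] <- nchar(genome_sense) + 1
    genome_sense <- paste0(genome_sense, exon_chunks[i])
    ends[i] <- nchar(genome_sense)
    if (i < n) genome_sense <- paste0(genome_sense, intron)
  }
  genome_sense <- paste0(genome_sense, strrep("A", flank))
  # CDS endpoints in sense coordinates
  cs_spliced <- nchar(utr5) + 1
  ce_spliced <- nchar(utr5) + nchar(cds)
  sp2sense <- function(sp) {
    cum <- c(0, cumsum(nchar(exon_chunks)))
    i <- findInterval(sp - 1e-9, cum)
    starts[i] + (sp - cum[i]) - 1
  }
  cds_sense <- c(sp2sense(cs_spliced), sp2sense(ce_spliced))
  if (strand == "+") {
    transcript_model(gene, tx_id, chrom = paste0("chr_", gene), strand = "+",
                     exons = tibble(start = starts, end = ends),
                     cds_start = cds_sense[1], cds_end = cds_sense[2],
                     spliced_seq = spliced, genome_seq = genome_sense)
  } else {
    lg <- nchar(genome_sense)
    transcript_model(gene, tx_id, chrom = paste0("chr_", gene), strand = "-",
                     exons = tibble(start = lg - ends + 1, end = lg - starts + 1),
                     cds_start = lg - cds_sense[2] + 1,
                     cds_end = lg - cds_sense[1] + 1,
                     spliced_seq = spliced, genome_seq = revcomp(genome_sense))
  }
}

# deterministic generic toy gene: random sense codons, UTRs, n exons
#' @keywords internal
make_toy_tx <- function(gene, tx_id, n_exons, n_codons, strand = "+",
                        seed = 1) {
  with_seed_if(seed + 1000L, {
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n_codons - 2, replace = TRUE),
                        collapse = ""),
                  "TAA")
    utr5 <- paste(sample(c("A", "C", "G"), 30, replace = TRUE), collapse = "")
    utr3 <- paste(sample(c("A", "C", "G"), 60, replace = TRUE), collapse = "")
    spliced <- paste0(utr5, cds, utr3)
    L <- nchar(spliced)
    cuts <- unique(round(seq(0, L, length.out = n_exons + 1)))
    chunks <- substring(spliced, head(cuts, -1) + 1, cuts[-1])
    build_tx_from_chunks(gene, tx_id, strand, utr5, cds, utr3, chunks)
  })
}

#' Bundled synthetic transcript models for the ten MODY genes
#'
#' Deterministic toy models: single-exon `KCNJ11` and `NEUROD1` analogues,
#' a 3-exon `INS` analogue encoding human preproinsulin with the published
#' truncating variants realisable as nucleotide edits (see
#' [ins_variant_panel()]), and generic multi-exon analogues for the remaining
#' genes (one of them, `HNF1B`, on the minus strand to exercise strand
#' handling). These are synthetic stand-ins with realistic structure, not
#' RefSeq records.
#'
#' @return Named list of [transcript_model()] objects.
#' @examples
#' names(toy_transcripts())
#' @export
toy_transcripts <- function() {
  ins_chunks <- c(
    substr(paste0(INS_TOY_UTR5, INS_TOY_CDS, INS_TOY_UTR3), 1, 50),
    substr(paste0(INS_TOY_UTR5, INS_TOY_CDS, INS_TOY_UTR3), 51, 246),
    substr(paste0(INS_TOY_UTR5, INS_TOY_CDS, INS_TOY_UTR3), 247, 510))
  ins <- build_tx_from_chunks("INS", "TOY_INS.1", "+",
                              INS_TOY_UTR5, INS_TOY_CDS, INS_TOY_UTR3,
                              ins_chunks)
  list(
    GCK    = make_toy_tx("GCK", "TOY_GCK.1", 5, 120, seed = 101),
    HNF1A  = make_toy_tx("HNF1A", "TOY_HNF1A.1", 4, 110, seed = 102),
    HNF4A  = make_toy_tx("HNF4A", "TOY_HNF4A.1", 4, 100, seed = 103),
    HNF1B  = make_toy_tx("HNF1B", "TOY_HNF1B.1", 4, 100, strand = "-",
                         seed = 104),
    ABCC8  = make_toy_tx("ABCC8", "TOY_ABCC8.1", 6, 160, seed = 105),
    KCNJ11 = make_toy_tx("KCNJ11", "TOY_KCNJ11.1", 1, 90, seed = 106),
    NEUROD1 = make_toy_tx("NEUROD1", "TOY_NEUROD1.1", 1, 90, seed = 107),
    PDX1   = make_toy_tx("PDX1", "TOY_PDX1.1", 2, 90, seed = 108),
    RFX6   = make_toy_tx("RFX6", "TOY_RFX6.1", 5, 150, seed = 109),
    INS    = ins)
}

#' Published INS truncating-variant panel on the bundled INS analogue
#'
#' Concrete nucleotide edits on the synthetic INS transcript that reproduce
#' the clinically reported protein consequences: four MODY-associated
#' NMD-escape variants (p.Gln78*, p.Leu82GlyfsTer52, p.Cys95*,
#' p.Glu83ValfsTer58) and two neonatal-diabetes variants (p.Tyr103*,
#' p.Tyr108*).
#'
#' @return Tibble with columns `name` (expected HGVS p.), `chrom`, `pos`,
#'   `ref`, `alt`.
#' @examples
#' ins_variant_panel()
#' @export
ins_variant_panel <- function() {
  tx <- toy_transcripts()[["INS"]]
  base_at <- function(cd) {
    sp <- cd + utr5_length(tx)
    substr(tx$spliced_seq, sp, sp)
  }
  g <- function(cd) cdna_to_genomic(cd, tx)
  tibble(
    name = c("p.Gln78*", "p.Leu82GlyfsTer52", "p.Glu83ValfsTer58",
             "p.Cys95*", "p.Tyr103*", "p.Tyr108*"),
    chrom = tx$chrom,
    pos = c(g(232), g(243), g(247), g(285), g(309), g(324)),
    ref = c("C", paste0(base_at(243), "CT"), "G", "C", "C", "C"),
    alt = c("T", base_at(243), "GTT", "A", "A", "A"))
}
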