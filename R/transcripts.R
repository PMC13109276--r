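# Transcript models and coordinate mapping.
#
# A transcript model is the coordinate frame for every consequence and NMD
# call: genomic exon intervals (1-based, inclusive), a genomic CDS interval,
# strand, and the spliced (mature mRNA) sequence in transcript orientation.
# cDNA coordinates follow HGVS c. numbering: c.1 is the A of the initiator
# ATG; intronic positions are expressed as the nearest exon boundary plus a
# signed offset (c.N+k / c.N-k).

#' Construct a transcript model
#'
#' @param gene Gene symbol.
#' @param tx_id Transcript identifier.
#' @param chrom Chromosome/contig name the exon coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`: genomic exon intervals,
#'   1-based inclusive, non-overlapping.
#' @param cds_start,cds_end Genomic positions of the CDS interval (the interval
#'   includes the stop codon); `cds_start <= cds_end` in genomic coordinates
#'   irrespective of strand.
#' @param spliced_seq Nucleotide string of the mature mRNA (5'UTR + CDS +
#'   3'UTR) in transcript orientation.
#' @param genome_seq Optional nucleotide string of the genomic reference for
#'   `chrom` (plus strand), used for reference-allele checks at intronic
#'   positions.
#' @return An object of class `transcript_model`.
#' @examples
#' tx <- toy_transcripts()[["INS"]]
#' tx
#' @export
transcript_model <- function(gene, tx_id, chrom, strand, exons,
                             cds_start, cds_end, spliced_seq,
                             genome_seq = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (any(exons$end < exons$start)) abort("exon end precedes start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons overlap or touch")
  }
  tx <- structure(
    list(gene = gene, tx_id = tx_id, chrom = chrom, strand = strand,
         exons = exons, cds_start = cds_start, cds_end = cds_end,
         spliced_seq = toupper(spliced_seq), genome_seq = genome_seq),
    class = "transcript_model"
  )
  validate_transcript(tx)
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- cds_span_spliced(x)
  cat(sprintf(
    "<transcript_model> %s (%s) %s strand, %d exon(s), CDS %d nt (%d aa), mRNA %d nt\n",
    x$gene, x$tx_id, x$strand, nrow(x$exons),
    cds[2] - cds[1] + 1, (cds[2] - cds[1] + 1) / 3 - 1, nchar(x$spliced_seq)))
  invisible(x)
}

#' @keywords internal
validate_transcript <- function(tx) {
  widths <- tx$exons$end - tx$exons$start + 1
  if (sum(widths) != nchar(tx$spliced_seq)) {
    abort(sprintf("spliced sequence length (%d) != total exon width (%d)",
                  nchar(tx$spliced_seq), sum(widths)))
  }
  cds <- cds_span_spliced(tx)
  cds_len <- cds[2] - cds[1] + 1
  if (cds_len %% 3 != 0) abort("CDS length is not a multiple of 3")
  aa <- translate_frame(substr(tx$spliced_seq, cds[1], cds[2]), to_stop = FALSE)
  aa_chr <- strsplit(aa$aa, "")[[1]]
  if (tail(aa_chr, 1) != "*") abort("CDS does not end in a stop codon")
  if (any(aa_chr[-length(aa_chr)] == "*")) abort("CDS has an internal stop codon")
  invisible(tx)
}

# ---- internal coordinate machinery -----------------------------------------

# exons ordered 5'->3' in transcript orientation
#' @keywords internal
exons_tx_order <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), ]
}

# cumulative spliced offset before each exon (tx order)
#' @keywords internal
exon_offsets <- function(tx) {
  ex <- exons_tx_order(tx)
  w <- ex$end - ex$start + 1
  c(0, cumsum(w))[seq_len(nrow(ex))]
}

#' @keywords internal
genomic_to_spliced <- function(pos, tx) {
  ex <- exons_tx_order(tx)
  off <- exon_offsets(tx)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    hit <- pos >= ex$start[i] & pos <= ex$end[i]
    if (!any(hit)) next
    within <- if (tx$strand == "+") pos[hit] - ex$start[i] + 1
              else ex$end[i] - pos[hit] + 1
    out[hit] <- off[i] + within
  }
  out
}

#' @keywords internal
spliced_to_genomic <- function(spos, tx) {
  ex <- exons_tx_order(tx)
  off <- exon_offsets(tx)
  w <- ex$end - ex$start + 1
  out <- rep(NA_integer_, length(spos))
  for (i in seq_len(nrow(ex))) {
    hit <- spos > off[i] & spos <= off[i] + w[i]
    if (!any(hit)) next
    within <- spos[hit] - off[i]
    out[hit] <- if (tx$strand == "+") ex$start[i] + within - 1
                else ex$end[i] - within + 1
  }
  out
}

# spliced-coordinate span of the CDS, c(start, end)
#' @keywords internal
cds_span_spliced <- function(tx) {
  sort(genomic_to_spliced(c(tx$cds_start, tx$cds_end), tx))
}

#' @keywords internal
utr5_length <- function(tx) cds_span_spliced(tx)[1] - 1L

# reference base at a genomic position, in plus-strand (genomic) orientation
#' @keywords internal
genomic_ref_base <- function(pos, tx) {
  sp <- genomic_to_spliced(pos, tx)
  if (!is.na(sp)) {
    b <- substr(tx$spliced_seq, sp, sp)
    return(if (tx$strand == "+") b else revcomp(b))
  }
  if (!is.null(tx$genome_seq)) return(substr(tx$genome_seq, pos, pos))
  NA_character_
}

# ---- user-facing coordinate mapping ----------------------------------------

#' Map genomic positions to cDNA (HGVS c.) coordinates
#'
#' Exonic positions map to 1-based cDNA coordinates counted from the
#' translation start (c.1 = A of ATG); 5'UTR positions yield zero or negative
#' numbers and 3'UTR positions continue past the CDS end (the `region` column
#' disambiguates). Intronic positions return the nearest exon-boundary cDNA
#' coordinate plus a signed offset, HGVS style (`c.N+k` after a donor,
#' `c.N-k` before an acceptor).
#'
#' @param pos Integer vector of genomic positions.
#' @param tx A [transcript_model()].
#' @return A tibble with one row per position: `pos`, `region`
#'   (`"utr5"`, `"cds"`, `"utr3"`, `"intron"`), `spliced_pos`, `cdna_pos`
#'   (for introns: the boundary exon position), `offset` (0 for exonic),
#'   `intron_index` (NA for exonic) and `label` (HGVS-style c. string).
#' @examples
#' tx <- toy_transcripts()[["INS"]]
#' genomic_to_cdna(tx$cds_start, tx)   # c.1
#' @export
genomic_to_cdna <- function(pos, tx) {
  span <- range(c(tx$exons$start, tx$exons$end))
  if (any(pos < span[1] | pos > span[2])) {
    abort(sprintf("position(s) outside transcript span [%d, %d]",
                  span[1], span[2]))
  }
  u5 <- utr5_length(tx)
  cds <- cds_span_spliced(tx)
  rows <- purrr::map(pos, function(p) {
    sp <- genomic_to_spliced(p, tx)
    if (!is.na(sp)) {
      cd <- sp - u5
      region <- if (sp < cds[1]) "utr5" else if (sp > cds[2]) "utr3" else "cds"
      lab <- if (region == "utr5") paste0("c.", cd - 1L)  # c.0 does not exist
             else if (region == "utr3") paste0("c.*", sp - cds[2])
             else paste0("c.", cd)
      return(tibble(pos = p, region = region, spliced_pos = sp,
                    cdna_pos = cd, offset = 0L, intron_index = NA_integer_,
                    label = lab))
    }
    intr <- locate_intron(p, tx)
    bnd_cd <- intr$boundary_spliced - u5
    lab <- paste0("c.", bnd_cd, ifelse(intr$offset > 0, "+", ""), intr$offset)
    tibble(pos = p, region = "intron", spliced_pos = NA_integer_,
           cdna_pos = bnd_cd, offset = intr$offset,
           intron_index = intr$intron_index, label = lab)
  })
  bind_rows(rows)
}

# nearest-boundary descriptor for an intronic genomic position
#' @keywords internal
locate_intron <- function(pos, tx) {
  ex <- exons_tx_order(tx)
  off <- exon_offsets(tx)
  w <- ex$end - ex$start + 1
  n <- nrow(ex)
  for (i in seq_len(n - 1)) {
    if (tx$strand == "+") {
      lo <- ex$end[i] + 1; hi <- ex$start[i + 1] - 1
      inside <- pos >= lo && pos <= hi
      donor_off <- pos - ex$end[i]
      acceptor_off <- pos - ex$start[i + 1]
    } else {
      lo <- ex$end[i + 1] + 1; hi <- ex$start[i] - 1
      inside <- pos >= lo && pos <= hi
      donor_off <- ex$start[i] - pos
      acceptor_off <- ex$end[i + 1] - pos
    }
    if (inside) {
      use_donor <- abs(donor_off) <= abs(acceptor_off)
      return(list(
        intron_index = i,
        offset = if (use_donor) donor_off else acceptor_off,
        boundary_spliced = if (use_donor) off[i] + w[i] else off[i + 1] + 1L,
        donor_offset = donor_off, acceptor_offset = acceptor_off))
    }
  }
  abort("position is neither exonic nor intronic within the transcript span")
}

#' Map cDNA coordinates back to genomic positions
#'
#' Inverse of [genomic_to_cdna()] for exonic coordinates.
#'
#' @param cdna_pos Integer vector of cDNA positions (c.1 = first CDS base;
#'   values may extend into the UTRs).
#' @param tx A [transcript_model()].
#' @return Integer vector of genomic positions.
#' @export
cdna_to_genomic <- function(cdna_pos, tx) {
  sp <- cdna_pos + utr5_length(tx)
  out <- spliced_to_genomic(sp, tx)
  if (any(is.na(out))) abort("cDNA position outside the spliced transcript")
  out
}

#' Classify a genomic position relative to essential splice sites
#'
#' Essential (canonical) splice positions are the first two and last two bases
#' of an intron: donor +1/+2 and acceptor -1/-2. Single-exon transcripts have
#' no introns and always return `"non_splice"`.
#'
#' @param pos Integer vector of genomic positions.
#' @param tx A [transcript_model()].
#' @return Character vector: `"essential_splice"` or `"non_splice"`.
#' @export
splice_region_class <- function(pos, tx) {
  vapply(pos, function(p) {
    if (nrow(tx$exons) < 2) return("non_splice")
    sp <- genomic_to_spliced(p, tx)
    if (!is.na(sp)) return("non_splice")
    intr <- tryCatch(locate_intron(p, tx), error = function(e) NULL)
    if (is.null(intr)) return("non_splice")
    if (intr$donor_offset %in% c(1, 2) ||
        intr$acceptor_offset %in% c(-1, -2)) "essential_splice"
    else "non_splice"
  }, "")
}

# ---- IO ---------------------------------------------------------------------

#' Read transcript models from the package JSON dialect
#'
#' The dialect is a JSON array of objects
#' `{gene, id, chrom, strand, exons: [[start, end], ...], cds: [start, end],
#' sequence, genome_sequence?}` with 1-based inclusive coordinates and the
#' spliced sequence in transcript orientation.
#'
#' @param path Path to a JSON file.
#' @return Named list of [transcript_model()] objects (names = gene symbols).
#' @export
read_transcripts_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- purrr::map(recs, function(r) {
    ex <- do.call(rbind, lapply(r$exons, unlist))
    transcript_model(
      gene = r$gene, tx_id = r$id, chrom = r$chrom %||% r$gene,
      strand = r$strand,
      exons = tibble(start = ex[, 1], end = ex[, 2]),
      cds_start = r$cds[[1]], cds_end = r$cds[[2]],
      spliced_seq = r$sequence, genome_seq = r$genome_sequence)
  })
  setNames(out, purrr::map_chr(out, "gene"))
}

#' Write transcript models to the package JSON dialect
#'
#' @param txs Named list of [transcript_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_json <- function(txs, path) {
  recs <- purrr::map(unname(txs), function(tx) {
    list(gene = tx$gene, id = tx$tx_id, chrom = tx$chrom, strand = tx$strand,
         exons = purrr::map2(tx$exons$start, tx$exons$end, c),
         cds = c(tx$cds_start, tx$cds_end),
         sequence = tx$spliced_seq, genome_sequence = tx$genome_seq)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Write transcript models as GFF3 plus a spliced-sequence FASTA
#'
#' Emits `exon` and `CDS` features (one file) and the spliced sequences named
#' by transcript id (second file). The pair round-trips through
#' [read_transcripts_gff3()].
#'
#' @param txs Named list of [transcript_model()] objects.
#' @param gff_path,fasta_path Output paths.
#' @return `gff_path`, invisibly.
#' @export
write_transcripts_gff3 <- function(txs, gff_path, fasta_path) {
  lines <- c("##gff-version 3")
  for (tx in txs) {
    lines <- c(lines, sprintf(
      "%s\tmodyburden\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_name=%s",
      tx$chrom, min(tx$exons$start), max(tx$exons$end), tx$strand,
      tx$tx_id, tx$gene))
    for (i in seq_len(nrow(tx$exons))) {
      lines <- c(lines, sprintf(
        "%s\tmodyburden\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        tx$chrom, tx$exons$start[i], tx$exons$end[i], tx$strand, tx$tx_id))
    }
    lines <- c(lines, sprintf(
      "%s\tmodyburden\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
      tx$chrom, tx$cds_start, tx$cds_end, tx$strand, tx$tx_id))
  }
  readr::write_lines(lines, gff_path)
  seqs <- Biostrings::DNAStringSet(purrr::map_chr(txs, "spliced_seq"))
  names(seqs) <- purrr::map_chr(txs, "tx_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(gff_path)
}

#' Read transcript models from GFF3 + spliced-sequence FASTA
#'
#' Expects `exon` features with a `Parent` attribute, one `CDS` feature per
#' transcript spanning the genomic CDS interval, and `mRNA` features carrying
#' `ID` and `gene_name`. Spliced sequences are read from `fasta_path`, named
#' by transcript id. Requires the rtracklayer package.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to a FASTA of spliced transcript sequences.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts_gff3 <- function(gff_path, fasta_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_transcripts_gff3() requires the rtracklayer package")
  }
  g <- rtracklayer::import(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- as.data.frame(g)
  mrna <- meta[meta$type == "mRNA", ]
  out <- purrr::map(seq_len(nrow(mrna)), function(i) {
    id <- mrna$ID[i]
    kids <- meta[!is.na(meta$Parent) & lengths(meta$Parent) > 0 &
                   vapply(meta$Parent, function(p) id %in% p, TRUE), ]
    ex <- kids[kids$type == "exon", ]
    cds <- kids[kids$type == "CDS", ]
    transcript_model(
      gene = mrna$gene_name[i], tx_id = id,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exons = tibble(start = ex$start, end = ex$end),
      cds_start = min(cds$start), cds_end = max(cds$end),
      spliced_seq = as.character(seqs[[id]]))
  })
  setNames(out, purrr::map_chr(out, "gene"))
}
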