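# small sequence helpers shared across modules

STOP_CODONS <- c("TAA", "TAG", "TGA")

AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Ter"
)

#' Translate a nucleotide string in reading frame 1
#'
#' Walks codons from the first base until the first stop codon (or the last
#' complete codon when no stop is found). The standard genetic code is used.
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param to_stop Stop at (and exclude) the first stop codon. When `FALSE` the
#'   full translation is returned with `*` for stops.
#' @return List with `aa` (amino-acid string, one-letter), `hit_stop` (logical,
#'   whether a stop codon terminated translation).
#' @keywords internal
translate_frame <- function(seq, to_stop = TRUE) {
  gc_tab <- as.character(Biostrings::GENETIC_CODE)
  names(gc_tab) <- names(Biostrings::GENETIC_CODE)
  n <- floor(nchar(seq) / 3)
  if (n == 0) return(list(aa = "", hit_stop = FALSE))
  starts <- 3 * seq_len(n) - 2
  codons <- substring(seq, starts, starts + 2)
  aa <- unname(gc_tab[codons])
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) {
      return(list(aa = paste(aa[seq_len(stop_at[1] - 1)], collapse = ""),
                  hit_stop = TRUE))
    }
    return(list(aa = paste(aa, collapse = ""), hit_stop = FALSE))
  }
  list(aa = paste(aa, collapse = ""), hit_stop = any(aa == "*"))
}

#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @keywords internal
aa_three <- function(aa1) {
  out <- AA3[strsplit(aa1, "")[[1]]]
  paste(out, collapse = "")
}

# deterministic RNG scoping: run code under a seed without touching the
# caller's RNG stream
#' @keywords internal
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
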