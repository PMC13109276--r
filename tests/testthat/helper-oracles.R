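# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct enumeration with choose(), golden-section
# search on the raw conditional likelihood, and Biostrings translation of
# hand-edited mRNA strings.

# exhaustive-enumeration two-sided Fisher p (probability-mass ordering)
oracle_fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; s <- a + c; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || s == 0 || (b + d) == 0) return(1)
  xs <- max(0, s - m2):min(s, m1)
  probs <- choose(m1, xs) * choose(m2, s - xs) / choose(N, s)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force conditional-MLE: coarse log-scale grid + golden-section refine
oracle_cmle_scan <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; s <- a + c
  loglik <- function(lp) {
    xs <- max(0, s - m2):min(s, m1)
    lw <- lchoose(m1, xs) + lchoose(m2, s - xs) + xs * lp
    (lchoose(m1, a) + lchoose(m2, s - a) + a * lp) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  grid <- seq(-15, 15, length.out = 1201)
  best <- grid[which.max(vapply(grid, loglik, 0))]
  gr <- (sqrt(5) - 1) / 2
  lo <- best - 0.05; hi <- best + 0.05
  for (i in 1:200) {
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    if (loglik(x1) < loglik(x2)) lo <- x1 else hi <- x2
  }
  exp((lo + hi) / 2)
}

# full-translation oracle: translate an edited mRNA string from the CDS start
# with Biostrings, stopping at the first stop codon
oracle_translate_to_stop <- function(mrna, cds_start) {
  s <- substr(mrna, cds_start, nchar(mrna))
  s <- substr(s, 1, 3 * (nchar(s) %/% 3))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}

# random small 2x2 table with margins bounded by max_n
random_table <- function(max_n = 30) {
  m1 <- sample(1:max_n, 1)
  m2 <- sample(1:max_n, 1)
  a <- sample(0:m1, 1)
  c <- sample(0:m2, 1)
  c(a = a, b = m1 - a, c = c, d = m2 - c)
}

# a hand-built 3-exon plus-strand toy used for cumulative-sum checks
manual_three_exon_tx <- function() {
  utr5 <- "ACGACG"                               # 6 nt
  cds <- paste0("ATG", "GCCAAAGAT", "CCGGTT", "TAA")  # 21 nt, 6 aa + stop
  utr3 <- "CACACACACA"                           # 10 nt
  spliced <- paste0(utr5, cds, utr3)             # 37 nt
  # exon1: spliced 1-10, exon2: 11-22, exon3: 23-37
  chunks <- c(substr(spliced, 1, 10), substr(spliced, 11, 22),
              substr(spliced, 23, 37))
  modyburden:::build_tx_from_chunks("TOY3", "TOY3.1", "+", utr5, cds, utr3,
                                    chunks, intron_len = 20, flank = 5)
}
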