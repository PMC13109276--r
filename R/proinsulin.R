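# Proinsulin truncation severity from cysteine topology.
#
# Correct insulin folding requires three disulfide bonds between six
# conserved cysteines of preproinsulin (110 aa): B7-A7 (residues 31-96),
# B19-A20 (43-109) and A6-A11 (95-100). Truncating variants that remove or
# disrupt the entire A chain leave the two B-chain cysteines unpaired -
# predicted to cause comparatively mild misfolding (MODY-like). Variants
# truncating late in the A chain retain some but not all A-chain cysteines,
# permitting aberrant crosslinking and severe misfolding (neonatal-like).
# Novel cysteines introduced by frameshift tails are inventoried separately
# and never change the severity class: whether they can pair is a question
# of spatial distance, reported by sg_distances() from supplied coordinates.

#' Preproinsulin domain and disulfide map
#'
#' @param signal,b_chain,c_peptide,a_chain Residue ranges (1-based,
#'   inclusive) of the four domains.
#' @param cysteines Residue indices of the six conserved cysteines.
#' @param disulfides Two-column matrix of disulfide-bonded pairs.
#' @param reference_seq The 110-aa preproinsulin sequence the map indexes
#'   into (defaults to the human sequence carried by the bundled INS
#'   analogue).
#' @return A `proinsulin_map` list.
#' @export
proinsulin_map <- function(signal = c(1, 24), b_chain = c(25, 54),
                           c_peptide = c(57, 87), a_chain = c(90, 110),
                           cysteines = c(31, 43, 95, 96, 100, 109),
                           disulfides = rbind(c(31, 96), c(43, 109),
                                              c(95, 100)),
                           reference_seq = NULL) {
  if (is.null(reference_seq)) {
    reference_seq <- translate_frame(INS_TOY_CDS)$aa
  }
  bad <- cysteines[substring(reference_seq, cysteines, cysteines) != "C"]
  if (length(bad)) {
    abort(paste0("map positions are not cysteines in the reference: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(disulfides[, 1] == disulfides[, 2]) ||
      !all(as.vector(disulfides) %in% cysteines)) {
    abort("disulfide partners must be distinct mapped cysteines")
  }
  structure(list(signal = signal, b_chain = b_chain, c_peptide = c_peptide,
                 a_chain = a_chain, cysteines = cysteines,
                 disulfides = disulfides, reference_seq = reference_seq,
                 length = nchar(reference_seq)),
            class = "proinsulin_map")
}

#' Cysteine inventory of a predicted mutant proinsulin
#'
#' Compares a mutant protein (from [predict_mutant_protein()], stop symbol
#' excluded) against the reference: residues before the first divergence are
#' "in frame"; conserved cysteines in that region are retained, cysteines in
#' a frameshifted novel tail are novel. A retained B-chain cysteine whose
#' A-chain disulfide partner is lost is unpaired.
#'
#' @param mutant_protein Amino-acid string (wild type allowed).
#' @param map A [proinsulin_map()].
#' @return A `truncation_profile` tibble row: `retained_cys` (list column),
#'   `novel_cys` (list column of tail positions), `a_chain_intact`,
#'   `unpaired_b_cys`, `truncated`, `frameshifted`, `pattern`.
#' @examples
#' tx <- toy_transcripts()[["INS"]]
#' v <- ins_variant_panel()
#' p <- predict_mutant_protein(v$pos[1], v$ref[1], v$alt[1], tx)
#' cysteine_inventory(p$mutant_protein)
#' @export
cysteine_inventory <- function(mutant_protein, map = proinsulin_map()) {
  ref <- map$reference_seq
  n_ref <- nchar(ref)
  n_mut <- nchar(mutant_protein)
  # first divergence between mutant and reference
  n <- min(n_ref, n_mut)
  i <- 1
  while (i <= n && substr(ref, i, i) == substr(mutant_protein, i, i)) {
    i <- i + 1
  }
  in_frame_end <- i - 1
  if (in_frame_end >= n_ref && n_mut > n_ref) {
    abort("mutant longer than reference without a frameshift")
  }
  frameshifted <- i <= n_mut && in_frame_end < n_ref
  truncated <- in_frame_end < n_ref
  retained <- map$cysteines[map$cysteines <= in_frame_end]
  novel <- integer(0)
  if (frameshifted && i <= n_mut) {
    tail_aa <- strsplit(substr(mutant_protein, i, n_mut), "")[[1]]
    novel <- (i:n_mut)[tail_aa == "C"]
  }
  a_cys <- map$cysteines[map$cysteines >= map$a_chain[1] &
                           map$cysteines <= map$a_chain[2]]
  b_cys <- map$cysteines[map$cysteines >= map$b_chain[1] &
                           map$cysteines <= map$b_chain[2]]
  partner <- function(p) {
    hit <- map$disulfides[map$disulfides[, 1] == p, 2]
    if (!length(hit)) hit <- map$disulfides[map$disulfides[, 2] == p, 1]
    hit
  }
  unpaired_b <- sum(vapply(intersect(b_cys, retained), function(p) {
    !all(partner(p) %in% retained)
  }, TRUE))
  profile <- tibble(
    retained_cys = list(retained), novel_cys = list(novel),
    a_chain_intact = in_frame_end >= map$a_chain[2],
    unpaired_b_cys = as.integer(unpaired_b),
    truncated = truncated, frameshifted = frameshifted)
  profile$pattern <- classify_pattern(profile, map)
  structure(profile, class = c("truncation_profile", class(profile)))
}

#' Classify truncation severity from cysteine topology
#'
#' `mody_like` when no A-chain cysteine survives in frame (A chain removed or
#' disrupted: unpaired B-chain cysteines, milder misfolding);
#' `neonatal_like` when a proper nonempty subset of A-chain cysteines
#' survives (aberrant crosslinking, severe misfolding); `indeterminate`
#' otherwise (e.g. the full-length wild type). Novel tail cysteines never
#' influence the class.
#'
#' @param profile A [cysteine_inventory()] row.
#' @param map A [proinsulin_map()].
#' @return `"mody_like"`, `"neonatal_like"` or `"indeterminate"`.
#' @export
classify_pattern <- function(profile, map = proinsulin_map()) {
  a_cys <- map$cysteines[map$cysteines >= map$a_chain[1] &
                           map$cysteines <= map$a_chain[2]]
  retained_a <- intersect(profile$retained_cys[[1]], a_cys)
  if (!profile$truncated[[1]]) return("indeterminate")
  if (length(retained_a) == 0) return("mody_like")
  if (length(retained_a) < length(a_cys)) return("neonatal_like")
  "indeterminate"
}

#' Pairwise SG-SG distances between cysteines from atomic coordinates
#'
#' Measures Euclidean distances between the sulfur (SG) atoms of listed
#' cysteine residues; a pair is flagged pairable when closer than `cutoff`
#' (default 5.5 A, chosen above the ~4.8 A typical wild-type SG-SG
#' distance). When a residue has no SG atom its CB atom is used as fallback,
#' flagged in the output; residues with neither atom are skipped with a
#' warning.
#'
#' @param coords A data frame with columns `resno`, `elety`, `x`, `y`, `z`
#'   (one row per atom), or a path to a PDB file (read with bio3d).
#' @param cys_positions Residue numbers to measure between.
#' @param cutoff Pairability cutoff in Angstrom.
#' @return Tibble: `res_i`, `res_j`, `distance`, `pairable`, `atom_i`,
#'   `atom_j`.
#' @export
sg_distances <- function(coords, cys_positions, cutoff = 5.5) {
  if (is.character(coords) && length(coords) == 1) {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      abort("reading PDB files requires the bio3d package")
    }
    pdb <- bio3d::read.pdb(coords)
    coords <- as_tibble(pdb$atom[, c("resno", "elety", "x", "y", "z")])
  }
  coords <- as_tibble(coords)
  atom_for <- function(res) {
    sg <- filter(coords, .data$resno == res, .data$elety == "SG")
    if (nrow(sg)) return(mutate(sg[1, ], used = "SG"))
    cb <- filter(coords, .data$resno == res, .data$elety == "CB")
    if (nrow(cb)) return(mutate(cb[1, ], used = "CB"))
    NULL
  }
  atoms <- purrr::map(cys_positions, atom_for)
  missing <- cys_positions[purrr::map_lgl(atoms, is.null)]
  if (length(missing)) {
    warn(paste0("no SG/CB atom for residue(s): ",
                paste(missing, collapse = ", "), "; pairs skipped"))
  }
  keep <- which(!purrr::map_lgl(atoms, is.null))
  if (length(keep) < 2) {
    return(tibble(res_i = integer(), res_j = integer(), distance = double(),
                  pairable = logical(), atom_i = character(),
                  atom_j = character()))
  }
  pairs <- utils::combn(keep, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    ai <- atoms[[pairs[1, k]]]
    aj <- atoms[[pairs[2, k]]]
    d <- sqrt((ai$x - aj$x)^2 + (ai$y - aj$y)^2 + (ai$z - aj$z)^2)
    tibble(res_i = cys_positions[pairs[1, k]],
           res_j = cys_positions[pairs[2, k]],
           distance = d, pairable = d < cutoff,
           atom_i = ai$used, atom_j = aj$used)
  })
  bind_rows(rows)
}

#' Profile the published INS truncation panel
#'
#' Runs annotation, cysteine inventory and severity classification for the
#' bundled panel of published INS truncating variants on the synthetic INS
#' analogue.
#'
#' @return Tibble: `name`, `hgvs_p`, `nmd_class`, `pattern`,
#'   `unpaired_b_cys`, `novel_cys_n`, `mutant_length`.
#' @examples
#' ins_panel_profile()
#' @export
ins_panel_profile <- function() {
  tx <- toy_transcripts()[["INS"]]
  panel <- ins_variant_panel()
  ann <- annotate_variants(panel, list(INS = tx))
  profs <- purrr::map(ann$mutant_protein, cysteine_inventory)
  tibble(
    name = panel$name,
    hgvs_p = ann$hgvs_p,
    nmd_class = ann$nmd_class,
    pattern = purrr::map_chr(profs, ~ .x$pattern[[1]]),
    unpaired_b_cys = purrr::map_int(profs, ~ .x$unpaired_b_cys[[1]]),
    novel_cys_n = purrr::map_int(profs, ~ length(.x$novel_cys[[1]])),
    mutant_length = nchar(ann$mutant_protein))
}
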