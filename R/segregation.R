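# Co-segregation LOD scoring under a dominant, (near-)fully-penetrant model.
#
# The simplified meiosis-counting formulation: each genotyped non-proband
# relative with known affection status contributes one informative meiosis.
# Under linkage the phenotype probability given genotype is
#   affected   | carrier     -> penetrance f
#   unaffected | carrier     -> 1 - f
#   unaffected | non-carrier -> 1
#   affected   | non-carrier -> phenocopy rate (default 0)
# whereas under independent transmission each genotype has probability 1/2.
# LOD = log10(prod(contributions) / 0.5^n), summed over families. With full
# penetrance and no discordance this reduces to n * log10(2) (10 concordant
# meioses ~ LOD 3.01, the classical strong-linkage threshold). Probands are
# excluded from the count (ascertainment).

#' Read a pedigree file (PED + genotype column)
#'
#' Expects the six standard PED columns (family, id, father, mother, sex,
#' affection with 1 = unaffected, 2 = affected, 0 = unknown) plus a seventh
#' genotype column coded `carrier` / `non_carrier` / `untested` (or the Fig.-3
#' style shorthand `N/M` -> carrier, `N/N` -> non-carrier, `.` -> untested).
#' An optional eighth column flags the proband (1/0); when absent the first
#' affected genotyped individual per family is taken as proband.
#'
#' @param path Path to a whitespace-delimited PED file without header.
#' @return A pedigree tibble: `family`, `id`, `father`, `mother`, `sex`,
#'   `affected` (`"yes"`, `"no"`, `"unknown"`), `genotype`, `proband`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 7) abort("PED file needs 6 standard columns + genotype")
  names(raw)[1:7] <- c("family", "id", "father", "mother", "sex", "aff",
                       "geno")
  ped <- tibble(
    family = raw$family, id = raw$id,
    father = if_else(raw$father %in% c("0", "."), NA_character_, raw$father),
    mother = if_else(raw$mother %in% c("0", "."), NA_character_, raw$mother),
    sex = raw$sex,
    affected = dplyr::case_match(raw$aff, "2" ~ "yes", "1" ~ "no",
                                 .default = "unknown"),
    genotype = dplyr::case_match(raw$geno,
      c("carrier", "N/M", "M/N") ~ "carrier",
      c("non_carrier", "N/N") ~ "non_carrier", .default = "untested"))
  if (ncol(raw) >= 8) {
    ped$proband <- raw[[8]] == "1"
  } else {
    ped <- ped |>
      group_by(.data$family) |>
      mutate(proband = seq_len(n()) ==
               which(.data$affected == "yes" & .data$genotype != "untested")[1]) |>
      ungroup()
    ped$proband[is.na(ped$proband)] <- FALSE
  }
  validate_pedigree(ped)
  ped
}

#' @keywords internal
validate_pedigree <- function(ped) {
  bad <- setdiff(stats::na.omit(c(ped$father, ped$mother)), ped$id)
  if (length(bad)) {
    abort(paste0("parent id(s) not present in pedigree: ",
                 paste(bad, collapse = ", ")))
  }
  pr <- filter(ped, .data$proband)
  if (any(pr$genotype == "untested")) abort("proband must be genotyped")
  invisible(ped)
}

#' Co-segregation LOD score across families
#'
#' @param ped A pedigree tibble (see [read_pedigree()]); may contain several
#'   families.
#' @param penetrance Probability that a carrier is affected (default 1).
#' @param phenocopy Probability that a non-carrier is affected (default 0;
#'   with the default an affected non-carrier refutes co-segregation,
#'   LOD = -Inf).
#' @return A `segregation_result` tibble with one row per family
#'   (`family`, `informative_meioses`, `concordant`, `discordant`, `lod`,
#'   `refuted`) and the combined LOD in the `combined_lod` attribute
#'   (LODs are additive across families).
#' @examples
#' ped <- sim_pedigrees(meioses_per_family = c(2, 2, 2, 2, 2), seed = 1)$ped
#' lod_score(ped)
#' @export
lod_score <- function(ped, penetrance = 1.0, phenocopy = 0.0) {
  stopifnot(penetrance > 0, penetrance <= 1, phenocopy >= 0, phenocopy < 1)
  validate_pedigree(ped)
  per_fam <- ped |>
    group_by(.data$family) |>
    summarise(res = list(lod_one_family(dplyr::pick(dplyr::everything()),
                                        penetrance, phenocopy))) |>
    tidyr::unnest_wider("res")
  combined <- sum(per_fam$lod)
  structure(per_fam, combined_lod = combined,
            penetrance = penetrance, phenocopy = phenocopy,
            class = c("segregation_result", class(per_fam)))
}

#' @keywords internal
lod_one_family <- function(fam, penetrance, phenocopy) {
  inf <- filter(fam, !.data$proband,
                .data$genotype %in% c("carrier", "non_carrier"),
                .data$affected %in% c("yes", "no"))
  n <- nrow(inf)
  if (n == 0) {
    return(list(informative_meioses = 0L, concordant = 0L, discordant = 0L,
                lod = 0, refuted = FALSE))
  }
  contrib <- purrr::map2_dbl(inf$affected, inf$genotype, function(aff, g) {
    if (g == "carrier") {
      if (aff == "yes") penetrance else 1 - penetrance
    } else {
      if (aff == "yes") phenocopy else 1
    }
  })
  concord <- sum((inf$affected == "yes") == (inf$genotype == "carrier"))
  lod <- sum(log10(contrib)) - n * log10(0.5)
  list(informative_meioses = n, concordant = as.integer(concord),
       discordant = as.integer(n - concord), lod = lod,
       refuted = is.infinite(lod) && lod < 0)
}

#' @export
print.segregation_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("combined LOD: %.3f (penetrance %.2f)\n",
              attr(x, "combined_lod"), attr(x, "penetrance")))
  invisible(x)
}

#' @export
tidy.segregation_result <- function(x, ...) as_tibble(x)

#' @export
glance.segregation_result <- function(x, ...) {
  tibble(families = nrow(x),
         informative_meioses = sum(x$informative_meioses),
         combined_lod = attr(x, "combined_lod"),
         refuted = any(x$refuted))
}

#' Flag de novo occurrence in each family
#'
#' A variant is confirmed de novo when the proband is a carrier and both
#' parents were genotyped non-carriers. An untested parent leaves the flag
#' `FALSE` with note `"unconfirmed"`.
#'
#' @param ped A pedigree tibble.
#' @return Tibble: `family`, `de_novo`, `note`.
#' @export
detect_de_novo <- function(ped) {
  ped |>
    group_by(.data$family) |>
    summarise(res = list({
      fam <- dplyr::pick(dplyr::everything())
      pr <- filter(fam, .data$proband)
      if (nrow(pr) != 1 || pr$genotype != "carrier") {
        list(de_novo = FALSE, note = "proband not a genotyped carrier")
      } else {
        par_ids <- c(pr$father, pr$mother)
        if (any(is.na(par_ids))) {
          list(de_novo = FALSE, note = "parent(s) absent from pedigree")
        } else {
          pg <- fam$genotype[match(par_ids, fam$id)]
          if (any(pg == "untested")) {
            list(de_novo = FALSE, note = "unconfirmed: parent untested")
          } else if (all(pg == "non_carrier")) {
            list(de_novo = TRUE, note = "both parents non-carrier")
          } else {
            list(de_novo = FALSE, note = "inherited: a parent carries the variant")
          }
        }
      }
    })) |>
    tidyr::unnest_wider("res")
}
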