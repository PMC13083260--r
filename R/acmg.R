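#' Functional-domain map of the U2-2 snRNA for PM1 scoring
#'
#' Nucleotide ranges (inclusive, snRNA numbering) of the functional domains
#' used to grade the PM1 "mutational hotspot / functional domain" evidence:
#' the U2/U6 helix II, stem-loop I and branch-site-interacting stem-loop
#' region and the Sm protein-binding site carry full PM1; the peripheral
#' stem-loops carry PM1 at supporting strength.
#'
#' @return data frame with columns `name`, `start_n`, `end_n`, `tier`.
#' @export
u2_domain_map <- function() {
  data.frame(
    name = c("U2/U6 helix II + SLI + BSL", "Sm site",
             "SLIIa", "SLIIb", "SLIII", "SLIV"),
    start_n = c(1L, 98L, 47L, 68L, 112L, 147L),
    end_n   = c(45L, 107L, 66L, 84L, 144L, 184L),
    tier = c("PM1", "PM1", "PM1_Supporting", "PM1_Supporting",
             "PM1_Supporting", "PM1_Supporting"),
    stringsAsFactors = FALSE
  )
}

#' Read a domain map from a YAML file
#'
#' Expects a top-level `domains:` list whose entries carry `name`, `start`,
#' `end` and `tier`; allows the map to be versioned per gene on disk.
#'
#' @param path YAML file path.
#' @return data frame in the [u2_domain_map()] layout.
#' @export
read_domain_map <- function(path) {
  y <- yaml::read_yaml(path)
  d <- y$domains
  if (is.null(d)) stop("no 'domains' entry in ", path)
  out <- do.call(rbind, lapply(d, function(e) {
    data.frame(name = e$name, start_n = as.integer(e$start),
               end_n = as.integer(e$end), tier = e$tier,
               stringsAsFactors = FALSE)
  }))
  .validate_domain_map(out)
  out
}

.validate_domain_map <- function(map) {
  stopifnot(all(map$start_n >= 1), all(map$end_n >= map$start_n))
  o <- order(map$start_n)
  s <- map$start_n[o]; e <- map$end_n[o]
  if (any(s[-1] <= e[-length(e)])) stop("domain ranges overlap")
  invisible(map)
}

#' Map an snRNA nucleotide position to a domain and PM1 tier
#'
#' @param n_position position in snRNA numbering: an integer or a string
#'   such as `"100"`, `"n.100"` or `"n.191+30"`. Positions with a
#'   downstream offset (`+k`) lie beyond the mature snRNA and map to no
#'   domain.
#' @param map domain map, default [u2_domain_map()].
#' @return list with `domain` and `tier` (both `NA_character_` when the
#'   position falls outside every range).
#' @export
map_position <- function(n_position, map = u2_domain_map()) {
  if (is.numeric(n_position)) {
    pos <- as.integer(n_position)
    offset <- 0L
  } else {
    s <- sub("^n\\.", "", trimws(as.character(n_position)))
    m <- regmatches(s, regexec("^(\\d+)(\\+(\\d+))?$", s))[[1]]
    if (length(m) == 0)
      stop("cannot parse snRNA position: '", n_position, "'")
    pos <- as.integer(m[2])
    offset <- if (m[4] == "") 0L else as.integer(m[4])
  }
  if (offset > 0)
    return(list(domain = NA_character_, tier = NA_character_))
  hit <- which(map$start_n <= pos & pos <= map$end_n)
  if (length(hit) == 0)
    return(list(domain = NA_character_, tier = NA_character_))
  list(domain = map$name[hit[1]], tier = map$tier[hit[1]])
}

#' PS2: de novo occurrence, downgraded for hypermutable snRNA genes
#'
#' snRNA genes are hypermutable, so a single de novo observation is weak
#' evidence; strength scales with the number of unrelated patients carrying
#' the same de novo variant.
#'
#' @param denovo_recurrence number of patients with the same de novo variant.
#' @return evidence code (`"PS2_Supporting"`, `"PS2_Moderate"`, `"PS2"`) or
#'   `NULL` when 0.
#' @export
score_ps2 <- function(denovo_recurrence) {
  stopifnot(denovo_recurrence >= 0)
  if (denovo_recurrence == 0) return(NULL)
  if (denovo_recurrence == 1) return("PS2_Supporting")
  if (denovo_recurrence <= 10) return("PS2_Moderate")
  "PS2"
}

#' PM2: absent or very rare in population databases
#'
#' @param gnomad_ac,aou_ac allele counts in gnomAD v3 and All of Us.
#' @return `"PM2_Supporting"` iff `gnomad_ac < 10` and `aou_ac < 50`,
#'   else `NULL`.
#' @export
score_pm2 <- function(gnomad_ac, aou_ac) {
  stopifnot(gnomad_ac >= 0, aou_ac >= 0)
  if (gnomad_ac < 10 && aou_ac < 50) "PM2_Supporting" else NULL
}

#' PS4: case recurrence, graded by population frequency band
#'
#' For rare variants (the PM2 band: gnomAD AC < 10 and AoU AC < 50) the
#' case-count tiers are 2 / 3-4 / >=5 for supporting / moderate / strong.
#' For intermediate-frequency variants (gnomAD AC 11-50 or AoU AC 51-250)
#' each tier is downgraded one step; more frequent variants score nothing.
#' When the two databases disagree the less favourable band applies.
#'
#' @param unrelated_case_count number of unrelated patients with the variant.
#' @param gnomad_ac,aou_ac allele counts.
#' @return evidence code or `NULL`.
#' @export
score_ps4 <- function(unrelated_case_count, gnomad_ac, aou_ac) {
  stopifnot(unrelated_case_count >= 0, gnomad_ac >= 0, aou_ac >= 0)
  rare <- gnomad_ac < 10 && aou_ac < 50
  too_frequent <- gnomad_ac > 50 || aou_ac > 250
  if (too_frequent) return(NULL)
  k <- unrelated_case_count
  if (rare) {
    if (k >= 5) return("PS4")
    if (k >= 3) return("PS4_Moderate")
    if (k == 2) return("PS4_Supporting")
    return(NULL)
  }
  # intermediate band
  if (k >= 5) return("PS4_Moderate")
  if (k >= 3) return("PS4_Supporting")
  NULL
}

#' PP1: cosegregation with disease in families
#'
#' @param coseg_affected affected family members in whom the variant
#'   cosegregates with disease.
#' @param coseg_total total family members (affected or unaffected) with
#'   informative segregation.
#' @param coseg_families number of unrelated families with cosegregation.
#' @return `"PP1_Moderate"` when segregation spans at least five members or
#'   at least two families (given any cosegregation evidence), `"PP1"` for
#'   cosegregation in two or more affected members, else `NULL`.
#' @export
score_pp1 <- function(coseg_affected, coseg_total, coseg_families) {
  stopifnot(coseg_affected >= 0, coseg_total >= 0, coseg_families >= 0)
  if (coseg_affected < 2) return(NULL)
  if (coseg_total >= 5 || coseg_families >= 2) return("PP1_Moderate")
  "PP1"
}

#' PM3: in trans with a likely pathogenic or pathogenic variant
#'
#' @param in_trans_with_lp_or_p logical; `NA` (phase unknown) scores
#'   nothing, with a warning.
#' @return `"PM3"` or `NULL`.
#' @export
score_pm3 <- function(in_trans_with_lp_or_p) {
  if (is.na(in_trans_with_lp_or_p)) {
    warning("phase unknown; PM3 not applied")
    return(NULL)
  }
  if (isTRUE(in_trans_with_lp_or_p)) "PM3" else NULL
}

.acmg_strengths <- c(
  PS2 = "Strong", PS2_Moderate = "Moderate", PS2_Supporting = "Supporting",
  PS4 = "Strong", PS4_Moderate = "Moderate", PS4_Supporting = "Supporting",
  PM1 = "Moderate", PM1_Supporting = "Supporting",
  PM2_Supporting = "Supporting", PM3 = "Moderate",
  PP1 = "Supporting", PP1_Moderate = "Moderate"
)

#' Strength of an ACMG evidence code
#' @param code evidence code, e.g. `"PS4_Moderate"`.
#' @return `"Supporting"`, `"Moderate"` or `"Strong"`.
#' @export
evidence_strength <- function(code) {
  s <- .acmg_strengths[code]
  if (anyNA(s)) stop("unknown evidence code: ",
                     paste(code[is.na(s)], collapse = ", "))
  unname(s)
}

#' Combine pathogenic-side ACMG evidence into a classification
#'
#' Standard ACMG/AMP combining rules restricted to the pathogenic side
#' (no benign codes are scored by this engine, so the floor is VUS):
#' Pathogenic for >= 2 Strong; 1 Strong with >= 3 Moderate, or 2 Moderate
#' plus >= 2 Supporting, or 1 Moderate plus >= 4 Supporting. Likely
#' pathogenic for 1 Strong with 1-2 Moderate or >= 2 Supporting;
#' >= 3 Moderate; 2 Moderate plus >= 2 Supporting; 1 Moderate plus >= 4
#' Supporting. Anything weaker is VUS.
#'
#' @param evidence character vector of evidence codes.
#' @return `"Pathogenic"`, `"Likely pathogenic"` or `"VUS"`.
#' @export
combine_acmg <- function(evidence) {
  if (length(evidence) == 0) return("VUS")
  s <- evidence_strength(evidence)
  S <- sum(s == "Strong"); M <- sum(s == "Moderate"); P <- sum(s == "Supporting")
  if (S >= 2 ||
      (S == 1 && (M >= 3 || (M == 2 && P >= 2) || (M == 1 && P >= 4))))
    return("Pathogenic")
  if ((S == 1 && (M >= 1 || P >= 2)) ||
      M >= 3 || (M == 2 && P >= 2) || (M == 1 && P >= 4))
    return("Likely pathogenic")
  "VUS"
}

#' Score and classify one variant dossier
#'
#' Gathers every applicable evidence code from the dossier fields — de novo
#' recurrence (PS2 tiers), unrelated case count against frequency bands
#' (PS4 tiers), population rarity (PM2_Supporting), functional-domain
#' position (PM1 tiers), cosegregation (PP1 tiers) and trans configuration
#' with a pathogenic allele (PM3) — then combines them with
#' [combine_acmg()]. Missing fields are treated as zero/false with a
#' warning.
#'
#' @param dossier a list or one-row data frame with fields `n_position`,
#'   `denovo_recurrence`, `unrelated_case_count`, `gnomad_ac`, `aou_ac`,
#'   `coseg_affected_members`, `coseg_total_members`, `coseg_families`,
#'   `in_trans_with_lp_or_p`.
#' @param map domain map, default [u2_domain_map()].
#' @return list with `evidence` (character vector), `classification`, and
#'   `domain` (the containing functional domain or NA).
#' @export
classify_variant <- function(dossier, map = u2_domain_map()) {
  d <- as.list(dossier)
  need0 <- c("denovo_recurrence", "unrelated_case_count", "gnomad_ac",
             "aou_ac", "coseg_affected_members", "coseg_total_members",
             "coseg_families")
  for (f in need0) {
    if (is.null(d[[f]]) || is.na(d[[f]])) {
      warning("dossier field '", f, "' missing; treated as 0")
      d[[f]] <- 0
    }
  }
  if (is.null(d$in_trans_with_lp_or_p)) d$in_trans_with_lp_or_p <- FALSE

  ev <- character()
  ev <- c(ev, score_ps2(d$denovo_recurrence))
  ev <- c(ev, score_ps4(d$unrelated_case_count, d$gnomad_ac, d$aou_ac))
  ev <- c(ev, score_pm2(d$gnomad_ac, d$aou_ac))
  dom <- list(domain = NA_character_, tier = NA_character_)
  if (!is.null(d$n_position) && !is.na(d$n_position)) {
    dom <- map_position(d$n_position, map)
    if (!is.na(dom$tier)) ev <- c(ev, dom$tier)
  }
  ev <- c(ev, score_pp1(d$coseg_affected_members, d$coseg_total_members,
                        d$coseg_families))
  if (!is.na(d$in_trans_with_lp_or_p) && isTRUE(d$in_trans_with_lp_or_p))
    ev <- c(ev, "PM3")
  list(evidence = ev, classification = combine_acmg(ev), domain = dom$domain)
}

#' Classify a table of variant dossiers
#'
#' @param dossiers data frame, one row per variant, with the fields of
#'   [classify_variant()] plus an id column (first column is used).
#' @param map domain map.
#' @return input with added `evidence` (comma-separated codes),
#'   `classification` and `domain` columns.
#' @export
classify_dossiers <- function(dossiers, map = u2_domain_map()) {
  res <- lapply(seq_len(nrow(dossiers)), function(i)
    classify_variant(dossiers[i, , drop = FALSE], map))
  dossiers$evidence <- vapply(res, function(r) paste(r$evidence, collapse = ","), "")
  dossiers$classification <- vapply(res, `[[`, "", "classification")
  dossiers$domain <- vapply(res, `[[`, "", "domain")
  dossiers
}
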