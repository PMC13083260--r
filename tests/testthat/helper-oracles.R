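# Independent brute-force oracles. These deliberately share no code with
# the package: enumeration and per-base loops here, interval trees and
# network algorithms there.

# Exact two-sided Fisher p for a 2 x k table by complete enumeration of
# all tables with the observed margins, summing the probability of every
# table at most as probable as the observed one.
fisher_enum_2xk <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  k <- ncol(tab)
  logprob <- function(a) {
    # a: first-row cells; probability of the table under fixed margins
    sum(lchoose(cs, a)) - lchoose(sum(cs), r1)
  }
  p_obs <- logprob(tab[1, ])
  total <- 0
  rec <- function(j, left, acc) {
    if (j == k) {
      if (left >= 0 && left <= cs[k]) {
        lp <- logprob(c(acc, left))
        if (lp <= p_obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (a in 0:min(cs[j], left)) rec(j + 1, left - a, c(acc, a))
  }
  rec(1, r1, integer())
  min(total, 1)
}

# Quadratic all-pairs interval overlap (0-based half-open).
naive_overlap <- function(genes, track) {
  sapply(seq_len(nrow(genes)), function(i) {
    any(track$chrom == genes$chrom[i] &
          track$start < genes$end[i] & track$end > genes$start[i])
  })
}

# Per-base loop over the gene body against one track's runs.
naive_summarize <- function(gene, track_data) {
  mx <- 0; covered <- 0L
  for (b in seq(gene$start, gene$end - 1L)) {
    hit <- which(track_data$chrom == gene$chrom &
                   track_data$start <= b & b < track_data$end)
    if (length(hit) > 0) {
      v <- track_data$score[hit[1]]
      if (v > 0) covered <- covered + 1L
      mx <- max(mx, v)
    }
  }
  list(max_signal = mx, covered_bases = covered)
}

# Literal transcription of the de novo rule and the four biallelic rules,
# enumerating every variant and variant pair per affected proband. The
# genotype table is pivoted to wide lookups, unlike the caller.
brute_force_events <- function(geno, ped, min_depth = 10) {
  gt_of <- function(sid, vid) {
    r <- geno[geno$sample_id == sid & geno$variant_id == vid, , drop = FALSE]
    if (nrow(r) == 0) list(gt = "0/0", dp = Inf) else
      list(gt = r$gt[1], dp = r$dp[1])
  }
  carrier <- function(g) g$gt %in% c("0/1", "1/1") && g$dp >= min_depth
  homref <- function(g) g$gt == "0/0" && g$dp >= min_depth
  out <- list()
  emit <- function(...) out[[length(out) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  pros <- ped[ped$phenotype == 2, , drop = FALSE]
  for (r in seq_len(nrow(pros))) {
    pid <- pros$sample_id[r]
    fam <- pros$family_id[r]
    fa <- pros$father_id[r]; mo <- pros$mother_id[r]
    fa <- if (!is.na(fa) && fa != "0" && fa %in% ped$sample_id) fa else NA
    mo <- if (!is.na(mo) && mo != "0" && mo %in% ped$sample_id) mo else NA
    mine <- geno[geno$sample_id == pid & geno$gt %in% c("0/1", "1/1") &
                   geno$dp >= min_depth & !is.na(geno$gene_id), , drop = FALSE]
    for (gene in unique(mine$gene_id)) {
      vs <- mine[mine$gene_id == gene, , drop = FALSE]
      # rule (1): homozygous
      for (i in which(vs$gt == "1/1"))
        emit(family_id = fam, sample_id = pid, gene_id = gene,
             kind = "biallelic", rule = "homozygous_or_hemizygous",
             variant1 = vs$variant_id[i], variant2 = NA_character_)
      hets <- vs$variant_id[vs$gt == "0/1"]
      orig <- sapply(hets, function(v) {
        if (is.na(fa) || is.na(mo)) {
          # duo: status relative to the single sequenced parent
          par <- if (!is.na(fa)) fa else mo
          if (is.na(par)) return("nothing")
          g <- gt_of(par, v)
          if (carrier(g)) return("inherited")
          if (homref(g) && is.finite(g$dp)) return("absent")
          return("nothing")
        }
        gf <- gt_of(fa, v); gm <- gt_of(mo, v)
        if (homref(gf) && homref(gm) && is.finite(gf$dp) && is.finite(gm$dp))
          return("de_novo")
        if (carrier(gm) && homref(gf)) return("maternal")
        if (carrier(gf) && homref(gm)) return("paternal")
        "nothing"
      })
      if (!is.na(fa) && !is.na(mo)) {
        for (v in hets[orig[hets] == "de_novo"])
          emit(family_id = fam, sample_id = pid, gene_id = gene,
               kind = "de_novo", rule = "trio_absent",
               variant1 = v, variant2 = NA_character_)
      }
      if (length(hets) >= 2) {
        prs <- utils::combn(hets, 2)
        for (c_i in seq_len(ncol(prs))) {
          a <- prs[1, c_i]; b <- prs[2, c_i]
          oa <- orig[[a]]; ob <- orig[[b]]
          if (!is.na(fa) && !is.na(mo)) {
            # rule (2): inherited from different parents
            if (setequal(c(oa, ob), c("maternal", "paternal")))
              emit(family_id = fam, sample_id = pid, gene_id = gene,
                   kind = "biallelic", rule = "trio_trans",
                   variant1 = min(a, b), variant2 = max(a, b))
            # rule (4): one inherited, one de novo
            if (oa %in% c("maternal", "paternal") && ob == "de_novo")
              emit(family_id = fam, sample_id = pid, gene_id = gene,
                   kind = "biallelic", rule = "denovo_plus_inherited",
                   variant1 = a, variant2 = b)
            if (ob %in% c("maternal", "paternal") && oa == "de_novo")
              emit(family_id = fam, sample_id = pid, gene_id = gene,
                   kind = "biallelic", rule = "denovo_plus_inherited",
                   variant1 = b, variant2 = a)
          } else if (!is.na(fa) || !is.na(mo)) {
            # rule (3): one inherited, one absent from the sequenced parent
            if (oa == "inherited" && ob == "absent")
              emit(family_id = fam, sample_id = pid, gene_id = gene,
                   kind = "biallelic", rule = "duo_partial",
                   variant1 = a, variant2 = b)
            if (ob == "inherited" && oa == "absent")
              emit(family_id = fam, sample_id = pid, gene_id = gene,
                   kind = "biallelic", rule = "duo_partial",
                   variant1 = b, variant2 = a)
          }
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(family_id = character(), sample_id = character(),
                      gene_id = character(), kind = character(),
                      rule = character(), variant1 = character(),
                      variant2 = character()))
  do.call(rbind, out)
}

# Canonical form for event-set comparison: unordered rule-(2) pairs are
# sorted lexicographically; rows sorted on all columns.
normalize_events <- function(ev) {
  ev <- ev[, c("family_id", "sample_id", "gene_id", "kind", "rule",
               "variant1", "variant2")]
  tt <- ev$rule == "trio_trans"
  if (any(tt)) {
    v1 <- pmin(ev$variant1[tt], ev$variant2[tt])
    v2 <- pmax(ev$variant1[tt], ev$variant2[tt])
    ev$variant1[tt] <- v1; ev$variant2[tt] <- v2
  }
  ev <- ev[do.call(order, ev), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
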