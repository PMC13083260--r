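#' Read a 6-column PED file
#'
#' @param path PED path (family, sample, father, mother, sex, phenotype;
#'   whitespace-separated, no header; `0` marks a missing parent).
#' @return data frame with `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected` (phenotype == 2) and a derived
#'   `structure` per offspring (`trio`, `duo_father`, `duo_mother`,
#'   `singleton`).
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("family_id", "sample_id", "father_id",
                                       "mother_id", "sex", "phenotype"))
  p$father_id[p$father_id == "0"] <- NA_character_
  p$mother_id[p$mother_id == "0"] <- NA_character_
  p$affected <- p$phenotype == 2
  present <- p$sample_id
  has_f <- !is.na(p$father_id) & p$father_id %in% present
  has_m <- !is.na(p$mother_id) & p$mother_id %in% present
  bad <- (!is.na(p$father_id) & !p$father_id %in% present) |
         (!is.na(p$mother_id) & !p$mother_id %in% present)
  if (any(bad))
    stop("parents referenced but absent from cohort: ",
         paste(p$sample_id[bad], collapse = ", "))
  p$structure <- ifelse(has_f & has_m, "trio",
                 ifelse(has_f, "duo_father",
                 ifelse(has_m, "duo_mother", "singleton")))
  p
}

#' Read genotypes from a VCF (GT, DP, AD)
#'
#' Parses a plain-text VCF v4.2 into a long genotype table. Multi-allelic
#' records are decomposed into one biallelic record per alternate allele
#' (genotype and allele depth recoded with respect to that allele).
#'
#' @param path VCF path.
#' @return data frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample_id`, `gt` (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`), `dp`,
#'   `alt_reads`, and `variant_id` (`chrom:pos:ref:alt`).
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    fmt <- strsplit(f[9], ":")[[1]]
    gt_i <- match("GT", fmt); dp_i <- match("DP", fmt); ad_i <- match("AD", fmt)
    if (is.na(gt_i)) stop("VCF record without GT field")
    alts <- strsplit(f[5], ",")[[1]]
    calls <- strsplit(f[-(1:9)], ":")
    for (ai in seq_along(alts)) {
      gt <- character(length(samples)); dp <- integer(length(samples))
      ar <- integer(length(samples))
      for (si in seq_along(samples)) {
        cc <- calls[[si]]
        g <- cc[gt_i]
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) {
          gt[si] <- "./."
        } else {
          n_alt <- sum(al == as.character(ai))
          gt[si] <- c("0/0", "0/1", "1/1")[n_alt + 1]
        }
        dp[si] <- if (!is.na(dp_i) && length(cc) >= dp_i && cc[dp_i] != ".")
          as.integer(cc[dp_i]) else NA_integer_
        ar[si] <- if (!is.na(ad_i) && length(cc) >= ad_i && cc[ad_i] != ".") {
          ad <- as.integer(strsplit(cc[ad_i], ",")[[1]])
          if (length(ad) >= ai + 1) ad[ai + 1] else NA_integer_
        } else NA_integer_
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alts[ai],
        sample_id = samples, gt = gt, dp = dp, alt_reads = ar,
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, out)
  if (is.null(g))
    g <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), sample_id = character(), gt = character(),
                    dp = integer(), alt_reads = integer())
  g$variant_id <- paste(g$chrom, g$pos, g$ref, g$alt, sep = ":")
  g
}

#' Assign variants to genes by position
#'
#' @param geno long genotype table ([read_vcf_genotypes()] layout).
#' @param genes gene data frame (0-based half-open coordinates).
#' @return `geno` with a `gene_id` column (`NA` outside all genes); a
#'   variant inside two genes is assigned to the first by table order.
#' @export
assign_genes <- function(geno, genes) {
  geno$gene_id <- NA_character_
  for (i in seq_len(nrow(genes))) {
    hit <- geno$chrom == genes$chrom[i] &
      geno$pos > genes$start[i] & geno$pos <= genes$end[i]
    geno$gene_id[hit & is.na(geno$gene_id)] <- genes$gene_id[i]
  }
  geno
}

.gt_has_alt <- function(gt) gt %in% c("0/1", "1/1")
.gt_hom_ref <- function(gt, dp, min_depth) gt == "0/0" & !is.na(dp) & dp >= min_depth

#' Call a de novo event at one site in a full trio
#'
#' The child carries the alternate allele while both parents are
#' confidently homozygous reference; all three genotypes must reach the
#' minimum depth. With a missing parent the site is not callable as de
#' novo (duo logic applies instead).
#'
#' @param child,father,mother one-row genotype records (gt, dp).
#' @param min_depth minimum read depth for every member, default 10.
#' @return `TRUE` when the site qualifies as de novo.
#' @export
call_de_novo <- function(child, father, mother, min_depth = 10) {
  if (is.null(father) || is.null(mother)) return(FALSE)
  .gt_has_alt(child$gt) && !is.na(child$dp) && child$dp >= min_depth &&
    .gt_hom_ref(father$gt, father$dp, min_depth) &&
    .gt_hom_ref(mother$gt, mother$dp, min_depth)
}

# genotype lookup helper: one row per (variant_id, sample) or NULL
.geno_of <- function(geno, vid, sid) {
  r <- geno[geno$variant_id == vid & geno$sample_id == sid, , drop = FALSE]
  if (nrow(r) == 0) NULL else r[1, , drop = FALSE]
}

#' Pedigree-aware candidate-event extraction
#'
#' For every affected proband and every gene, extracts de novo events
#' (full trios only) and biallelic events under four rules:
#' (1) homozygous (or hemizygous) genotypes; (2) in trios, two
#' heterozygous variants inherited from different parents; (3) in duos,
#' one variant inherited from the sequenced parent and one confidently
#' absent from that parent; (4) one inherited plus one de novo variant,
#' phase assumed in trans pending manual review. Two heterozygous
#' variants inherited from the same parent are in cis and yield no event.
#' All genotypes used as evidence must reach the minimum depth.
#'
#' @param geno long genotype table with `gene_id` (see [assign_genes()]).
#' @param ped pedigree from [read_ped()].
#' @param min_depth minimum depth, default 10.
#' @param cnv optional data frame of carrier deletions (`sample_id`,
#'   `chrom`, `start`, `end`) granting hemizygosity when a deletion covers
#'   the gene; heterozygous variants under such deletions become rule-(1)
#'   events.
#' @param genes gene table (needed only when `cnv` is supplied).
#' @return data frame of candidate events: `family_id`, `sample_id`,
#'   `gene_id`, `kind`, `rule`, `variant1`, `variant2`, `phase`,
#'   `origin1`, `origin2`.
#' @export
call_candidate_events <- function(geno, ped, min_depth = 10, cnv = NULL,
                                  genes = NULL) {
  if (is.null(geno$gene_id)) stop("genotypes lack gene_id; run assign_genes()")
  probands <- ped[ped$affected & ped$structure != "parent_only", , drop = FALSE]
  ev <- list()
  add <- function(fam, sid, gene, kind, rule, v1, v2 = NA_character_,
                  phase = "unknown", o1 = "unknown", o2 = NA_character_) {
    ev[[length(ev) + 1]] <<- data.frame(
      family_id = fam, sample_id = sid, gene_id = gene, kind = kind,
      rule = rule, variant1 = v1, variant2 = v2, phase = phase,
      origin1 = o1, origin2 = o2, stringsAsFactors = FALSE)
  }

  for (pi in seq_len(nrow(probands))) {
    pr <- probands[pi, ]
    pg <- geno[geno$sample_id == pr$sample_id & !is.na(geno$gene_id) &
                 .gt_has_alt(geno$gt), , drop = FALSE]
    pg <- pg[!is.na(pg$dp) & pg$dp >= min_depth, , drop = FALSE]
    if (nrow(pg) == 0) next

    for (gene in unique(pg$gene_id)) {
      gg <- pg[pg$gene_id == gene, , drop = FALSE]
      hemi <- .gene_hemizygous(cnv, genes, gene, pr$sample_id)

      # rule (1): homozygous / hemizygous
      hom <- gg$gt == "1/1" | (hemi & gg$gt == "0/1")
      for (i in which(hom)) {
        org <- .inherited_origin(geno, gg$variant_id[i], pr, min_depth)
        add(pr$family_id, pr$sample_id, gene, "biallelic",
            "homozygous_or_hemizygous", gg$variant_id[i],
            phase = "trans_confirmed", o1 = org)
      }

      hets <- gg[gg$gt == "0/1" & !hom, , drop = FALSE]
      if (pr$structure == "trio") {
        stat <- vapply(hets$variant_id, function(v)
          .trio_variant_status(geno, v, pr, min_depth), "")
        # de novo single-variant events
        for (i in which(stat == "de_novo"))
          add(pr$family_id, pr$sample_id, gene, "de_novo", "trio_absent",
              hets$variant_id[i])
        # biallelic pairs: rules (2) and (4)
        if (nrow(hets) >= 2) {
          for (i in seq_len(nrow(hets) - 1)) for (j in (i + 1):nrow(hets)) {
            si <- stat[i]; sj <- stat[j]
            if ((si == "maternal" && sj == "paternal") ||
                (si == "paternal" && sj == "maternal")) {
              add(pr$family_id, pr$sample_id, gene, "biallelic", "trio_trans",
                  hets$variant_id[i], hets$variant_id[j],
                  phase = "trans_confirmed", o1 = si, o2 = sj)
            } else if (si %in% c("maternal", "paternal") && sj == "de_novo") {
              add(pr$family_id, pr$sample_id, gene, "biallelic",
                  "denovo_plus_inherited", hets$variant_id[i],
                  hets$variant_id[j], phase = "trans_assumed",
                  o1 = si, o2 = "unknown")
            } else if (sj %in% c("maternal", "paternal") && si == "de_novo") {
              add(pr$family_id, pr$sample_id, gene, "biallelic",
                  "denovo_plus_inherited", hets$variant_id[j],
                  hets$variant_id[i], phase = "trans_assumed",
                  o1 = sj, o2 = "unknown")
            }
          }
        }
      } else if (pr$structure %in% c("duo_father", "duo_mother")) {
        par_id <- if (pr$structure == "duo_father") pr$father_id else pr$mother_id
        par_lab <- if (pr$structure == "duo_father") "paternal" else "maternal"
        stat <- vapply(hets$variant_id, function(v) {
          pgt <- .geno_of(geno, v, par_id)
          if (is.null(pgt)) return("unknown")
          if (.gt_has_alt(pgt$gt) && !is.na(pgt$dp) && pgt$dp >= min_depth)
            return("inherited")
          if (.gt_hom_ref(pgt$gt, pgt$dp, min_depth)) return("absent")
          "unknown"
        }, "")
        if (nrow(hets) >= 2) {
          for (i in seq_len(nrow(hets) - 1)) for (j in (i + 1):nrow(hets)) {
            if (stat[i] == "inherited" && stat[j] == "absent") {
              add(pr$family_id, pr$sample_id, gene, "biallelic", "duo_partial",
                  hets$variant_id[i], hets$variant_id[j],
                  o1 = par_lab, o2 = "unknown")
            } else if (stat[j] == "inherited" && stat[i] == "absent") {
              add(pr$family_id, pr$sample_id, gene, "biallelic", "duo_partial",
                  hets$variant_id[j], hets$variant_id[i],
                  o1 = par_lab, o2 = "unknown")
            }
          }
        }
      }
      # singletons: only rule (1) homozygous events are callable
    }
  }
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(family_id = character(), sample_id = character(),
                      gene_id = character(), kind = character(),
                      rule = character(), variant1 = character(),
                      variant2 = character(), phase = character(),
                      origin1 = character(), origin2 = character())
  out
}

# status of a het variant in a full trio: de_novo / maternal / paternal /
# ambiguous (both parents carry) / unknown (depth or genotype missing)
.trio_variant_status <- function(geno, vid, pr, min_depth) {
  f <- .geno_of(geno, vid, pr$father_id)
  m <- .geno_of(geno, vid, pr$mother_id)
  if (is.null(f) || is.null(m)) return("unknown")
  f_carrier <- .gt_has_alt(f$gt) && !is.na(f$dp) && f$dp >= min_depth
  m_carrier <- .gt_has_alt(m$gt) && !is.na(m$dp) && m$dp >= min_depth
  f_ref <- .gt_hom_ref(f$gt, f$dp, min_depth)
  m_ref <- .gt_hom_ref(m$gt, m$dp, min_depth)
  if (f_ref && m_ref) return("de_novo")
  if (m_carrier && f_ref) return("maternal")
  if (f_carrier && m_ref) return("paternal")
  if (f_carrier && m_carrier) return("ambiguous")
  "unknown"
}

# parental origin of an inherited (e.g. homozygous-constituent) variant
.inherited_origin <- function(geno, vid, pr, min_depth) {
  if (pr$structure != "trio") return("unknown")
  s <- .trio_variant_status(geno, vid, pr, min_depth)
  if (s %in% c("maternal", "paternal")) s else "unknown"
}

.gene_hemizygous <- function(cnv, genes, gene, sample_id) {
  if (is.null(cnv)) return(FALSE)
  if (is.null(genes)) stop("gene table required when CNV calls are supplied")
  gi <- genes[genes$gene_id == gene, , drop = FALSE]
  if (nrow(gi) == 0) return(FALSE)
  any(cnv$sample_id == sample_id & cnv$chrom == gi$chrom &
        cnv$start <= gi$start & cnv$end >= gi$end)
}

#' Gene-level QC: cohort median VAF and problematic-region overlap
#'
#' A gene passes QC when the median variant allele fraction over
#' heterozygous carrier calls (depth > 0) is at least `min_median_vaf`
#' (a mappability proxy: systematic mapping artefacts drag carrier VAFs
#' below the heterozygous expectation) and when less than
#' `max_problematic_overlap` of the gene body overlaps problematic
#' regions.
#'
#' @param gene one-row gene data frame.
#' @param carrier_calls genotype rows for heterozygous carriers in the gene.
#' @param problematic interval data frame (0-based half-open) or `NULL`.
#' @param min_median_vaf default 0.3.
#' @param max_problematic_overlap default 0.5 (strict: fraction must be
#'   strictly below).
#' @return list with `qc_pass`, `median_vaf`, `problematic_fraction`,
#'   `reasons` (character vector, empty on pass).
#' @export
gene_qc <- function(gene, carrier_calls, problematic = NULL,
                    min_median_vaf = 0.3, max_problematic_overlap = 0.5) {
  hets <- carrier_calls[carrier_calls$gt == "0/1", , drop = FALSE]
  hets <- hets[!is.na(hets$dp) & hets$dp > 0, , drop = FALSE]
  reasons <- character()
  if (nrow(hets) == 0) {
    med <- NA_real_
    reasons <- c(reasons, "no heterozygous carrier call with depth > 0")
  } else {
    med <- stats::median(hets$alt_reads / hets$dp)
    if (med < min_median_vaf)
      reasons <- c(reasons, sprintf("median VAF %.3f < %.2f", med, min_median_vaf))
  }
  frac <- 0
  if (!is.null(problematic) && nrow(problematic) > 0) {
    p <- problematic[problematic$chrom == gene$chrom, , drop = FALSE]
    if (nrow(p) > 0) {
      gr <- IRanges::IRanges(gene$start + 1L, gene$end)
      pr <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
      ov <- IRanges::intersect(IRanges::reduce(gr), pr)
      frac <- sum(IRanges::width(ov)) / (gene$end - gene$start)
    }
  }
  if (frac >= max_problematic_overlap)
    reasons <- c(reasons,
                 sprintf("problematic-region overlap %.2f >= %.2f",
                         frac, max_problematic_overlap))
  list(qc_pass = length(reasons) == 0, median_vaf = med,
       problematic_fraction = frac, reasons = reasons)
}

#' Population-frequency filter profiles
#'
#' Three nested profiles with strict-inequality semantics as printed:
#' `initial` requires fewer than 3 gnomAD homozygotes and fewer than 5
#' internal-database homozygotes; `rare` additionally requires gnomAD
#' AC < 100 and no gnomAD flag; `rnu2_refined` keeps the homozygote caps,
#' drops the gnomAD AC cap, and requires AoU AC < 50 (de novo) or < 200
#' (biallelic) with zero AoU homozygotes.
#'
#' @param freq one-row frequency record: `gnomad_ac`, `gnomad_nhomalt`,
#'   `internal_nhomalt`, `aou_ac`, `aou_nhomalt`, `gnomad_flagged`.
#' @param kind `"de_novo"` or `"biallelic"`.
#' @param profile `"initial"`, `"rare"` or `"rnu2_refined"`.
#' @return list with `pass` and `reasons` (every violated threshold).
#' @export
frequency_filter <- function(freq, kind = c("de_novo", "biallelic"),
                             profile = c("initial", "rare", "rnu2_refined")) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  f <- as.list(freq)
  reasons <- character()
  if (!(f$gnomad_nhomalt < 3))
    reasons <- c(reasons, "gnomad_nhomalt >= 3")
  if (!(f$internal_nhomalt < 5))
    reasons <- c(reasons, "internal_nhomalt >= 5")
  if (profile == "rare") {
    if (!(f$gnomad_ac < 100)) reasons <- c(reasons, "gnomad_ac >= 100")
    if (isTRUE(as.logical(f$gnomad_flagged)))
      reasons <- c(reasons, "gnomad_flagged")
  }
  if (profile == "rnu2_refined") {
    cap <- if (kind == "de_novo") 50 else 200
    if (!(f$aou_ac < cap))
      reasons <- c(reasons, sprintf("aou_ac >= %d", cap))
    if (!(f$aou_nhomalt == 0))
      reasons <- c(reasons, "aou_nhomalt > 0")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Apply a frequency profile to candidate events
#'
#' A biallelic event passes only if every constituent variant passes.
#'
#' @param events candidate-event data frame.
#' @param freq frequency table keyed by `variant_id`.
#' @param profile profile name, see [frequency_filter()].
#' @return the passing subset of `events`.
#' @export
apply_frequency_filter <- function(events, freq,
                                   profile = c("initial", "rare", "rnu2_refined")) {
  profile <- match.arg(profile)
  if (nrow(events) == 0) return(events)
  pass_one <- function(vid, kind) {
    if (is.na(vid)) return(TRUE)
    fr <- freq[freq$variant_id == vid, , drop = FALSE]
    if (nrow(fr) == 0) stop("no frequency record for variant ", vid)
    frequency_filter(fr[1, ], kind, profile)$pass
  }
  keep <- vapply(seq_len(nrow(events)), function(i) {
    k <- events$kind[i]
    pass_one(events$variant1[i], k) && pass_one(events$variant2[i], k)
  }, logical(1))
  events[keep, , drop = FALSE]
}

#' Set parental origin on event variants from trio genotypes
#'
#' Inherited variants take the carrying parent as origin; variants carried
#' by both parents stay unknown. De novo variants stay unknown unless a
#' read-backed phase annotation (`variant_id`, `sample_id`, `origin`) is
#' supplied.
#'
#' @param events candidate-event data frame.
#' @param geno long genotype table.
#' @param ped pedigree.
#' @param phase_annotation optional data frame of externally determined
#'   origins.
#' @param min_depth minimum depth for parental evidence.
#' @return `events` with `origin1`/`origin2` updated.
#' @export
phase_parental_origin <- function(events, geno, ped, phase_annotation = NULL,
                                  min_depth = 10) {
  look_ext <- function(vid, sid) {
    if (is.null(phase_annotation)) return(NA_character_)
    r <- phase_annotation[phase_annotation$variant_id == vid &
                            phase_annotation$sample_id == sid, , drop = FALSE]
    if (nrow(r) == 0) NA_character_ else r$origin[1]
  }
  for (i in seq_len(nrow(events))) {
    pr <- ped[ped$sample_id == events$sample_id[i], , drop = FALSE][1, ]
    for (slot in c(1, 2)) {
      vcol <- paste0("variant", slot); ocol <- paste0("origin", slot)
      vid <- events[[vcol]][i]
      if (is.na(vid)) next
      ext <- look_ext(vid, events$sample_id[i])
      if (!is.na(ext)) { events[[ocol]][i] <- ext; next }
      if (events[[ocol]][i] %in% c("maternal", "paternal")) next
      if (pr$structure == "trio") {
        s <- .trio_variant_status(geno, vid, pr, min_depth)
        if (s %in% c("maternal", "paternal")) events[[ocol]][i] <- s
      }
    }
  }
  events
}

#' End-to-end cohort screen
#'
#' Parses cohort files, assigns variants to genes, extracts candidate
#' events, applies gene QC and the requested frequency profile.
#'
#' @param vcf,ped_path,freq_path file paths (VCF; PED; frequency TSV with
#'   `variant_id` plus the [frequency_filter()] columns).
#' @param genes gene data frame.
#' @param problematic optional problematic-region intervals.
#' @param profile frequency profile.
#' @param min_depth minimum depth.
#' @return list with `events` (filtered), `all_events` (pre-filter),
#'   `gene_qc` (per-gene QC table).
#' @export
screen_cohort <- function(vcf, ped_path, freq_path, genes,
                          problematic = NULL, profile = "rare",
                          min_depth = 10) {
  geno <- assign_genes(read_vcf_genotypes(vcf), genes)
  ped <- read_ped(ped_path)
  freq <- utils::read.delim(freq_path, stringsAsFactors = FALSE)
  ev <- call_candidate_events(geno, ped, min_depth = min_depth)
  qc <- lapply(unique(ev$gene_id), function(g) {
    gi <- genes[genes$gene_id == g, , drop = FALSE][1, ]
    carrier <- geno[!is.na(geno$gene_id) & geno$gene_id == g &
                      .gt_has_alt(geno$gt), , drop = FALSE]
    r <- gene_qc(gi, carrier, problematic)
    data.frame(gene_id = g, qc_pass = r$qc_pass, median_vaf = r$median_vaf,
               problematic_fraction = r$problematic_fraction,
               stringsAsFactors = FALSE)
  })
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(gene_id = character(), qc_pass = logical(),
               median_vaf = numeric(), problematic_fraction = numeric())
  ev_qc <- ev[ev$gene_id %in% qc$gene_id[qc$qc_pass], , drop = FALSE]
  list(events = apply_frequency_filter(ev_qc, freq, profile),
       all_events = ev, gene_qc = qc)
}
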