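#' Generate a synthetic rare-disease cohort with planted events
#'
#' Simulates families (trios, duos, singletons per the configured mix),
#' plants at most one candidate event per family with genotypes and read
#' depths that satisfy every caller filter, and adds benign background
#' variation (cis pairs, transmitted singles, alleles carried by both
#' parents) constructed so that it can never satisfy any of the de novo
#' or biallelic rules. The planted-event list is the ground truth the
#' caller must recover exactly.
#'
#' Planted kinds map to caller expectations as follows: `de_novo` yields
#' one de novo event; `compound_het` one trio-trans biallelic event;
#' `homozygous` one rule-(1) event; `duo_partial` one duo biallelic
#' event; `denovo_plus_inherited` one biallelic pair *and* the de novo
#' single-variant event for its de novo half (both are real findings and
#' both appear in the truth).
#'
#' @param config a [sim_config()].
#' @param genes gene catalog data frame; default from
#'   [simulate_gene_fixture()] run on the same config.
#' @param family_plan optional data frame with one row per family and
#'   columns `structure` (`trio`/`duo`/`singleton`) and `kind` (planted
#'   event kind), overriding the random structure and event mixes. A kind
#'   that cannot exist in the requested structure (e.g. a compound
#'   heterozygote in a singleton, which is unphaseable by construction)
#'   is rejected.
#' @return list with `geno` (long genotype table), `ped`, `meta`
#'   (per-proband labels), `freq` (per-variant frequency table), `genes`,
#'   and `truth` (expected candidate events).
#' @export
simulate_cohort <- function(config = sim_config(), genes = NULL,
                            family_plan = NULL) {
  set.seed(config$seed)
  if (is.null(genes)) genes <- simulate_gene_fixture(config)$genes
  n_fam <- config$n_families
  if (!is.null(family_plan)) {
    stopifnot(all(c("structure", "kind") %in% names(family_plan)))
    n_fam <- nrow(family_plan)
    needs <- list(de_novo = "trio", compound_het = "trio",
                  denovo_plus_inherited = "trio", duo_partial = "duo")
    for (i in seq_len(n_fam)) {
      k <- family_plan$kind[i]
      if (!is.null(needs[[k]]) && family_plan$structure[i] != needs[[k]])
        stop("planted event '", k, "' impossible in a ",
             family_plan$structure[i], " (family ", i, ")")
    }
    structs <- family_plan$structure
  } else {
    structs <- sample(names(config$family_structure_mix), n_fam,
                      replace = TRUE, prob = config$family_structure_mix)
  }
  geno <- list(); ped <- list(); meta <- list(); truth <- list()
  vmeta <- new.env()  # variant_id -> planted flag
  bases <- c("A", "C", "G", "T")

  add_geno <- function(fam, vid, chrom, pos, ref, alt, sid, gt) {
    dp <- sample(20:40, 1)
    ar <- switch(gt,
                 "0/0" = 0L,
                 "0/1" = as.integer(round(dp * stats::runif(1, 0.38, 0.62))),
                 "1/1" = dp)
    geno[[length(geno) + 1]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, sample_id = sid,
      gt = gt, dp = dp, alt_reads = ar, variant_id = vid,
      stringsAsFactors = FALSE)
  }

  used_pos <- new.env()
  new_variant <- function(gene, planted) {
    key <- gene$gene_id
    taken <- if (is.null(used_pos[[key]])) integer() else used_pos[[key]]
    pos <- sample(setdiff(seq(gene$start + 1L, gene$end), taken), 1)
    used_pos[[key]] <- c(taken, pos)
    ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
    vid <- paste(gene$chrom, pos, ref, alt, sep = ":")
    vmeta[[vid]] <- planted
    list(vid = vid, chrom = gene$chrom, pos = pos, ref = ref, alt = alt)
  }

  for (f in seq_len(n_fam)) {
    fam <- sprintf("FAM%04d", f)
    child <- paste0(fam, "_c")
    father <- paste0(fam, "_f"); mother <- paste0(fam, "_m")
    st <- structs[f]
    duo_parent <- if (st == "duo") sample(c("father", "mother"), 1) else NA
    members <- switch(st,
                      trio = c(child, father, mother),
                      duo = c(child, if (duo_parent == "father") father else mother),
                      singleton = child)
    ped[[f]] <- data.frame(
      family_id = fam,
      sample_id = members,
      father_id = c(if (st == "trio" || identical(duo_parent, "father")) father else "0",
                    rep("0", length(members) - 1)),
      mother_id = c(if (st == "trio" || identical(duo_parent, "mother")) mother else "0",
                    rep("0", length(members) - 1)),
      sex = sample(1:2, length(members), replace = TRUE),
      phenotype = c(2L, rep(1L, length(members) - 1)),
      stringsAsFactors = FALSE)

    if (!is.null(family_plan)) {
      kind <- family_plan$kind[f]
    } else {
      allowed <- switch(st,
                        trio = c("none", "de_novo", "compound_het", "homozygous",
                                 "denovo_plus_inherited"),
                        duo = c("none", "homozygous", "duo_partial"),
                        singleton = c("none", "homozygous"))
      w <- config$event_mix[allowed]
      kind <- sample(allowed, 1, prob = w / sum(w))
    }
    ev_gene_i <- sample(nrow(genes), 1)
    g <- genes[ev_gene_i, ]

    if (kind == "de_novo") {
      v <- new_variant(g, TRUE)
      add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, child, "0/1")
      add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, father, "0/0")
      add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, mother, "0/0")
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "de_novo", rule = "trio_absent", variant1 = v$vid,
        variant2 = NA_character_, stringsAsFactors = FALSE)
    } else if (kind == "compound_het") {
      v1 <- new_variant(g, TRUE); v2 <- new_variant(g, TRUE)
      ord <- order(c(v1$pos, v2$pos))  # caller pairs in position order
      vv <- list(v1, v2)[ord]
      add_geno(fam, vv[[1]]$vid, vv[[1]]$chrom, vv[[1]]$pos, vv[[1]]$ref, vv[[1]]$alt, child, "0/1")
      add_geno(fam, vv[[1]]$vid, vv[[1]]$chrom, vv[[1]]$pos, vv[[1]]$ref, vv[[1]]$alt, mother, "0/1")
      add_geno(fam, vv[[1]]$vid, vv[[1]]$chrom, vv[[1]]$pos, vv[[1]]$ref, vv[[1]]$alt, father, "0/0")
      add_geno(fam, vv[[2]]$vid, vv[[2]]$chrom, vv[[2]]$pos, vv[[2]]$ref, vv[[2]]$alt, child, "0/1")
      add_geno(fam, vv[[2]]$vid, vv[[2]]$chrom, vv[[2]]$pos, vv[[2]]$ref, vv[[2]]$alt, father, "0/1")
      add_geno(fam, vv[[2]]$vid, vv[[2]]$chrom, vv[[2]]$pos, vv[[2]]$ref, vv[[2]]$alt, mother, "0/0")
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "biallelic", rule = "trio_trans", variant1 = vv[[1]]$vid,
        variant2 = vv[[2]]$vid, stringsAsFactors = FALSE)
    } else if (kind == "homozygous") {
      v <- new_variant(g, TRUE)
      add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, child, "1/1")
      if (st == "trio") {
        add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, father, "0/1")
        add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, mother, "0/1")
      } else if (st == "duo") {
        par <- if (duo_parent == "father") father else mother
        add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, par, "0/1")
      }
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "biallelic", rule = "homozygous_or_hemizygous",
        variant1 = v$vid, variant2 = NA_character_, stringsAsFactors = FALSE)
    } else if (kind == "duo_partial") {
      par <- if (duo_parent == "father") father else mother
      v1 <- new_variant(g, TRUE); v2 <- new_variant(g, TRUE)
      # v1 inherited from the sequenced parent, v2 absent from it
      add_geno(fam, v1$vid, v1$chrom, v1$pos, v1$ref, v1$alt, child, "0/1")
      add_geno(fam, v1$vid, v1$chrom, v1$pos, v1$ref, v1$alt, par, "0/1")
      add_geno(fam, v2$vid, v2$chrom, v2$pos, v2$ref, v2$alt, child, "0/1")
      add_geno(fam, v2$vid, v2$chrom, v2$pos, v2$ref, v2$alt, par, "0/0")
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "biallelic", rule = "duo_partial", variant1 = v1$vid,
        variant2 = v2$vid, stringsAsFactors = FALSE)
    } else if (kind == "denovo_plus_inherited") {
      v1 <- new_variant(g, TRUE); v2 <- new_variant(g, TRUE)
      carrier <- sample(c(father, mother), 1)
      other <- setdiff(c(father, mother), carrier)
      # v1 inherited, v2 de novo
      add_geno(fam, v1$vid, v1$chrom, v1$pos, v1$ref, v1$alt, child, "0/1")
      add_geno(fam, v1$vid, v1$chrom, v1$pos, v1$ref, v1$alt, carrier, "0/1")
      add_geno(fam, v1$vid, v1$chrom, v1$pos, v1$ref, v1$alt, other, "0/0")
      add_geno(fam, v2$vid, v2$chrom, v2$pos, v2$ref, v2$alt, child, "0/1")
      add_geno(fam, v2$vid, v2$chrom, v2$pos, v2$ref, v2$alt, father, "0/0")
      add_geno(fam, v2$vid, v2$chrom, v2$pos, v2$ref, v2$alt, mother, "0/0")
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "de_novo", rule = "trio_absent", variant1 = v2$vid,
        variant2 = NA_character_, stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        family_id = fam, sample_id = child, gene_id = g$gene_id,
        kind = "biallelic", rule = "denovo_plus_inherited",
        variant1 = v1$vid, variant2 = v2$vid, stringsAsFactors = FALSE)
    }

    # background variation in a different gene: never event-forming
    if (stats::runif(1) < config$background_rate) {
      bg_pool <- setdiff(seq_len(nrow(genes)), ev_gene_i)
      if (length(bg_pool) > 0) {
        bg <- genes[if (length(bg_pool) == 1) bg_pool else sample(bg_pool, 1), ]
        mode <- sample(c("cis_pair", "transmitted_single", "common"), 1)
        if (mode == "cis_pair" && st == "trio") {
          par <- sample(c(father, mother), 1)
          oth <- setdiff(c(father, mother), par)
          for (k in 1:2) {
            v <- new_variant(bg, FALSE)
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, child, "0/1")
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, par, "0/1")
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, oth, "0/0")
          }
        } else if (mode == "common" && st == "trio") {
          v <- new_variant(bg, FALSE)
          add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, child, "0/1")
          add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, father, "0/1")
          add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, mother, "0/1")
        } else {
          # one transmitted (or, for singletons, lone) heterozygous variant
          v <- new_variant(bg, FALSE)
          add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, child, "0/1")
          if (st == "trio") {
            par <- sample(c(father, mother), 1)
            oth <- setdiff(c(father, mother), par)
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, par, "0/1")
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, oth, "0/0")
          } else if (st == "duo") {
            par <- if (duo_parent == "father") father else mother
            add_geno(fam, v$vid, v$chrom, v$pos, v$ref, v$alt, par, "0/1")
          }
        }
      }
    }

    meta[[f]] <- data.frame(
      sample_id = child, family_id = fam,
      phenotype_group = if (stats::runif(1) < config$ndd_fraction) "NDD" else "non_NDD",
      solved_status = sample(c("solved", "unsolved"), 1, prob = c(0.3, 0.7)),
      solved_gene = NA_character_, stringsAsFactors = FALSE)
  }

  geno <- do.call(rbind, geno)
  ped <- do.call(rbind, ped)
  meta <- do.call(rbind, meta)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(family_id = character(), sample_id = character(),
               gene_id = character(), kind = character(), rule = character(),
               variant1 = character(), variant2 = character())
  vids <- unique(geno$variant_id)
  planted <- vapply(vids, function(v) isTRUE(vmeta[[v]]), logical(1))
  freq <- data.frame(
    variant_id = vids,
    gnomad_ac = ifelse(planted, 0L, stats::rpois(length(vids), 2)),
    gnomad_nhomalt = 0L, internal_nhomalt = 0L,
    aou_ac = ifelse(planted, 0L, stats::rpois(length(vids), 5)),
    aou_nhomalt = 0L, gnomad_flagged = FALSE, stringsAsFactors = FALSE)
  list(geno = geno, ped = ped, meta = meta, freq = freq, genes = genes,
       truth = truth)
}

#' Write a synthetic cohort to VCF, PED and TSV files
#'
#' The VCF is v4.2, 1-based, one biallelic record per variant with
#' GT:DP:AD per sample (samples without a genotype line at a site are
#' written as confidently homozygous reference at depth 30).
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory.
#' @return named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             meta = file.path(dir, "samples.tsv"),
             freq = file.path(dir, "frequencies.tsv"),
             truth = file.path(dir, "event_truth.tsv"))
  samples <- cohort$ped$sample_id
  g <- cohort$geno
  key <- unique(g[, c("chrom", "pos", "ref", "alt", "variant_id")])
  key <- key[order(key$chrom, key$pos, key$ref, key$alt), ]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(key))) {
    rows <- g[g$variant_id == key$variant_id[i], , drop = FALSE]
    cells <- vapply(samples, function(s) {
      r <- rows[rows$sample_id == s, , drop = FALSE]
      if (nrow(r) == 0) return("0/0:30:30,0")
      sprintf("%s:%d:%d,%d", r$gt[1], r$dp[1], r$dp[1] - r$alt_reads[1],
              r$alt_reads[1])
    }, "")
    lines <- c(lines, paste(c(key$chrom[i], key$pos[i], key$variant_id[i],
                              key$ref[i], key$alt[i], ".", "PASS", ".",
                              "GT:DP:AD", cells), collapse = "\t"))
  }
  writeLines(lines, paths["vcf"])
  utils::write.table(cohort$ped[, c("family_id", "sample_id", "father_id",
                                    "mother_id", "sex", "phenotype")],
                     paths["ped"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$freq, paths["freq"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Simulate per-gene carrier status for burden testing
#'
#' Directly generates the event and label tables consumed by
#' [run_enrichment()], with per-group carrier probabilities per gene —
#' the fast path for power and type-I-error studies that do not need
#' genotype-level round trips.
#'
#' @param n_group1,n_group2 samples per group (group1 = NDD / unsolved
#'   depending on partition).
#' @param gene_rates data frame: `gene_id`, `rate_group1`, `rate_group2`.
#' @param partition which label pair to emit.
#' @param kind event kind to assign to carriers.
#' @param seed integer seed.
#' @return list with `events` and `labels`.
#' @export
simulate_burden_cohort <- function(n_group1, n_group2, gene_rates,
                                   partition = c("ndd_vs_nonndd",
                                                 "solved_vs_unsolved"),
                                   kind = "de_novo", seed = 1L) {
  partition <- match.arg(partition)
  stopifnot(all(gene_rates$rate_group1 >= 0 & gene_rates$rate_group1 <= 1),
            all(gene_rates$rate_group2 >= 0 & gene_rates$rate_group2 <= 1))
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_group1 + n_group2))
  grp <- rep(c(1, 2), c(n_group1, n_group2))
  labels <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (partition == "ndd_vs_nonndd") {
    labels$phenotype_group <- ifelse(grp == 1, "NDD", "non_NDD")
  } else {
    labels$solved_status <- ifelse(grp == 1, "unsolved", "solved")
  }
  ev <- list()
  for (i in seq_len(nrow(gene_rates))) {
    rate <- ifelse(grp == 1, gene_rates$rate_group1[i],
                   gene_rates$rate_group2[i])
    hit <- stats::runif(length(ids)) < rate
    if (any(hit))
      ev[[length(ev) + 1]] <- data.frame(
        sample_id = ids[hit], gene_id = gene_rates$gene_id[i], kind = kind,
        stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(sample_id = character(), gene_id = character(),
               kind = character())
  list(events = events, labels = labels)
}
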