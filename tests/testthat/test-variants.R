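# small constructors for hand-built cohorts
g_row <- function(sid, vid, gt, dp = 30, gene = "G1") {
  parts <- strsplit(vid, ":")[[1]]
  ar <- switch(gt, "0/0" = 0L, "0/1" = as.integer(round(dp / 2)),
               "1/1" = dp, "./." = NA_integer_)
  data.frame(chrom = parts[1], pos = as.integer(parts[2]), ref = parts[3],
             alt = parts[4], sample_id = sid, gt = gt, dp = dp,
             alt_reads = ar, variant_id = vid, gene_id = gene,
             stringsAsFactors = FALSE)
}
trio_ped <- function(fam = "F1") {
  data.frame(family_id = fam, sample_id = paste0(fam, c("_c", "_f", "_m")),
             father_id = c(paste0(fam, "_f"), NA, NA),
             mother_id = c(paste0(fam, "_m"), NA, NA),
             sex = c(1, 1, 2), phenotype = c(2, 1, 1),
             affected = c(TRUE, FALSE, FALSE),
             structure = c("trio", "singleton", "singleton"),
             stringsAsFactors = FALSE)
}
duo_ped <- function(fam = "F1", parent = "mother") {
  par <- paste0(fam, if (parent == "mother") "_m" else "_f")
  data.frame(family_id = fam, sample_id = c(paste0(fam, "_c"), par),
             father_id = c(if (parent == "father") par else NA, NA),
             mother_id = c(if (parent == "mother") par else NA, NA),
             sex = c(1, 2), phenotype = c(2, 1),
             affected = c(TRUE, FALSE),
             structure = c(paste0("duo_", parent), "singleton"),
             stringsAsFactors = FALSE)
}

test_that("site-level de novo calls enforce genotypes and depth in all three", {
  ch <- list(gt = "0/1", dp = 30)
  expect_true(call_de_novo(ch, list(gt = "0/0", dp = 25), list(gt = "0/0", dp = 28)))
  expect_false(call_de_novo(ch, list(gt = "0/1", dp = 25), list(gt = "0/0", dp = 28)))
  expect_false(call_de_novo(ch, list(gt = "0/0", dp = 8), list(gt = "0/0", dp = 28)))
  expect_false(call_de_novo(list(gt = "0/1", dp = 9),
                            list(gt = "0/0", dp = 30), list(gt = "0/0", dp = 30)))
  expect_false(call_de_novo(ch, NULL, list(gt = "0/0", dp = 30)))
})

test_that("cohort de novo extraction requires parental hom-ref at depth", {
  ped <- trio_ped()
  v <- "chr1:100:A:T"
  geno <- rbind(g_row("F1_c", v, "0/1"), g_row("F1_f", v, "0/0"),
                g_row("F1_m", v, "0/0"))
  ev <- call_candidate_events(geno, ped)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "de_novo")
  # low-depth parent kills the call
  geno2 <- geno; geno2$dp[2] <- 8
  expect_equal(nrow(call_candidate_events(geno2, ped)), 0)
})

test_that("biallelic rule 1: homozygous proband regardless of structure", {
  v <- "chr1:100:A:T"
  ped <- trio_ped()
  geno <- rbind(g_row("F1_c", v, "1/1"), g_row("F1_f", v, "0/1"),
                g_row("F1_m", v, "0/1"))
  ev <- call_candidate_events(geno, ped)
  expect_equal(ev$rule, "homozygous_or_hemizygous")
  expect_equal(ev$kind, "biallelic")
  # singleton homozygote also qualifies
  sped <- data.frame(family_id = "F2", sample_id = "F2_c",
                     father_id = NA, mother_id = NA, sex = 1, phenotype = 2,
                     affected = TRUE, structure = "singleton",
                     stringsAsFactors = FALSE)
  ev2 <- call_candidate_events(g_row("F2_c", v, "1/1"), sped)
  expect_equal(ev2$rule, "homozygous_or_hemizygous")
})

test_that("biallelic rule 2: trans compound het needs opposite parental origins", {
  ped <- trio_ped()
  a <- "chr1:100:A:T"; b <- "chr1:120:C:G"
  trans <- rbind(
    g_row("F1_c", a, "0/1"), g_row("F1_f", a, "0/0"), g_row("F1_m", a, "0/1"),
    g_row("F1_c", b, "0/1"), g_row("F1_f", b, "0/1"), g_row("F1_m", b, "0/0"))
  ev <- call_candidate_events(trans, ped)
  expect_equal(ev$rule, "trio_trans")
  expect_setequal(c(ev$origin1, ev$origin2), c("maternal", "paternal"))
  # cis: both from the mother -> nothing
  cis <- trans
  cis$gt[cis$sample_id == "F1_f"] <- "0/0"
  cis$alt_reads[cis$sample_id == "F1_f"] <- 0L
  cis$gt[cis$sample_id == "F1_m"] <- "0/1"
  cis$alt_reads[cis$sample_id == "F1_m"] <- 15L
  expect_equal(nrow(call_candidate_events(cis, ped)), 0)
})

test_that("biallelic rule 3: duo with one inherited and one absent variant", {
  ped <- duo_ped(parent = "mother")
  a <- "chr1:100:A:T"; b <- "chr1:120:C:G"
  geno <- rbind(
    g_row("F1_c", a, "0/1"), g_row("F1_m", a, "0/1"),
    g_row("F1_c", b, "0/1"), g_row("F1_m", b, "0/0"))
  ev <- call_candidate_events(geno, ped)
  expect_equal(ev$rule, "duo_partial")
  expect_equal(ev$variant1, a)  # the inherited one
  expect_equal(ev$origin1, "maternal")
  expect_equal(ev$phase, "unknown")
  # both inherited from the sequenced parent -> no event
  geno2 <- geno; geno2$gt[4] <- "0/1"; geno2$alt_reads[4] <- 15L
  expect_equal(nrow(call_candidate_events(geno2, ped)), 0)
})

test_that("biallelic rule 4: de novo plus inherited pair is trans-assumed", {
  ped <- trio_ped()
  a <- "chr1:100:A:T"; b <- "chr1:120:C:G"
  geno <- rbind(
    g_row("F1_c", a, "0/1"), g_row("F1_f", a, "0/1"), g_row("F1_m", a, "0/0"),
    g_row("F1_c", b, "0/1"), g_row("F1_f", b, "0/0"), g_row("F1_m", b, "0/0"))
  ev <- call_candidate_events(geno, ped)
  pair <- ev[ev$rule == "denovo_plus_inherited", ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$variant1, a)
  expect_equal(pair$variant2, b)
  expect_equal(pair$phase, "trans_assumed")
  # the de novo half is also reported on its own
  expect_true(any(ev$kind == "de_novo" & ev$variant1 == b))
})

test_that("hemizygosity through an overlapping deletion promotes a het", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 50L, end = 200L,
                      strand = "+", stringsAsFactors = FALSE)
  sped <- data.frame(family_id = "F1", sample_id = "F1_c", father_id = NA,
                     mother_id = NA, sex = 1, phenotype = 2, affected = TRUE,
                     structure = "singleton", stringsAsFactors = FALSE)
  geno <- g_row("F1_c", "chr1:100:A:T", "0/1")
  expect_equal(nrow(call_candidate_events(geno, sped)), 0)
  cnv <- data.frame(sample_id = "F1_c", chrom = "chr1", start = 0L, end = 500L)
  ev <- call_candidate_events(geno, sped, cnv = cnv, genes = genes)
  expect_equal(ev$rule, "homozygous_or_hemizygous")
})

test_that("gene QC applies the median-VAF and problematic-overlap rules", {
  gene <- data.frame(gene_id = "G1", chrom = "chr1", start = 0L, end = 100L)
  calls <- data.frame(gt = "0/1", dp = c(20, 20, 20),
                      alt_reads = c(9, 10, 4))  # VAFs 0.45, 0.50, 0.20
  r <- gene_qc(gene, calls)
  expect_true(r$qc_pass)
  expect_equal(r$median_vaf, 0.45)
  low <- data.frame(gt = "0/1", dp = 20, alt_reads = 5)  # VAF 0.25
  expect_false(gene_qc(gene, low)$qc_pass)
  # 60% of the gene inside a problematic region
  bad <- data.frame(chrom = "chr1", start = 0L, end = 60L)
  r2 <- gene_qc(gene, calls, problematic = bad)
  expect_false(r2$qc_pass)
  expect_equal(r2$problematic_fraction, 0.6)
  ok <- data.frame(chrom = "chr1", start = 0L, end = 49L)
  expect_true(gene_qc(gene, calls, problematic = ok)$qc_pass)
  # zero-depth calls are excluded from the median
  zd <- data.frame(gt = "0/1", dp = c(0, 20), alt_reads = c(0, 10))
  expect_equal(gene_qc(gene, zd)$median_vaf, 0.5)
  expect_false(gene_qc(gene, zd[1, ])$qc_pass)
})

test_that("frequency profiles use strict printed inequalities", {
  mk <- function(gac = 0, ghom = 0, ihom = 0, aac = 0, ahom = 0, flag = FALSE)
    data.frame(gnomad_ac = gac, gnomad_nhomalt = ghom, internal_nhomalt = ihom,
               aou_ac = aac, aou_nhomalt = ahom, gnomad_flagged = flag)
  expect_false(frequency_filter(mk(ghom = 3), "de_novo", "initial")$pass)
  expect_true(frequency_filter(mk(ghom = 2, ihom = 4), "de_novo", "initial")$pass)
  expect_false(frequency_filter(mk(ihom = 5), "de_novo", "initial")$pass)
  expect_false(frequency_filter(mk(gac = 100), "de_novo", "rare")$pass)
  expect_true(frequency_filter(mk(gac = 99), "de_novo", "rare")$pass)
  expect_false(frequency_filter(mk(flag = TRUE), "de_novo", "rare")$pass)
  # refined criteria: AoU caps differ by inheritance
  expect_true(frequency_filter(mk(aac = 49), "de_novo", "rnu2_refined")$pass)
  expect_false(frequency_filter(mk(aac = 50), "de_novo", "rnu2_refined")$pass)
  expect_true(frequency_filter(mk(aac = 199), "biallelic", "rnu2_refined")$pass)
  expect_false(frequency_filter(mk(aac = 200), "biallelic", "rnu2_refined")$pass)
  expect_false(frequency_filter(mk(ahom = 1), "de_novo", "rnu2_refined")$pass)
  # the refined profile drops the heterozygote cap but keeps homozygote caps
  expect_true(frequency_filter(mk(gac = 5000), "biallelic", "rnu2_refined")$pass)
  expect_false(frequency_filter(mk(ghom = 3), "biallelic", "rnu2_refined")$pass)
  # every violated threshold is named
  r <- frequency_filter(mk(ghom = 3, ihom = 7, gac = 150, flag = TRUE),
                        "de_novo", "rare")
  expect_length(r$reasons, 4)
})

test_that("raising any frequency count never converts fail to pass", {
  set.seed(31)
  cols <- c("gnomad_ac", "gnomad_nhomalt", "internal_nhomalt", "aou_ac",
            "aou_nhomalt")
  for (i in 1:40) {
    f <- data.frame(gnomad_ac = sample(0:120, 1),
                    gnomad_nhomalt = sample(0:4, 1),
                    internal_nhomalt = sample(0:6, 1),
                    aou_ac = sample(0:250, 1), aou_nhomalt = sample(0:2, 1),
                    gnomad_flagged = FALSE)
    prof <- sample(c("initial", "rare", "rnu2_refined"), 1)
    kind <- sample(c("de_novo", "biallelic"), 1)
    before <- frequency_filter(f, kind, prof)$pass
    f2 <- f
    cc <- sample(cols, 1)
    f2[[cc]] <- f2[[cc]] + sample(1:50, 1)
    after <- frequency_filter(f2, kind, prof)$pass
    expect_false(!before && after, info = paste(prof, kind, cc))
  }
})

test_that("parental origin phasing uses carriers and external annotations", {
  ped <- trio_ped()
  a <- "chr1:100:A:T"; b <- "chr1:120:C:G"
  geno <- rbind(
    g_row("F1_c", a, "0/1"), g_row("F1_f", a, "0/0"), g_row("F1_m", a, "0/1"),
    g_row("F1_c", b, "0/1"), g_row("F1_f", b, "0/0"), g_row("F1_m", b, "0/0"))
  ev <- data.frame(family_id = "F1", sample_id = "F1_c", gene_id = "G1",
                   kind = "de_novo", rule = "trio_absent",
                   variant1 = c(a, b), variant2 = NA_character_,
                   phase = "unknown", origin1 = "unknown",
                   origin2 = NA_character_, stringsAsFactors = FALSE)
  out <- phase_parental_origin(ev, geno, ped)
  expect_equal(out$origin1, c("maternal", "unknown"))
  ann <- data.frame(variant_id = b, sample_id = "F1_c", origin = "paternal")
  out2 <- phase_parental_origin(ev, geno, ped, phase_annotation = ann)
  expect_equal(out2$origin1, c("maternal", "paternal"))
})

test_that("VCF parsing round-trips genotypes and decomposes multiallelics", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
           paste(c("chr1", "100", ".", "A", "T,G", ".", "PASS", ".",
                   "GT:DP:AD", "1/2:40:0,22,18", "0/1:30:14,16,0"),
                 collapse = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  g <- read_vcf_genotypes(f)
  expect_equal(nrow(g), 4)  # 2 alt alleles x 2 samples
  s1t <- g[g$sample_id == "S1" & g$alt == "T", ]
  expect_equal(s1t$gt, "0/1")
  expect_equal(s1t$alt_reads, 22L)
  s1g <- g[g$sample_id == "S1" & g$alt == "G", ]
  expect_equal(s1g$gt, "0/1")
  expect_equal(s1g$alt_reads, 18L)
  s2g <- g[g$sample_id == "S2" & g$alt == "G", ]
  expect_equal(s2g$gt, "0/0")
})

test_that("pedigree parsing derives family structures and validates parents", {
  p <- tempfile()
  writeLines(c("F1\tF1_c\tF1_f\tF1_m\t1\t2",
               "F1\tF1_f\t0\t0\t1\t1",
               "F1\tF1_m\t0\t0\t2\t1",
               "F2\tF2_c\t0\tF2_m\t2\t2",
               "F2\tF2_m\t0\t0\t2\t1",
               "F3\tF3_c\t0\t0\t1\t2"), p)
  ped <- read_ped(p)
  expect_equal(ped$structure[ped$sample_id == "F1_c"], "trio")
  expect_equal(ped$structure[ped$sample_id == "F2_c"], "duo_mother")
  expect_equal(ped$structure[ped$sample_id == "F3_c"], "singleton")
  writeLines("F1\tF1_c\tF1_f\t0\t1\t2", p)
  expect_error(read_ped(p), "absent")
})
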