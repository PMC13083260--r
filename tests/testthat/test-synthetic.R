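test_that("generators are deterministic: same config, identical outputs", {
  cfg <- sim_config(seed = 42, n_genes = 10, n_families = 25)
  expect_identical(simulate_gene_fixture(cfg), simulate_gene_fixture(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_clinical_matrix(cfg), simulate_clinical_matrix(cfg))
  expect_identical(simulate_feature_matrix(cfg), simulate_feature_matrix(cfg))
  # byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  write_gene_fixture(simulate_gene_fixture(cfg), d1)
  write_gene_fixture(simulate_gene_fixture(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("config validation enforces proportion and rate invariants", {
  expect_error(sim_config(family_structure_mix = c(trio = 0.5, duo = 0.2,
                                                   singleton = 0.1)),
               "sum to 1")
  expect_error(sim_config(background_rate = 1.2))
  expect_error(sim_config(molecular = list(n_controls = 10,
                                           n_cases = c(n4GA = 1, n35AG = 1,
                                                       biallelic = 1),
                                           n_features = 5, baseline = 0.5,
                                           noise_sd = -1, planted = NULL)))
  expect_error(sim_config(n_families = 0))
})

test_that("YAML configs round-trip through the reader", {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, n_genes = 5, n_families = 12,
                        family_structure_mix = list(trio = 0.5, duo = 0.3,
                                                    singleton = 0.2)), p)
  cfg <- read_sim_config(p)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_families, 12L)
  expect_equal(unname(cfg$family_structure_mix["duo"]), 0.3)
})

test_that("planted events are recovered exactly from the emitted files", {
  cfg <- sim_config(seed = 77, n_families = 40)
  co <- simulate_cohort(cfg)
  d <- tempfile()
  paths <- write_cohort(co, d)
  res <- screen_cohort(paths["vcf"], paths["ped"], paths["freq"], co$genes,
                       profile = "rare")
  expect_identical(normalize_events(res$events), normalize_events(co$truth))
})

test_that("an event-free cohort yields no candidate events", {
  cfg <- sim_config(seed = 5, n_families = 15,
                    event_mix = c(none = 1, de_novo = 0, compound_het = 0,
                                  homozygous = 0, duo_partial = 0,
                                  denovo_plus_inherited = 0))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth), 0)
  geno <- assign_genes(co$geno, co$genes)
  ped <- co$ped; ped$affected <- ped$phenotype == 2
  ped$structure <- "unused"
  d <- tempfile()
  paths <- write_cohort(co, d)
  res <- screen_cohort(paths["vcf"], paths["ped"], paths["freq"], co$genes)
  expect_equal(nrow(res$all_events), 0)
})

test_that("a single planted trio de novo round-trips through the VCF", {
  cfg <- sim_config(seed = 3, n_families = 1)
  co <- simulate_cohort(cfg, family_plan = data.frame(structure = "trio",
                                                      kind = "de_novo"))
  d <- tempfile()
  paths <- write_cohort(co, d)
  res <- screen_cohort(paths["vcf"], paths["ped"], paths["freq"], co$genes)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$kind, "de_novo")
  expect_equal(res$events$variant1, co$truth$variant1)
})

test_that("impossible planted events are rejected by structure", {
  cfg <- sim_config(seed = 3, n_families = 1)
  expect_error(simulate_cohort(cfg, family_plan = data.frame(
    structure = "singleton", kind = "compound_het")), "impossible")
  expect_error(simulate_cohort(cfg, family_plan = data.frame(
    structure = "trio", kind = "duo_partial")), "impossible")
})

test_that("null clinical generation produces no enrichment, planted odds do", {
  null_sig <- vapply(1:30, function(s) {
    sim <- simulate_clinical_matrix(sim_config(seed = s, clinical = list(
      n_per_group = c(a = 25, b = 25), n_features = 8, baseline_rate = 0.3,
      odds_multiplier = 1, missing_rate = 0.1)))
    res <- compare_clinical(sim$matrix, sim$groups, m = 8)
    sum(res$p_adjusted < 0.05)
  }, numeric(1))
  expect_gte(mean(null_sig == 0), 0.9)
  # zero missing rate emits a complete matrix
  sim0 <- simulate_clinical_matrix(sim_config(seed = 1, clinical = list(
    n_per_group = c(a = 10, b = 10), n_features = 5, baseline_rate = 0.4,
    odds_multiplier = 1, missing_rate = 0)))
  expect_false(anyNA(sim0$matrix))
})

test_that("null cohort enrichment p-values are not anti-conservative", {
  # exact-test p values are discrete and conservative, so strict
  # uniformity fails by construction; the property that matters is that
  # they are never stochastically smaller than uniform (no inflation)
  rates <- data.frame(gene_id = sprintf("G%02d", 1:40),
                      rate_group1 = 0.05, rate_group2 = 0.05)
  sim <- simulate_burden_cohort(250, 250, rates, seed = 17)
  res <- run_enrichment(sim$events, sim$labels, "ndd_vs_nonndd")
  ks <- suppressWarnings(stats::ks.test(res$p_raw[res$retained], "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(res$p_raw[res$retained] < 0.05), 0.05 + 0.07)
})

test_that("truncation of out-of-range molecular means warns and bounds values", {
  cfg <- sim_config(seed = 4, molecular = list(
    n_controls = 20, n_cases = c(n4GA = 2, n35AG = 2, biallelic = 2),
    n_features = 5, baseline = 0.95, noise_sd = 0.01,
    planted = data.frame(feature = 1, pattern = "common", effect = 0.2)))
  expect_warning(sim <- simulate_feature_matrix(cfg), "truncating")
  expect_true(all(sim$values >= 0 & sim$values <= 1))
})
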