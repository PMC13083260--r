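mk_covs <- function(n, case = NULL) {
  set.seed(1000 + n)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             age = runif(n, 1, 60),
             sex = sample(c("F", "M"), n, TRUE),
             cell_1 = runif(n, 0.1, 0.4), cell_2 = runif(n, 0.1, 0.4),
             case = case %||% rep(0:1, length.out = n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a noise-free planted effect is recovered exactly", {
  cv <- mk_covs(40)
  y <- 0.4 + 0.001 * cv$age + 0.08 * cv$case
  fit <- fit_feature_model(y, cv)
  expect_equal(fit$effect_main, 0.08, tolerance = 1e-10)
  expect_lt(fit$p_main, 1e-20)
})

test_that("coefficients match the closed-form normal equations on a small fixture", {
  # 6 points, two predictors: solve (X'X)^-1 X'y by hand as the oracle
  cv <- data.frame(sample_id = paste0("s", 1:6),
                   age = c(2, 4, 6, 8, 10, 12), sex = c(0, 1, 0, 1, 0, 1),
                   case = c(0, 0, 0, 1, 1, 1))
  y <- c(0.31, 0.35, 0.30, 0.46, 0.42, 0.50)
  X <- cbind(1, cv$age, cv$sex, cv$case)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- fit_feature_model(y, cv)
  expect_equal(fit$effect_main, beta[4], tolerance = 1e-12)
  # residual-based t p-value from first principles
  r <- y - X %*% beta
  s2 <- sum(r^2) / (6 - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[4, 4])
  p <- 2 * pt(abs(beta[4] / se), df = 2, lower.tail = FALSE)
  expect_equal(fit$p_main, p, tolerance = 1e-12)
})

test_that("null model p-values are uniform under label permutation", {
  set.seed(55)
  n <- 60
  cv <- mk_covs(n, case = sample(rep(0:1, each = 30)))
  vals <- matrix(runif(500 * n, 0.3, 0.7), 500, n)
  fit <- fit_feature_model(vals, cv)
  ks <- suppressWarnings(stats::ks.test(fit$p_main, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank deficiency and undersized designs are rejected by name", {
  cv <- mk_covs(30)
  cv$cell_2 <- cv$cell_1 * 2
  expect_error(fit_feature_model(runif(30), cv), "cell_2")
  expect_error(fit_feature_model(runif(5), mk_covs(5)), "more samples")
})

test_that("splicing filter applies all three thresholds and keeps best per gene", {
  res <- data.frame(
    feature_id = c("e1", "e2", "e3", "e4", "e5"),
    gene_id = c("GA", "GA", "GB", "GC", "GD"),
    mean_coverage = c(12, 50, 12, 12, 8),
    effect_main = c(0.06, 0.2, 0.04, -0.07, 0.3),
    p_main = c(0.001, 0.004, 0.005, 0.005, 1e-6))
  out <- filter_splicing(res)
  # e3 fails |dPSI|, e5 fails coverage; GA keeps only its smaller-p event
  expect_setequal(out$feature_id, c("e1", "e4"))
  expect_lte(nrow(out), length(unique(res$gene_id)))
  # tie on p resolves to the smaller feature id
  tie <- data.frame(feature_id = c("b", "a"), gene_id = "G",
                    mean_coverage = 20, effect_main = 0.1, p_main = 0.002)
  expect_equal(filter_splicing(tie)$feature_id, "a")
})

test_that("control-trained residuals are centred on controls and shift with cases", {
  set.seed(9)
  n <- 60
  cv <- mk_covs(n, case = rep(c(0, 1), c(50, 10)))
  ctrl <- cv$sample_id[cv$case == 0]
  base <- 0.5 + 0.002 * cv$age + 0.05 * (cv$sex == "M")
  vals <- rbind(base + 0.1 * cv$case + rnorm(n, 0, 0.01),
                base + rnorm(n, 0, 0.01))
  colnames(vals) <- cv$sample_id
  r <- residualize(vals, cv, ctrl)
  expect_lt(max(abs(rowMeans(r[, ctrl]))), 1e-10)
  case_ids <- setdiff(cv$sample_id, ctrl)
  expect_equal(mean(r[1, case_ids]), 0.1, tolerance = 0.05)
  expect_lt(abs(mean(r[2, case_ids])), 0.01)
})

test_that("probe patterns partition significant probes", {
  expect_equal(classify_probe(1e-7, -0.06, 0.5, 0.01, 0.5, 0.01), "common")
  expect_equal(classify_probe(0.5, 0.01, 0.5, 0.01, 1e-8, 0.09),
               "specific_biallelic")
  expect_equal(classify_probe(0.5, 0.01, 1e-8, 0.09, 0.5, 0.01),
               "specific_n35AG")
  expect_equal(classify_probe(0.2, 0.04, 0.2, 0.04, 0.2, 0.04), "none")
  # main + opposing variant effects: reference-class-specific
  expect_equal(classify_probe(1e-9, 0.1, 1e-9, -0.1, 1e-9, -0.1),
               "specific_n4GA")
  # main + same-sign variant effect stays common
  expect_equal(classify_probe(1e-9, 0.1, 1e-9, 0.1, 0.5, 0.0), "common")
  # exhaustively: every sig/non-sig combination yields exactly one pattern
  ps <- c(1e-8, 0.5); es <- c(0.1, 0.01)
  pats <- c("common", "specific_n35AG", "specific_biallelic",
            "specific_n4GA", "none")
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    expect_true(classify_probe(ps[a], es[a], ps[b], -es[b], ps[cc], es[cc])
                %in% pats)
})

test_that("pattern summaries compute per-sample means and exact Wilcoxon", {
  adj <- rbind(p1 = c(1, 2, 3, 4, 5, 6), p2 = c(6, 5, 4, 3, 2, 1),
               q1 = c(1, 2, 3, 4, 5, 6))
  colnames(adj) <- paste0("s", 1:6)
  pats <- c(p1 = "common", p2 = "common", q1 = "specific_n35AG")
  grp <- setNames(rep(c("ctrl", "case"), each = 3), colnames(adj))
  ps <- pattern_summary(adj, pats, grp)
  expect_equal(unname(unlist(ps$sample_means[, "common"])), rep(3.5, 6))
  # distinct groups {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  q <- ps$tests[ps$tests$pattern == "specific_n35AG", ]
  expect_equal(q$p, 0.1)
  expect_equal(stats::wilcox.test(c(1, 4), c(2, 3))$p.value, 1)
})

test_that("planted molecular effects are recovered with correct patterns", {
  cfg <- sim_config(seed = 11, molecular = list(
    n_controls = 50, n_cases = c(n4GA = 4, n35AG = 3, biallelic = 3),
    n_features = 100, baseline = 0.5, noise_sd = 0.02,
    planted = data.frame(feature = 1:20,
                         pattern = rep(c("common", "specific_n35AG",
                                         "specific_biallelic",
                                         "specific_n4GA"), 5),
                         effect = 0.1)))
  sim <- simulate_feature_matrix(cfg)
  cl <- classify_probes(fit_feature_model(sim$values, sim$covariates,
                                          variant_terms = TRUE))
  detected <- cl$pattern[1:20] != "none"
  expect_gte(mean(detected), 0.9)
  expect_equal(sum(cl$pattern[1:20][detected] !=
                     sim$truth$pattern[1:20][detected]), 0)
  expect_equal(sum(cl$pattern[21:100] != "none"), 0)
})

test_that("zero noise reproduces planted effects to machine precision", {
  cfg <- sim_config(seed = 2, molecular = list(
    n_controls = 30, n_cases = c(n4GA = 4, n35AG = 3, biallelic = 3),
    n_features = 10, baseline = 0.4, noise_sd = 0,
    planted = data.frame(feature = 1, pattern = "common", effect = 0.1)))
  sim <- simulate_feature_matrix(cfg)
  fit <- fit_feature_model(sim$values, sim$covariates, variant_terms = TRUE)
  expect_equal(fit$effect_main[1], 0.1, tolerance = 1e-12)
  expect_equal(max(abs(fit$effect_main[-1])), 0, tolerance = 1e-12)
})
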