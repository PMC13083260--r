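#' Covariate-adjusted per-feature linear model
#'
#' Fits one ordinary-least-squares model per feature (splicing event PSI
#' or CpG methylation beta): value ~ intercept + age + sex + cell
#' fractions + group term(s). With `variant_terms = FALSE` the design
#' carries a single case/control indicator (the splicing analysis); with
#' `variant_terms = TRUE` two variant-specific indicators (`n35AG`,
#' `biallelic`) are added alongside the main case-control effect, the
#' remaining variant class (n.4G>A) acting as the reference (the
#' methylation analysis).
#'
#' @param values features x samples numeric matrix (or one feature vector).
#' @param covariates data frame with one row per sample in matrix column
#'   order: `age` (years), `sex` (`"F"`/`"M"`), zero or more `cell_*`
#'   fraction columns, `case` (0/1), and for `variant_terms = TRUE`
#'   `n35AG` and `biallelic` indicator columns.
#' @param variant_terms include the two variant-specific coefficients.
#' @return data frame, one row per feature, with estimate/p columns per
#'   modelled group term (`effect_main`, `p_main`, and when requested
#'   `effect_n35AG`, `p_n35AG`, `effect_biallelic`, `p_biallelic`).
#' @export
fit_feature_model <- function(values, covariates, variant_terms = FALSE) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == nrow(covariates))
  cells <- grep("^cell_", names(covariates), value = TRUE)
  terms <- c("age", "sex", cells, "case")
  if (variant_terms) terms <- c(terms, "n35AG", "biallelic")
  miss <- setdiff(terms, names(covariates))
  if (length(miss)) stop("covariates missing: ", paste(miss, collapse = ", "))
  covariates$sex <- .sex_indicator(covariates$sex)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = "+"))), covariates)
  if (nrow(covariates) <= ncol(X))
    stop("need more samples than predictors (n = ", nrow(covariates),
         ", p = ", ncol(X), ")")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  want <- c(case = "main")
  if (variant_terms) want <- c(want, n35AG = "n35AG", biallelic = "biallelic")

  fit <- stats::lm.fit(X, t(values))
  coefs <- t(fit$coefficients)                      # features x predictors
  res <- t(as.matrix(fit$residuals))                # features x samples
  df <- nrow(X) - qx$rank
  sigma2 <- rowSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  rows <- lapply(names(want), function(term) {
    j <- match(term, colnames(coefs))
    se <- sqrt(sigma2 * XtXinv[j, j])
    est <- coefs[, j]
    p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
    out <- data.frame(est, p)
    names(out) <- paste0(c("effect_", "p_"), want[[term]])
    out
  })
  out <- do.call(cbind, rows)
  out <- cbind(data.frame(feature_id = rownames(values) %||%
                            paste0("f", seq_len(nrow(values)))), out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# code sex as a 0/1 male indicator whatever the input representation
.sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(sex)
  as.numeric(sex %in% c("M", "male", "Male", "1"))
}

#' Filter splicing association results
#'
#' Keeps events with mean junction coverage above 10, an absolute fitted
#' group effect (delta PSI) above 0.05 and p below 0.01, then retains the
#' single most significant event per gene (ties broken by smaller feature
#' id).
#'
#' @param results association table from [fit_feature_model()] with added
#'   `gene_id` and `mean_coverage` columns.
#' @param min_coverage,min_delta_psi,max_p thresholds.
#' @return the filtered, one-row-per-gene subset.
#' @export
filter_splicing <- function(results, min_coverage = 10, min_delta_psi = 0.05,
                            max_p = 0.01) {
  stopifnot(all(c("gene_id", "mean_coverage") %in% names(results)))
  keep <- results$mean_coverage > min_coverage &
    abs(results$effect_main) > min_delta_psi &
    results$p_main < max_p
  r <- results[keep, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  r <- r[order(r$gene_id, r$p_main, r$feature_id), , drop = FALSE]
  r[!duplicated(r$gene_id), , drop = FALSE]
}

#' Residualize features on a control-trained covariate baseline
#'
#' Fits the covariate-only model (age, sex, cell fractions) per feature on
#' control samples, then subtracts the predicted baseline from every
#' sample — cases included — so that residuals express deviation from the
#' control expectation.
#'
#' @param values features x samples matrix.
#' @param covariates data frame, one row per sample in column order.
#' @param control_ids character vector of control sample (column) names.
#' @return residual matrix, same shape as `values`.
#' @export
residualize <- function(values, covariates, control_ids) {
  stopifnot(ncol(values) == nrow(covariates))
  cells <- grep("^cell_", names(covariates), value = TRUE)
  terms <- c("age", "sex", cells)
  covariates$sex <- .sex_indicator(covariates$sex)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = "+"))), covariates)
  ctrl <- match(control_ids, colnames(values))
  if (anyNA(ctrl)) stop("control ids absent from value matrix")
  if (length(ctrl) < ncol(X) + 2)
    stop("need at least ", ncol(X) + 2, " controls to train the baseline")
  beta <- qr.coef(qr(X[ctrl, , drop = FALSE]), t(values[, ctrl, drop = FALSE]))
  pred <- X %*% beta                                # samples x features
  values - t(pred)
}

#' Classify a significant CpG probe into a variant-association pattern
#'
#' Per-coefficient significance is p below `p_threshold` with absolute
#' effect above `effect_threshold`. Probes significant only for the main
#' case-control effect are common to all variant classes; probes
#' significant only for one variant-specific coefficient are specific to
#' that class; probes where the main effect is accompanied by a
#' variant-specific effect of opposite sign are specific to the reference
#' class (n.4G>A), the opposing coefficients cancelling the main shift in
#' the other classes.
#'
#' @param p_main,effect_main,p_n35AG,effect_n35AG,p_biallelic,effect_biallelic
#'   per-coefficient p values and estimates.
#' @param p_threshold,effect_threshold significance thresholds.
#' @return one of `"common"`, `"specific_n35AG"`, `"specific_biallelic"`,
#'   `"specific_n4GA"`, `"none"`.
#' @export
classify_probe <- function(p_main, effect_main, p_n35AG, effect_n35AG,
                           p_biallelic, effect_biallelic,
                           p_threshold = 1e-5, effect_threshold = 0.05) {
  sig <- function(p, e) p < p_threshold & abs(e) > effect_threshold
  s_main <- sig(p_main, effect_main)
  s_35 <- sig(p_n35AG, effect_n35AG)
  s_bi <- sig(p_biallelic, effect_biallelic)
  if (!s_main && !s_35 && !s_bi) return("none")
  if (s_main && !s_35 && !s_bi) return("common")
  if (!s_main && s_35 && !s_bi) return("specific_n35AG")
  if (!s_main && !s_35 && s_bi) return("specific_biallelic")
  # main effect plus variant-specific effect(s)
  opposing <- (s_35 && sign(effect_n35AG) != sign(effect_main)) ||
    (s_bi && sign(effect_biallelic) != sign(effect_main))
  if (s_main && opposing) return("specific_n4GA")
  if (s_main) return("common")
  # both variant-specific terms significant without a main effect
  "specific_n35AG"
}

#' Classify every probe in an association table
#'
#' @param results association table from
#'   `fit_feature_model(..., variant_terms = TRUE)`.
#' @param p_threshold,effect_threshold thresholds, see [classify_probe()].
#' @return `results` with a `pattern` column.
#' @export
classify_probes <- function(results, p_threshold = 1e-5,
                            effect_threshold = 0.05) {
  results$pattern <- vapply(seq_len(nrow(results)), function(i)
    classify_probe(results$p_main[i], results$effect_main[i],
                   results$p_n35AG[i], results$effect_n35AG[i],
                   results$p_biallelic[i], results$effect_biallelic[i],
                   p_threshold, effect_threshold), "")
  results
}

#' Per-sample pattern means and pairwise Wilcoxon comparisons
#'
#' For each association pattern, averages the adjusted (residualized)
#' values over that pattern's probes per sample, then compares the
#' per-sample means between every pair of groups with a two-sided
#' Wilcoxon rank-sum test (exact when both groups have at most 50 samples
#' and no ties; normal approximation with tie correction otherwise).
#'
#' @param adjusted features x samples matrix of adjusted values.
#' @param patterns named character vector: pattern per feature.
#' @param groups named character vector: group per sample.
#' @return list with `sample_means` (samples x patterns data frame) and
#'   `tests` (pattern, group pair, W, p).
#' @export
pattern_summary <- function(adjusted, patterns, groups) {
  pats <- setdiff(unique(patterns), "none")
  if (length(pats) == 0) stop("no non-trivial pattern present")
  sm <- sapply(pats, function(p) {
    idx <- which(patterns == p)
    if (length(idx) == 1) adjusted[idx, ] else colMeans(adjusted[idx, , drop = FALSE])
  })
  sm <- as.data.frame(sm)
  rownames(sm) <- colnames(adjusted)
  groups <- groups[colnames(adjusted)]
  tests <- list()
  gl <- unique(groups)
  for (p in pats) {
    if (length(which(patterns == p)) == 0) { warning("empty pattern ", p); next }
    for (i in seq_along(gl)) for (j in seq_along(gl)) {
      if (i >= j) next
      x <- sm[groups == gl[i], p]; y <- sm[groups == gl[j], p]
      exact <- length(x) <= 50 && length(y) <= 50 &&
        !any(duplicated(c(x, y)))
      wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
      tests[[length(tests) + 1]] <- data.frame(
        pattern = p, group1 = gl[i], group2 = gl[j],
        W = unname(wt$statistic), p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  list(sample_means = sm, tests = do.call(rbind, tests))
}
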