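#' Compare one categorical clinical feature between variant groups
#'
#' Exact two-sided Fisher test on the observed contingency table (2 x 2 up
#' to 2 x 5), Bonferroni-adjusted with an explicit family size `m`
#' (family sizes are study-level choices — e.g. the number of features
#' compared between two variant classes — and are never inferred).
#'
#' @param tab contingency table: groups in rows, feature levels in columns.
#' @param m Bonferroni family size.
#' @return list with `p_raw`, `p_adjusted`, `m`, `tested`.
#' @export
compare_feature <- function(tab, m) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0)
    return(list(p_raw = NA_real_, p_adjusted = NA_real_, m = m, tested = FALSE))
  p <- fisher_two_sided(tab)
  list(p_raw = p, p_adjusted = bonferroni_adjust(p, m), m = m, tested = TRUE)
}

#' Keep features with enough informative patients to reach significance
#'
#' A feature is kept when the most extreme allocation of its informative
#' (non-missing) patients across the two groups could yield a two-sided
#' Fisher p below `alpha` — i.e. the feature is testable at all in this
#' cohort. Features with too few informative patients per group are
#' dropped before testing rather than diluting the Bonferroni family.
#'
#' @param matrix patients x features data frame/matrix with values in
#'   \[0, 1\] or `NA`.
#' @param groups factor/character of group labels per patient (2 groups).
#' @param alpha significance level.
#' @return character vector of retained feature names.
#' @export
retain_features <- function(matrix, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  keep <- vapply(colnames(matrix), function(f) {
    inf <- !is.na(matrix[, f])
    n1 <- sum(inf & groups == levels(groups)[1])
    n2 <- sum(inf & groups == levels(groups)[2])
    if (n1 == 0 || n2 == 0) return(FALSE)
    # most extreme observable table: all-1 in one group, all-0 in the other
    fisher_two_sided(matrix(c(n1, 0, 0, n2), nrow = 2, byrow = TRUE)) < alpha
  }, logical(1))
  colnames(matrix)[keep]
}

#' Compare all retained clinical features between two groups
#'
#' Dichotomous features (values 0/1) are tabulated 2 x 2; graded features
#' form 2 x k tables over their observed levels.
#'
#' @param matrix patients x features (values in \[0,1\] or `NA`).
#' @param groups two-level group label per patient.
#' @param m Bonferroni family size (explicit, per study design).
#' @param alpha retention significance level.
#' @return data frame: `feature`, informative counts, `p_raw`,
#'   `p_adjusted`, sorted by adjusted p.
#' @export
compare_clinical <- function(matrix, groups, m, alpha = 0.05) {
  groups <- as.factor(groups)
  feats <- retain_features(matrix, groups, alpha)
  rows <- lapply(feats, function(f) {
    v <- matrix[, f]
    inf <- !is.na(v)
    tab <- table(groups[inf], factor(v[inf]))
    cmp <- compare_feature(tab, m)
    data.frame(feature = f,
               n_group1 = sum(inf & groups == levels(groups)[1]),
               n_group2 = sum(inf & groups == levels(groups)[2]),
               p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(feature = character(), n_group1 = integer(),
                      n_group2 = integer(), p_raw = numeric(),
                      p_adjusted = numeric()))
  out[order(out$p_adjusted, out$p_raw), , drop = FALSE]
}

#' Hierarchical clustering of patients on clinical features
#'
#' Features (rows of the transposed matrix) are z-scored across patients;
#' patient-patient distances are Euclidean over pairwise-complete entries
#' rescaled by the proportion observed (the [stats::dist()] convention for
#' missing data), or computed after zero-filling; agglomeration is
#' Ward.D2.
#'
#' @param matrix patients x features, values in \[0,1\] or `NA`.
#' @param missing `"pairwise"` (default) or `"zero"` (replace missing by 0
#'   after scaling).
#' @return list with `hclust` (the tree) and `order` (leaf order as
#'   patient names).
#' @export
cluster_patients <- function(matrix, missing = c("pairwise", "zero")) {
  missing <- match.arg(missing)
  stopifnot(nrow(matrix) >= 2)
  m <- as.matrix(matrix)
  # z-score each feature across patients; constant features map to 0
  zs <- apply(m, 2, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    mu <- mean(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mu) / s
  })
  rownames(zs) <- rownames(m)
  if (missing == "zero") zs[is.na(zs)] <- 0
  d <- stats::dist(zs)
  hc <- stats::hclust(d, method = "ward.D2")
  list(hclust = hc, order = rownames(zs)[hc$order])
}

#' PCA of patients on clinical features
#'
#' Missing values are replaced by 0, columns centered and unit-scaled,
#' then decomposed by SVD; zero-variance columns are dropped with a
#' warning. Component signs follow the convention that the
#' largest-magnitude loading of each component is positive.
#'
#' @param matrix patients x features.
#' @return list with `scores`, `loadings`, `var_explained`.
#' @export
pca_patients <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  m[is.na(m)] <- 0
  v <- apply(m, 2, stats::sd)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}
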