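#' Generate a synthetic molecular feature matrix with covariates
#'
#' Emulates a PSI (splicing) or beta (methylation) matrix: per-feature
#' baselines, covariate effects (age, sex, blood cell fractions), planted
#' case or variant-class-specific effects, and truncated-Gaussian noise
#' keeping values in \[0, 1\]. Cases split into the three variant classes
#' (n.4G>A reference, n.35A>G, biallelic); a planted `pattern` decides
#' which samples carry the shift:
#' `common` shifts every case, `specific_n35AG` and `specific_biallelic`
#' shift only that class, and `specific_n4GA` shifts only the reference
#' class (realized as a main effect opposed by equal variant-specific
#' effects).
#'
#' @param config a [sim_config()]; uses the `molecular` block and `seed`.
#'   `molecular$planted` is a data frame (`feature` index, `pattern`,
#'   `effect`); `NULL` plants nothing (a null matrix).
#' @return list with `values` (features x samples), `covariates` (one row
#'   per sample: `age`, `sex`, `cell_1..3`, `case`, `n35AG`, `biallelic`),
#'   `groups` (sample class labels), and `truth`.
#' @export
simulate_feature_matrix <- function(config = sim_config()) {
  mo <- config$molecular
  set.seed(config$seed)
  nc <- mo$n_controls
  ncase <- mo$n_cases
  stopifnot(all(c("n4GA", "n35AG", "biallelic") %in% names(ncase)))
  n <- nc + sum(ncase)
  groups <- c(rep("control", nc),
              rep(c("n4GA", "n35AG", "biallelic"), ncase))
  ids <- sprintf("S%03d", seq_len(n))
  cells <- matrix(stats::rgamma(n * 3, shape = 2), n, 3)
  # measured fractions cover a variable share of the blood; the remainder
  # (unprofiled cell types) keeps the design full rank
  cells <- cells / rowSums(cells) * stats::runif(n, 0.75, 0.95)
  covariates <- data.frame(
    sample_id = ids,
    age = round(stats::runif(n, 1, 60), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cell_1 = cells[, 1], cell_2 = cells[, 2], cell_3 = cells[, 3],
    case = as.numeric(groups != "control"),
    n35AG = as.numeric(groups == "n35AG"),
    biallelic = as.numeric(groups == "biallelic"),
    stringsAsFactors = FALSE)

  m <- mo$n_features
  base <- rep(mo$baseline, length.out = m)
  # mild covariate structure common to all samples
  b_age <- stats::rnorm(m, 0, 0.0005)
  b_sex <- stats::rnorm(m, 0, 0.01)
  b_cell <- matrix(stats::rnorm(m * 3, 0, 0.02), m, 3)
  sexn <- as.numeric(covariates$sex == "M")

  mu <- matrix(base, m, n) +
    outer(b_age, covariates$age) + outer(b_sex, sexn) + b_cell %*% t(cells)

  truth <- data.frame(feature = sprintf("f%04d", seq_len(m)),
                      pattern = "none", effect = 0, stringsAsFactors = FALSE)
  if (!is.null(mo$planted)) {
    for (i in seq_len(nrow(mo$planted))) {
      j <- mo$planted$feature[i]
      pat <- mo$planted$pattern[i]
      eff <- mo$planted$effect[i]
      shift <- switch(pat,
        common = eff * (groups != "control"),
        specific_n35AG = eff * (groups == "n35AG"),
        specific_biallelic = eff * (groups == "biallelic"),
        specific_n4GA = eff * (groups == "n4GA"),
        stop("unknown planted pattern: ", pat))
      mu[j, ] <- mu[j, ] + shift
      truth$pattern[j] <- pat
      truth$effect[j] <- eff
    }
  }
  if (any(mu < 0 | mu > 1))
    warning("planted effects push some means outside [0, 1]; truncating")
  vals <- mu + matrix(stats::rnorm(m * n, 0, mo$noise_sd), m, n)
  vals <- pmin(pmax(vals, 0), 1)
  dimnames(vals) <- list(truth$feature, ids)
  list(values = vals, covariates = covariates, groups = stats::setNames(groups, ids),
       truth = truth)
}

#' Write a molecular matrix and covariates to TSV
#'
#' @param sim list from [simulate_feature_matrix()].
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_feature_matrix <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(values = file.path(dir, "features.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "feature_truth.tsv"))
  utils::write.table(data.frame(feature_id = rownames(sim$values),
                                sim$values, check.names = FALSE),
                     paths["values"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$covariates, paths["covariates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
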