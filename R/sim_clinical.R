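#' Generate a synthetic categorical clinical feature matrix
#'
#' Binary features on the 0-1 severity scale with a per-feature baseline
#' rate in group 1 and a planted odds multiplier in group 2; entries are
#' then masked missing completely at random.
#'
#' @param config a [sim_config()]; uses the `clinical` block and `seed`.
#' @return list with `matrix` (patients x features, 0/1/NA), `groups`
#'   (factor per patient) and `truth` (per-feature data frame with
#'   `baseline_rate` and `odds_multiplier`).
#' @export
simulate_clinical_matrix <- function(config = sim_config()) {
  cl <- config$clinical
  set.seed(config$seed)
  npg <- cl$n_per_group
  stopifnot(length(npg) >= 2)
  groups <- factor(rep(names(npg), npg), levels = names(npg))
  n <- sum(npg); m <- cl$n_features
  odds_mult <- rep(cl$odds_multiplier, length.out = m)
  p1 <- rep(cl$baseline_rate, m)
  o2 <- (p1 / (1 - p1)) * odds_mult
  p2 <- o2 / (1 + o2)
  mat <- matrix(NA_real_, n, m,
                dimnames = list(sprintf("P%03d", seq_len(n)),
                                sprintf("feat%02d", seq_len(m))))
  for (j in seq_len(m)) {
    p <- ifelse(groups == levels(groups)[1], p1[j], p2[j])
    mat[, j] <- as.numeric(stats::runif(n) < p)
  }
  if (cl$missing_rate > 0)
    mat[matrix(stats::runif(n * m) < cl$missing_rate, n, m)] <- NA_real_
  list(matrix = mat, groups = groups,
       truth = data.frame(feature = colnames(mat), baseline_rate = p1,
                          odds_multiplier = odds_mult,
                          stringsAsFactors = FALSE))
}

#' Write a clinical matrix plus group labels to TSV
#'
#' @param sim list from [simulate_clinical_matrix()].
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_clinical_matrix <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "clinical.tsv"),
             groups = file.path(dir, "clinical_groups.tsv"))
  df <- data.frame(patient_id = rownames(sim$matrix), sim$matrix,
                   check.names = FALSE)
  utils::write.table(df, paths["matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(patient_id = rownames(sim$matrix), group = sim$groups),
    paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
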