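#' Exact two-sided Fisher test on a 2 x k contingency table
#'
#' Thin, validated front end to [stats::fisher.test()] used throughout the
#' burden and clinical comparisons. The two-sided p value follows the
#' sum-of-probabilities convention: it is the total probability of all
#' tables (with the observed margins) whose probability does not exceed
#' that of the observed table. Degenerate tables, where a whole row or
#' column margin is zero, carry no information and return p = 1.
#'
#' @param tab integer matrix with 2 rows and 2 to 5 columns (or k x 2),
#'   non-negative counts.
#' @return the two-sided p value (scalar).
#' @export
fisher_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (any(is.na(tab))) stop("contingency table contains NA")
  if (any(tab < 0)) stop("contingency table contains negative cells")
  if (any(tab != round(tab))) stop("contingency table cells must be integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  min(stats::fisher.test(tab)$p.value, 1)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p numeric vector of raw p values in \[0, 1\].
#' @param m family size; must be at least `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p values")
  pmin(1, m * p)
}

#' Minimum carrier count needed to reach significance
#'
#' Smallest number of carriers m such that the most extreme allocation of
#' those m carriers between two groups of sizes `n1` and `n2` yields a
#' two-sided Fisher p value below `alpha`. Used to decide which genes (or
#' clinical features) are even testable in a cohort of a given size.
#'
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param convention `"sum_smaller"` (sum of table probabilities not
#'   exceeding the observed one; the [stats::fisher.test()] convention) or
#'   `"doubled_one_sided"` (twice the smaller tail, capped at 1).
#' @return the minimum carrier count, or `NA_integer_` if no allocation of
#'   up to `n1 + n2` carriers reaches significance.
#' @export
min_carriers <- function(n1, n2, alpha = 0.05,
                         convention = c("sum_smaller", "doubled_one_sided")) {
  convention <- match.arg(convention)
  stopifnot(n1 > 0, n2 > 0, alpha > 0, alpha < 1)
  for (m in seq_len(n1 + n2)) {
    p <- Inf
    if (m <= n1) p <- min(p, .extreme_p(m, n1, n2, convention))
    if (m <= n2) p <- min(p, .extreme_p(m, n2, n1, convention))
    if (p < alpha) return(m)
  }
  NA_integer_
}

# two-sided p for the table [[m, 0], [nA - m, nB]]
.extreme_p <- function(m, nA, nB, convention) {
  tab <- matrix(c(m, 0L, nA - m, nB), nrow = 2, byrow = TRUE)
  if (convention == "sum_smaller") return(fisher_two_sided(tab))
  # doubled one-sided: carriers hypergeometric over groups
  lo <- stats::phyper(m, nA, nB, m)           # P(X <= m) with X ~ carriers in A
  hi <- stats::phyper(m - 1, nA, nB, m, lower.tail = FALSE)  # P(X >= m)
  min(1, 2 * min(lo, hi))
}

#' One-tailed binomial predominance test with exact lower confidence bound
#'
#' Upper-tail exact binomial test of `k` successes in `n` trials against a
#' null proportion `p0`, with a one-sided Clopper-Pearson lower bound on
#' the success proportion. Used, e.g., to test whether de novo alleles
#' arise predominantly on one parental haplotype, or whether a clinical
#' feature predominates in carriers.
#'
#' @param k number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability, in (0, 1).
#' @param conf_level one-sided confidence level for the lower bound.
#' @return a list with `k`, `n`, `p0`, `p_one_tailed` and `ci_lower`
#'   (the `1 - conf_level` quantile of Beta(k, n - k + 1); 0 when k = 0).
#' @export
binomial_predominance <- function(k, n, p0 = 0.5, conf_level = 0.95) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  ci_lower <- if (k == 0) 0 else stats::qbeta(1 - conf_level, k, n - k + 1)
  structure(
    list(k = k, n = n, p0 = p0, p_one_tailed = p, ci_lower = ci_lower),
    class = "binomial_predominance"
  )
}

#' @export
print.binomial_predominance <- function(x, ...) {
  cat(sprintf("One-tailed binomial test: %d / %d vs p0 = %g\n", x$k, x$n, x$p0))
  cat(sprintf("  P = %.3g; one-sided 95%% lower bound = %.4f\n",
              x$p_one_tailed, x$ci_lower))
  invisible(x)
}

#' Mosaic (or any) allele fraction as an integer percentage
#'
#' @param alt_reads reads supporting the alternate allele.
#' @param total_reads total reads at the site.
#' @return `round(100 * alt_reads / total_reads)`.
#' @export
allele_fraction_percent <- function(alt_reads, total_reads) {
  stopifnot(total_reads > 0, alt_reads >= 0, alt_reads <= total_reads)
  round(100 * alt_reads / total_reads)
}

#' Reassign cases solved by known snRNA disease genes to the unsolved group
#'
#' Discovery burden analyses compare solved and unsolved cases; cases whose
#' diagnosis rests on a variant in an snRNA gene with an already-known
#' disease association are relabelled unsolved, restoring the state of
#' knowledge that preceded those associations.
#'
#' @param labels data frame with columns `sample_id`, `solved_status`
#'   (`"solved"`/`"unsolved"`) and `solved_gene` (NA when unsolved).
#' @param known_snrna_genes character vector of gene ids.
#' @return `labels` with the affected rows set to `"unsolved"`.
#' @export
reassign_known_solved <- function(labels, known_snrna_genes) {
  stopifnot(all(c("sample_id", "solved_status", "solved_gene") %in% names(labels)))
  hit <- labels$solved_status == "solved" &
    !is.na(labels$solved_gene) &
    labels$solved_gene %in% known_snrna_genes
  labels$solved_status[hit] <- "unsolved"
  labels
}

#' Gene-level carrier burden enrichment
#'
#' Builds one 2 x 2 carrier-by-group table per gene (a carrier is a sample
#' with at least one qualifying event in that gene), applies the
#' minimum-carrier retention rule, tests retained genes with the exact
#' two-sided Fisher test, and Bonferroni-corrects over the genes actually
#' tested within the partition/stratum.
#'
#' @param events data frame of candidate events with at least `sample_id`,
#'   `gene_id` and `kind` (`"de_novo"`/`"biallelic"`); pass events already
#'   filtered to the frequency profile of interest.
#' @param labels data frame with `sample_id` plus `solved_status` and/or
#'   `phenotype_group` columns labelling every analyzed sample.
#' @param partition `"solved_vs_unsolved"` or `"ndd_vs_nonndd"`.
#' @param kind event-kind stratum to test, or `NULL` for all events.
#' @param alpha significance level used both for the retention rule and
#'   (after adjustment) for reporting.
#' @param convention passed to [min_carriers()].
#' @return data frame with one row per gene: carrier counts per group,
#'   `retained`, `p_raw`, `p_adjusted`, `m`.
#' @export
run_enrichment <- function(events, labels,
                           partition = c("solved_vs_unsolved", "ndd_vs_nonndd"),
                           kind = NULL, alpha = 0.05,
                           convention = "sum_smaller") {
  partition <- match.arg(partition)
  if (!is.null(kind)) events <- events[events$kind %in% kind, , drop = FALSE]
  unlabeled <- setdiff(unique(events$sample_id), labels$sample_id)
  if (length(unlabeled) > 0)
    stop("samples with events but no label: ", paste(unlabeled, collapse = ", "))

  grp <- if (partition == "solved_vs_unsolved") {
    factor(labels$solved_status, levels = c("unsolved", "solved"))
  } else {
    factor(labels$phenotype_group, levels = c("NDD", "non_NDD"))
  }
  if (anyNA(grp)) stop("every analyzed sample must carry a group label")
  names_grp <- levels(grp)
  n1 <- sum(grp == names_grp[1])
  n2 <- sum(grp == names_grp[2])
  m_min <- min_carriers(n1, n2, alpha, convention)

  genes <- sort(unique(events$gene_id))
  rows <- lapply(genes, function(g) {
    carriers <- unique(events$sample_id[events$gene_id == g])
    is_car <- labels$sample_id %in% carriers
    c1 <- sum(is_car & grp == names_grp[1])
    c2 <- sum(is_car & grp == names_grp[2])
    retained <- !is.na(m_min) && (c1 + c2) >= m_min
    p <- if (retained) {
      fisher_two_sided(matrix(c(c1, c2, n1 - c1, n2 - c2), nrow = 2, byrow = TRUE))
    } else NA_real_
    data.frame(gene_id = g, carriers_group1 = c1, carriers_group2 = c2,
               n_group1 = n1, n_group2 = n2, retained = retained,
               p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), carriers_group1 = integer(),
                      carriers_group2 = integer(), n_group1 = integer(),
                      n_group2 = integer(), retained = logical(),
                      p_raw = numeric(), p_adjusted = numeric(), m = integer())
    return(res)
  }
  m <- sum(res$retained)
  res$p_adjusted <- NA_real_
  if (m > 0)
    res$p_adjusted[res$retained] <- bonferroni_adjust(res$p_raw[res$retained], m)
  res$m <- m
  attr(res, "group_levels") <- names_grp
  attr(res, "min_carriers") <- m_min
  res
}
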