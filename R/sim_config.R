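#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults encode the statistical structure the pipeline's analyses
#' assume: a rare-disease cohort of mostly trios with a minority of duos
#' and singletons, de novo and biallelic events planted at known
#' positions, carrier rates that may differ between phenotype groups, and
#' bounded molecular values with truncated-Gaussian noise.
#'
#' @param seed integer; the single source of randomness for every output.
#' @param n_genes number of synthetic snRNA genes.
#' @param n_families number of families in the cohort.
#' @param family_structure_mix named proportions over
#'   `c("trio", "duo", "singleton")`; must sum to 1.
#' @param event_mix named proportions over planted event kinds
#'   `c("none", "de_novo", "compound_het", "homozygous", "duo_partial",
#'   "denovo_plus_inherited")`; kinds incompatible with a family's
#'   structure are renormalized away per family. Must sum to 1.
#' @param background_rate per-family probability of benign background
#'   variation (cis pairs, transmitted singles, common alleles) that must
#'   never form a candidate event.
#' @param ndd_fraction probability a proband is labelled NDD.
#' @param clinical list: `n_per_group`, `n_features`, `baseline_rate`,
#'   `odds_multiplier` (scalar or per-feature vector; 1 = null),
#'   `missing_rate`.
#' @param molecular list: `n_controls`, `n_cases` (named: n4GA, n35AG,
#'   biallelic), `n_features`, `baseline`, `noise_sd`, `planted`
#'   (data frame `feature`, `pattern`, `effect`) or `NULL`.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 8L,
                       n_families = 50L,
                       family_structure_mix = c(trio = 0.7, duo = 0.2,
                                                singleton = 0.1),
                       event_mix = c(none = 0.3, de_novo = 0.2,
                                     compound_het = 0.15, homozygous = 0.15,
                                     duo_partial = 0.1,
                                     denovo_plus_inherited = 0.1),
                       background_rate = 0.4,
                       ndd_fraction = 0.6,
                       clinical = list(n_per_group = c(group1 = 30, group2 = 30),
                                       n_features = 20, baseline_rate = 0.3,
                                       odds_multiplier = 1, missing_rate = 0.1),
                       molecular = list(n_controls = 50,
                                        n_cases = c(n4GA = 4, n35AG = 3,
                                                    biallelic = 3),
                                        n_features = 200, baseline = 0.5,
                                        noise_sd = 0.02, planted = NULL)) {
  stopifnot(n_genes >= 1, n_families >= 1)
  if (abs(sum(family_structure_mix) - 1) > 1e-8)
    stop("family_structure_mix proportions must sum to 1")
  if (abs(sum(event_mix) - 1) > 1e-8)
    stop("event_mix proportions must sum to 1")
  stopifnot(background_rate >= 0, background_rate <= 1,
            ndd_fraction >= 0, ndd_fraction <= 1,
            clinical$baseline_rate >= 0, clinical$baseline_rate <= 1,
            clinical$missing_rate >= 0, clinical$missing_rate <= 1,
            molecular$noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_families = as.integer(n_families),
                 family_structure_mix = family_structure_mix,
                 event_mix = event_mix, background_rate = background_rate,
                 ndd_fraction = ndd_fraction, clinical = clinical,
                 molecular = molecular),
            class = "sim_config")
}

#' Read a generator configuration from YAML
#'
#' Top-level keys mirror the [sim_config()] arguments; omitted keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "n_genes", "n_families", "background_rate",
              "ndd_fraction"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  for (k in c("family_structure_mix", "event_mix"))
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  for (k in c("clinical", "molecular"))
    if (!is.null(y[[k]])) {
      defaults <- formals(sim_config)[[k]]
      v <- eval(defaults)
      v[names(y[[k]])] <- y[[k]]
      args[[k]] <- v
    }
  do.call(sim_config, args)
}
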