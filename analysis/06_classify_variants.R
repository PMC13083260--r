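#!/usr/bin/env Rscript
# Hypermutability-adjusted ACMG classification: score evidence dossiers
# for a panel of representative U2-2 variants and combine into
# Pathogenic / Likely pathogenic / VUS calls.

suppressPackageStartupMessages(library(snrnascreen))

# representative dossiers: a recurrent dominant hotspot variant, a
# recessive allele in trans with a pathogenic partner, a cosegregating
# familial variant, and a common variant that should stay VUS
dossiers <- data.frame(
  variant = c("n.4G>A-like", "n.35A>G-like", "trans-partner",
              "familial", "frequent"),
  n_position = c("n.4", "n.35", "n.100", "n.120", "n.150"),
  denovo_recurrence = c(11, 11, 0, 0, 0),
  unrelated_case_count = c(11, 11, 2, 1, 2),
  gnomad_ac = c(0, 0, 3, 5, 200),
  aou_ac = c(2, 1, 20, 30, 600),
  coseg_affected_members = c(0, 0, 0, 3, 0),
  coseg_total_members = c(0, 0, 0, 5, 0),
  coseg_families = c(0, 0, 0, 1, 0),
  in_trans_with_lp_or_p = c(FALSE, FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

out <- classify_dossiers(dossiers)
print(out[, c("variant", "n_position", "evidence", "classification")])
utils::write.table(out, "results/acmg_classifications.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
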