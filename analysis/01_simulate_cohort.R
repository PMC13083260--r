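#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a gene catalog with annotation and
# signal tracks, and a rare-disease cohort (VCF/PED/metadata/frequencies)
# with planted de novo and biallelic events. Everything downstream reads
# the files written here.

suppressPackageStartupMessages(library(snrnascreen))

cfg <- sim_config(seed = 20260101, n_genes = 30, n_families = 200)
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

fix <- simulate_gene_fixture(cfg)
write_gene_fixture(fix, "results/sim/genes")
cat(sprintf("gene fixture: %d genes, %d cCRE-overlapping, %d hypermutable, %d HGNC\n",
            nrow(fix$genes), sum(fix$truth$ccre_true),
            length(fix$hypermutable_ids), length(fix$hgnc_ids)))

co <- simulate_cohort(cfg, genes = fix$genes)
write_cohort(co, "results/sim/cohort")
cat(sprintf("cohort: %d families (%d samples), %d planted events (%d de novo, %d biallelic)\n",
            cfg$n_families, nrow(co$ped), nrow(co$truth),
            sum(co$truth$kind == "de_novo"), sum(co$truth$kind == "biallelic")))
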