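#!/usr/bin/env Rscript
# Summarize small-RNA signal per gene (max normalized signal and covered
# bases per tissue/mode) and apply the detectability rule: >= 50% of the
# snRNA type's expected length covered in at least one tissue, all reads.

suppressPackageStartupMessages(library(snrnascreen))

base <- "results/sim/genes"
genes <- read_gene_table(file.path(base, "genes.tsv"))
tracks <- read_track_manifest(file.path(base, "tracks.tsv"))

su <- summarize_expression_all(genes, tracks)
su$log10_max <- report_log10(su$max_signal)
exp_len <- expected_snrna_lengths()[genes$snrna_type[match(su$gene_id, genes$gene_id)]]
su$coverage_fraction <- su$covered_bases / exp_len
su$coverage_bin <- coverage_bin(su$coverage_fraction)

det <- vapply(seq_len(nrow(genes)), function(i)
  detectable(su[su$gene_id == genes$gene_id[i], , drop = FALSE],
             genes$snrna_type[i]), logical(1))
cat(sprintf("%d of %d genes detectable in brain small RNA-seq signal\n",
            sum(det), nrow(genes)))
print(table(su$coverage_bin[su$mode == "all_reads"]))

utils::write.table(su, "results/expression_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(gene_id = genes$gene_id, detectable = det),
                   "results/expression_detectable.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
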