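#!/usr/bin/env Rscript
# Prioritize putatively functional snRNA genes: keep placed spliceosomal
# genes that overlap an ENCODE-style cCRE, are hypermutable, or carry an
# HGNC-approved symbol. H3K27ac overlap is annotated but does not gate.

suppressPackageStartupMessages(library(snrnascreen))

base <- "results/sim/genes"
genes <- read_gene_table(file.path(base, "genes.tsv"))
out <- prioritize_catalog(genes,
                          read_bed(file.path(base, "ccre.bed")),
                          read_bed(file.path(base, "h3k27ac.bed")),
                          readLines(file.path(base, "hypermutable.txt")),
                          readLines(file.path(base, "hgnc.txt")))

cat("filtering stages:\n")
print(out$stage_counts)
cat(sprintf("retained %d of %d placed spliceosomal genes\n",
            nrow(out$retained), nrow(out$genes)))
print(table(out$retained$retention_reason))

utils::write.table(out$retained, "results/catalog_retained.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
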