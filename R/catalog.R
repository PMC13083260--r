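#' Read a gene catalog TSV
#'
#' Columns: `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#' `strand`, `snrna_type`, `is_spliceosomal`, `is_pseudogene_annotation`.
#'
#' @param path TSV path with a header row.
#' @return data frame of gene records.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "snrna_type",
            "is_spliceosomal", "is_pseudogene_annotation")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) stop("gene table missing columns: ",
                             paste(miss, collapse = ", "))
  stopifnot(all(g$start < g$end), all(nzchar(g$chrom)))
  g$is_spliceosomal <- as.logical(g$is_spliceosomal)
  g$is_pseudogene_annotation <- as.logical(g$is_pseudogene_annotation)
  g
}

#' Read a BED file (0-based half-open) into an interval data frame
#'
#' @param path BED path (3+ columns, no header).
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 3) stop("BED file needs at least 3 columns: ", path)
  data.frame(chrom = b[[1]], start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), stringsAsFactors = FALSE)
}

#' Keep genes placed on identifiable chromosomes
#'
#' Drops records on contigs, scaffolds or patches by keeping only the
#' chromosomes listed in `allowed_chroms`; input order is preserved.
#'
#' @param genes gene data frame.
#' @param allowed_chroms character vector, e.g. `paste0("chr", c(1:22, "X", "Y"))`.
#' @return the retained subset.
#' @export
filter_placed <- function(genes, allowed_chroms) {
  stopifnot(length(allowed_chroms) > 0)
  genes[genes$chrom %in% allowed_chroms, , drop = FALSE]
}

#' Flag genes overlapping an annotation track
#'
#' Strand-agnostic 1-bp-or-more overlap between gene bodies and track
#' intervals under 0-based half-open semantics: `[10,20)` and `[20,30)` do
#' not overlap.
#'
#' @param genes gene data frame (`chrom`, `start`, `end`).
#' @param track interval data frame (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()].
#' @return logical vector, one entry per gene.
#' @export
flag_overlaps <- function(genes, track) {
  bad <- which(is.na(track$start) | is.na(track$end) | track$start >= track$end)
  if (length(bad) > 0)
    stop("malformed track interval at row(s): ", paste(bad, collapse = ", "))
  out <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0) next
    # shift half-open [s,e) to 1-based closed [s+1, e]
    gr <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
    tr <- IRanges::IRanges(track$start[ti] + 1L, track$end[ti])
    out[gi] <- IRanges::overlapsAny(gr, tr)
  }
  out
}

#' Retain putatively functional snRNA genes
#'
#' A gene (already restricted to placed, spliceosomal records) is retained
#' iff it overlaps a candidate cis-regulatory element, is reported
#' hypermutable, or carries an HGNC-approved symbol. H3K27ac overlap, when
#' present as a flag, is reported but does not gate retention.
#'
#' @param genes gene data frame with a logical `ccre_overlap` column.
#' @param hypermutable_ids,hgnc_ids character vectors of gene ids.
#' @return the retained subset, with a `retention_reason` column.
#' @export
prioritize <- function(genes, hypermutable_ids, hgnc_ids) {
  if (is.null(genes$ccre_overlap))
    stop("genes must carry a 'ccre_overlap' flag; run flag_overlaps() first")
  hyper <- genes$gene_id %in% hypermutable_ids
  hgnc <- genes$gene_id %in% hgnc_ids
  keep <- genes$ccre_overlap | hyper | hgnc
  out <- genes[keep, , drop = FALSE]
  out$retention_reason <- apply(
    cbind(cCRE = genes$ccre_overlap, hypermutable = hyper, HGNC = hgnc)[keep, , drop = FALSE],
    1, function(r) paste(names(r)[r], collapse = "+"))
  out
}

#' Full catalog prioritization pipeline
#'
#' Restricts to placed chromosomes, then to spliceosomal genes, annotates
#' cCRE and H3K27ac overlap, and applies the retention rule, reporting the
#' count surviving each stage.
#'
#' @param genes gene data frame ([read_gene_table()] layout).
#' @param ccre_track,h3k27ac_track interval data frames.
#' @param hypermutable_ids,hgnc_ids character vectors of ids.
#' @param allowed_chroms chromosomes considered placed.
#' @return list with `genes` (annotated placed spliceosomal set),
#'   `retained` (prioritized subset) and `stage_counts`.
#' @export
prioritize_catalog <- function(genes, ccre_track, h3k27ac_track,
                               hypermutable_ids, hgnc_ids,
                               allowed_chroms = paste0("chr", c(1:22, "X", "Y"))) {
  n_total <- nrow(genes)
  placed <- filter_placed(genes, allowed_chroms)
  splice <- placed[placed$is_spliceosomal, , drop = FALSE]
  splice$ccre_overlap <- flag_overlaps(splice, ccre_track)
  splice$h3k27ac_overlap <- flag_overlaps(splice, h3k27ac_track)
  splice$hypermutable <- splice$gene_id %in% hypermutable_ids
  splice$hgnc_approved <- splice$gene_id %in% hgnc_ids
  retained <- prioritize(splice, hypermutable_ids, hgnc_ids)
  list(
    genes = splice,
    retained = retained,
    stage_counts = c(total = n_total, placed = nrow(placed),
                     spliceosomal_placed = nrow(splice),
                     retained = nrow(retained))
  )
}
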