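#' Generate a synthetic gene catalog with annotation tracks and signal
#'
#' Builds `n_genes` synthetic snRNA genes with known annotation ground
#' truth: per-gene cCRE and H3K27ac overlap status (intervals are placed
#' either overlapping the gene body or strictly outside it), hypermutable
#' and HGNC membership, and strand-specific per-tissue signal tracks with
#' controlled covered-base counts. Gene lengths equal the expected mature
#' length of their snRNA type so that coverage fractions are exact by
#' construction.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (catalog data frame), `ccre`, `h3k27ac`
#'   (interval data frames), `hypermutable_ids`, `hgnc_ids`, `tracks`
#'   (list of [signal_track()]), and `truth` (per-gene data frame with
#'   `ccre_true`, `h3k27ac_true`, `hypermutable`, `hgnc`, `retained_true`,
#'   `covered_allreads`, `detectable_true`).
#' @export
simulate_gene_fixture <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  lens <- expected_snrna_lengths()
  types <- rep(names(lens), length.out = n)
  glen <- unname(lens[types])
  genes <- data.frame(
    gene_id = sprintf("SNG%03d", seq_len(n)),
    chrom = paste0("chr", rep(1:4, length.out = n)),
    start = 10000L + (seq_len(n) - 1L) * 5000L,
    strand = rep(c("+", "-"), length.out = n),
    snrna_type = types,
    is_spliceosomal = TRUE,
    is_pseudogene_annotation = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)
  genes$end <- genes$start + glen
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                     "snrna_type", "is_spliceosomal",
                     "is_pseudogene_annotation")]
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in synthetic catalog")

  ccre_true <- stats::runif(n) < 0.4
  h3k_true <- stats::runif(n) < 0.4
  hyper <- genes$gene_id[stats::runif(n) < 0.3]
  hgnc <- genes$gene_id[stats::runif(n) < 0.3]

  mk_track <- function(flag) {
    rows <- lapply(seq_len(n), function(i) {
      if (flag[i]) {
        # interval sharing >= 1 base with the gene body
        data.frame(chrom = genes$chrom[i],
                   start = genes$start[i] + 5L,
                   end = genes$start[i] + 30L)
      } else {
        # interval strictly beyond the half-open gene end
        data.frame(chrom = genes$chrom[i],
                   start = genes$end[i] + 200L,
                   end = genes$end[i] + 260L)
      }
    })
    do.call(rbind, rows)
  }
  ccre <- mk_track(ccre_true)
  h3k27ac <- mk_track(h3k_true)

  # signal: per gene a coverage fraction drawn from fixed bins
  frac_bins <- c(0, 0.3, 0.6, 0.8, 1.0)
  tissues <- c("cortex", "cerebellum")
  covered <- matrix(0L, n, length(tissues),
                    dimnames = list(genes$gene_id, tissues))
  for (t in seq_along(tissues)) {
    fr <- sample(frac_bins, n, replace = TRUE)
    covered[, t] <- as.integer(round(fr * glen))
  }
  tracks <- list()
  for (t in tissues) for (mode in c("all_reads", "unique_reads")) {
    for (s in c("+", "-")) {
      idx <- which(genes$strand == s & covered[, t] > 0)
      runs <- if (length(idx) == 0) {
        data.frame(chrom = character(), start = integer(),
                   end = integer(), score = numeric())
      } else {
        data.frame(chrom = genes$chrom[idx],
                   start = genes$start[idx],
                   end = genes$start[idx] + covered[idx, t],
                   score = round(stats::rlnorm(length(idx), 3, 1), 3),
                   stringsAsFactors = FALSE)
      }
      tracks[[length(tracks) + 1]] <- signal_track(t, mode, s, runs)
    }
  }

  truth <- data.frame(
    gene_id = genes$gene_id,
    ccre_true = ccre_true, h3k27ac_true = h3k_true,
    hypermutable = genes$gene_id %in% hyper,
    hgnc = genes$gene_id %in% hgnc,
    covered_allreads = apply(covered, 1, max),
    stringsAsFactors = FALSE)
  truth$retained_true <- truth$ccre_true | truth$hypermutable | truth$hgnc
  truth$detectable_true <- truth$covered_allreads >= 0.5 * glen

  list(genes = genes, ccre = ccre, h3k27ac = h3k27ac,
       hypermutable_ids = hyper, hgnc_ids = hgnc,
       tracks = tracks, truth = truth)
}

#' Write a gene fixture to disk
#'
#' Emits the gene TSV, cCRE and H3K27ac BED files (0-based half-open),
#' newline-delimited id lists, one bedGraph per (tissue, mode, strand)
#' plus a track manifest, and the truth TSV.
#'
#' @param fix a fixture from [simulate_gene_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_gene_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             ccre = file.path(dir, "ccre.bed"),
             h3k27ac = file.path(dir, "h3k27ac.bed"),
             hypermutable = file.path(dir, "hypermutable.txt"),
             hgnc = file.path(dir, "hgnc.txt"),
             manifest = file.path(dir, "tracks.tsv"),
             truth = file.path(dir, "gene_truth.tsv"))
  utils::write.table(fix$genes, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_bed <- function(df, path)
    utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_bed(fix$ccre, paths["ccre"])
  .write_bed(fix$h3k27ac, paths["h3k27ac"])
  writeLines(fix$hypermutable_ids, paths["hypermutable"])
  writeLines(fix$hgnc_ids, paths["hgnc"])
  man <- do.call(rbind, lapply(fix$tracks, function(t) {
    fn <- sprintf("%s_%s_%s.bedgraph", t$tissue, t$mode,
                  if (t$strand == "+") "plus" else "minus")
    data.frame(tissue = t$tissue, mode = t$mode, strand = t$strand,
               file = fn, stringsAsFactors = FALSE)
  }))
  for (i in seq_along(fix$tracks)) {
    t <- fix$tracks[[i]]
    d <- t$data
    utils::write.table(
      data.frame(d$chrom, d$start, d$end, d$score),
      file.path(dir, man$file[i]),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(man, paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fix$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read signal tracks listed in a manifest
#'
#' @param manifest_path manifest TSV written by [write_gene_fixture()]
#'   (columns `tissue`, `mode`, `strand`, `file`; files resolved relative
#'   to the manifest).
#' @return list of [signal_track()] objects.
#' @export
read_track_manifest <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i)
    signal_track(man$tissue[i], man$mode[i], man$strand[i],
                 read_bedgraph(file.path(base, man$file[i]))))
}
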