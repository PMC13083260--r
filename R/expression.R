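#' Expected mature lengths per snRNA type
#'
#' Expected number of transcribed bases for each spliceosomal snRNA type,
#' used as the denominator of the coverage fraction in the detectability
#' rule.
#'
#' @return named integer vector.
#' @export
expected_snrna_lengths <- function() {
  c(U1 = 164L, U2 = 191L, U4 = 141L, U5 = 116L, U6 = 107L, U7 = 63L,
    U4ATAC = 127L, U6ATAC = 126L, U11 = 134L, U12 = 150L, other = 40L)
}

#' Read a bedGraph file into a run data frame
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open,
#'   no header; `track` lines are skipped).
#' @return data frame with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  b <- utils::read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), score = as.numeric(b[[4]]),
             stringsAsFactors = FALSE)
}

#' Construct a signal track
#'
#' @param tissue tissue label.
#' @param mode `"all_reads"` or `"unique_reads"`.
#' @param strand `"+"` or `"-"`.
#' @param data run data frame (`chrom`, `start`, `end`, `score`), runs
#'   sorted and non-overlapping per chromosome, scores >= 0.
#' @return a `signal_track` list.
#' @export
signal_track <- function(tissue, mode = c("all_reads", "unique_reads"),
                         strand = c("+", "-"), data) {
  mode <- match.arg(mode); strand <- match.arg(strand)
  stopifnot(all(data$score >= 0), all(data$start < data$end))
  structure(list(tissue = tissue, mode = mode, strand = strand, data = data),
            class = "signal_track")
}

#' Summarize per-base small-RNA signal over a gene
#'
#' For each track whose strand matches the gene strand, computes the
#' maximum signal over bases within the gene body and the number of bases
#' with signal strictly greater than zero (capped at the gene length).
#' Tracks on the opposite strand are ignored; when no track matches, a
#' zero summary is returned with a warning.
#'
#' @param gene one-row gene data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param tracks list of [signal_track()] objects.
#' @return data frame with one row per (tissue, mode): `gene_id`, `tissue`,
#'   `mode`, `max_signal`, `covered_bases`.
#' @export
summarize_expression <- function(gene, tracks) {
  matching <- Filter(function(t) t$strand == gene$strand, tracks)
  if (length(matching) == 0) {
    warning("no signal track on strand '", gene$strand, "' for gene ",
            gene$gene_id)
    return(data.frame(gene_id = gene$gene_id, tissue = NA_character_,
                      mode = NA_character_, max_signal = 0,
                      covered_bases = 0L, stringsAsFactors = FALSE))
  }
  glen <- gene$end - gene$start
  rows <- lapply(matching, function(t) {
    d <- t$data[t$data$chrom == gene$chrom, , drop = FALSE]
    ov_start <- pmax(d$start, gene$start)
    ov_end <- pmin(d$end, gene$end)
    w <- pmax(0L, ov_end - ov_start)
    covered <- sum(w[d$score > 0])
    mx <- if (any(w > 0)) max(d$score[w > 0]) else 0
    data.frame(gene_id = gene$gene_id, tissue = t$tissue, mode = t$mode,
               max_signal = mx, covered_bases = as.integer(min(covered, glen)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a whole gene table against a track set
#'
#' @param genes gene data frame.
#' @param tracks list of [signal_track()] objects.
#' @return row-bound per-gene summaries.
#' @export
summarize_expression_all <- function(genes, tracks) {
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    summarize_expression(genes[i, , drop = FALSE], tracks)))
}

#' Detectability rule for an snRNA gene
#'
#' A gene counts as detectable when, in at least one tissue and considering
#' all mapped reads, the number of covered bases reaches at least 50% of
#' the expected length for its snRNA type.
#'
#' @param summary per-gene summary rows from [summarize_expression()];
#'   must include at least one `all_reads` entry.
#' @param snrna_type the gene's snRNA type.
#' @param table expected-length table, default [expected_snrna_lengths()].
#' @param min_fraction coverage fraction threshold (ties pass).
#' @return logical.
#' @export
detectable <- function(summary, snrna_type, table = expected_snrna_lengths(),
                       min_fraction = 0.5) {
  if (!snrna_type %in% names(table))
    stop("unknown snRNA type: ", snrna_type)
  ar <- summary[summary$mode %in% "all_reads", , drop = FALSE]
  if (nrow(ar) == 0) return(FALSE)
  max(ar$covered_bases) >= min_fraction * table[[snrna_type]]
}

#' log10 of a maximum signal, with a sentinel for zero
#'
#' @param max_signal non-negative signal value.
#' @return `log10(max_signal)`; `NA` for zero input (excluded from plots).
#' @export
report_log10 <- function(max_signal) {
  if (any(max_signal < 0)) stop("signal must be non-negative")
  ifelse(max_signal > 0, log10(max_signal), NA_real_)
}

#' Coverage-fraction reporting bin
#'
#' @param fraction covered_bases / expected bases.
#' @return one of `"100%"`, `"75-99%"`, `"50-74%"`, `"<50%"`.
#' @export
coverage_bin <- function(fraction) {
  cut(pmin(fraction, 1), breaks = c(-Inf, 0.5, 0.75, 1 - 1e-9, Inf),
      labels = c("<50%", "50-74%", "75-99%", "100%"), right = FALSE) |>
    as.character()
}
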