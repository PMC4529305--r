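# read trimming/filtering, base-level statistics and in-silico k-mer
# coverage normalization

#' Trimming and normalization parameters
#'
#' One merged rule set with a fixed operation order replaces the chained
#' external trimmers the pipeline emulates: (1) adapter clip at the best
#' suffix/prefix overlap (>= 5 nt, >= 90% identity), (2) removal of up to
#' `trim_ns_right` trailing Ns, (3) quality-trimming of both ends below
#' `qual_trim_threshold`, (4) rejection on mean quality or remaining length.
#'
#' @param adapter adapter to clip (character).
#' @param qual_trim_threshold terminal bases below this Phred are trimmed.
#' @param min_mean_qual reject a mate whose mean quality falls below this.
#' @param min_len reject a mate shorter than this after trimming (nt).
#' @param trim_ns_right maximum trailing Ns removed.
#' @param adapter_min_overlap,adapter_min_identity adapter-clip thresholds.
#' @param norm_k k-mer size for coverage normalization.
#' @param max_cov coverage ceiling for normalization.
#' @return an object of class `trim_params`.
#' @export
trim_params <- function(adapter = DEFAULT_ADAPTER,
                        qual_trim_threshold = 28L,
                        min_mean_qual = 28,
                        min_len = 20L,
                        trim_ns_right = 2L,
                        adapter_min_overlap = 5L,
                        adapter_min_identity = 0.9,
                        norm_k = 25L,
                        max_cov = 30) {
  p <- list(adapter = toupper(adapter),
            qual_trim_threshold = as.integer(qual_trim_threshold),
            min_mean_qual = min_mean_qual,
            min_len = as.integer(min_len),
            trim_ns_right = as.integer(trim_ns_right),
            adapter_min_overlap = as.integer(adapter_min_overlap),
            adapter_min_identity = adapter_min_identity,
            norm_k = as.integer(norm_k),
            max_cov = max_cov)
  if (p$min_len < 1) stopf("min_len must be >= 1")
  if (p$qual_trim_threshold < 0 || p$min_mean_qual < 0)
    stopf("quality thresholds must be non-negative")
  class(p) <- "trim_params"
  p
}

#' Trim read pairs
#'
#' Applies, per mate and in this order: adapter clipping, trailing-N
#' removal, terminal quality trimming, then rejection if mean quality or
#' remaining length falls below threshold. A pair is rejected if either
#' mate is rejected; rejection reasons partition the rejected pairs.
#'
#' @param pairs data.frame with mate1_seq/mate1_qual/mate2_seq/mate2_qual
#'   (as produced by [simulate_reads()]).
#' @param params a [trim_params()].
#' @return list with `pairs` (trimmed surviving pairs) and `rejected`
#'   (data.frame pair_id, reason).
#' @export
trim_read_pairs <- function(pairs, params = trim_params()) {
  need <- c("mate1_seq", "mate1_qual", "mate2_seq", "mate2_qual")
  if (!all(need %in% names(pairs))) stopf("pairs lacks mate columns")
  if (any(nchar(pairs$mate1_seq) != nchar(pairs$mate1_qual)) ||
      any(nchar(pairs$mate2_seq) != nchar(pairs$mate2_qual)))
    stopf("sequence/quality length mismatch")
  t1 <- cpp_trim_mates(pairs$mate1_seq, pairs$mate1_qual, params$adapter,
                       params$qual_trim_threshold, params$min_mean_qual,
                       params$min_len, params$trim_ns_right,
                       params$adapter_min_overlap,
                       params$adapter_min_identity)
  t2 <- cpp_trim_mates(pairs$mate2_seq, pairs$mate2_qual, params$adapter,
                       params$qual_trim_threshold, params$min_mean_qual,
                       params$min_len, params$trim_ns_right,
                       params$adapter_min_overlap,
                       params$adapter_min_identity)
  # mate1's reason wins when both mates fail (fixed partition rule)
  reason <- ifelse(!is.na(t1$reason), t1$reason, t2$reason)
  keep <- is.na(reason)
  out <- pairs[keep, , drop = FALSE]
  out$mate1_seq <- t1$seq[keep]
  out$mate1_qual <- t1$qual[keep]
  out$mate2_seq <- t2$seq[keep]
  out$mate2_qual <- t2$qual[keep]
  rejected <- data.frame(
    pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id[!keep]
              else which(!keep),
    reason = reason[!keep])
  list(pairs = out, rejected = rejected)
}

#' Base-level quality statistics
#'
#' Q20 is computed per base: the percentage of base calls with Phred >= 20
#' (a per-read variant is also returned as `q20_read_pct`). GC excludes Ns
#' from numerator and denominator.
#'
#' @param seqs,quals parallel character vectors (both mates concatenated is
#'   fine).
#' @param n_raw_reads optional raw-read count to report alongside.
#' @return an object of class `qc_stats`: total_raw_reads,
#'   total_clean_reads, total_nucleotides, q20_pct, q20_read_pct, gc_pct.
#' @export
base_stats <- function(seqs, quals, n_raw_reads = length(seqs)) {
  if (length(seqs) == 0) {
    warnf("empty read stream; statistics are all zero")
    out <- list(total_raw_reads = n_raw_reads, total_clean_reads = 0L,
                total_nucleotides = 0, q20_pct = 0, q20_read_pct = 0,
                gc_pct = 0)
    class(out) <- "qc_stats"
    return(out)
  }
  stopifnot(length(seqs) == length(quals))
  total <- sum(nchar(seqs))
  below <- count_below_phred(quals, 20L)
  gc <- nchar(gsub("[^GCgc]", "", seqs))
  acgt <- nchar(gsub("[^ACGTacgt]", "", seqs))
  out <- list(total_raw_reads = n_raw_reads,
              total_clean_reads = length(seqs),
              total_nucleotides = total,
              q20_pct = 100 * (total - sum(below)) / total,
              q20_read_pct = 100 * mean(below == 0),
              gc_pct = if (sum(acgt) > 0) 100 * sum(gc) / sum(acgt) else 0)
  class(out) <- "qc_stats"
  out
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf(
    "Read QC: %s raw, %s clean, %s nt, Q20 %.1f%%, GC %.1f%%\n",
    format(x$total_raw_reads, big.mark = ","),
    format(x$total_clean_reads, big.mark = ","),
    format(x$total_nucleotides, big.mark = ","),
    x$q20_pct, x$gc_pct))
  invisible(x)
}

#' In-silico k-mer coverage normalization
#'
#' Single streaming pass: a pair is accepted iff the median multiplicity
#' (in the table accumulated so far, canonical k-mers) of at least one mate
#' is at most `max_cov`; accepted pairs then update the table. The output
#' is a subsequence of the input (order-dependent by design, matching
#' digital normalization semantics for a non-stranded library).
#'
#' @param pairs data.frame with mate1_seq/mate2_seq.
#' @param params a [trim_params()] (uses `norm_k`, `max_cov`).
#' @return the retained subset of `pairs`.
#' @export
normalize_by_kmer_coverage <- function(pairs, params = trim_params()) {
  if (nrow(pairs) == 0) return(pairs)
  if (params$norm_k > max(nchar(c(pairs$mate1_seq, pairs$mate2_seq))))
    stopf("norm_k exceeds the longest read")
  keep <- cpp_normalize_pairs(pairs$mate1_seq, pairs$mate2_seq,
                              params$norm_k, params$max_cov)
  pairs[keep, , drop = FALSE]
}

#' Write QC statistics
#'
#' @param stats a `qc_stats` object.
#' @param path_tsv,path_json output paths (either may be NULL).
#' @return invisibly, the stats.
#' @export
write_qc_stats <- function(stats, path_tsv = NULL, path_json = NULL) {
  df <- data.frame(metric = names(unclass(stats)),
                   value = unlist(unclass(stats)), row.names = NULL)
  if (!is.null(path_tsv))
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(unclass(stats), path_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(stats)
}
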