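# read-to-transcript assignment, TPM/FPKM estimation (simplified EM for
# multi-mappers), Unigene roll-up and library complexity

#' Map read pairs to a transcriptome
#'
#' Seed-and-extend matching without indels: 31-mer seeds (up to three
#' non-overlapping offsets per mate, both orientations since the library
#' is non-stranded) locate candidate placements, which are verified by
#' full-mate comparison allowing at most `max_mismatch` substitutions.
#' A pair is concordant when its mates land on one transcript, inward,
#' with a fragment no longer than `max_fragment`; an inward pair whose
#' fragment exceeds the ceiling is reported with `concordant = FALSE`.
#' All equally-best placements (minimal total mismatches) are reported.
#'
#' @param pairs data.frame with pair_id, mate1_seq, mate2_seq.
#' @param transcripts data.frame with transcript_id, sequence.
#' @param seed_len seed k-mer length (nt).
#' @param max_mismatch per-mate mismatch allowance.
#' @param max_fragment maximum fragment length (nt) for concordance.
#' @return data.frame of alignment records: pair_id, transcript_id,
#'   fragment_start, fragment_end (0-based half-open transcript
#'   coordinates), orientation of mate1 (`F`/`R`), concordant, mismatches.
#' @export
map_reads <- function(pairs, transcripts, seed_len = 31L,
                      max_mismatch = 2L, max_fragment = 800L) {
  empty <- data.frame(pair_id = character(0), transcript_id = character(0),
                      fragment_start = integer(0), fragment_end = integer(0),
                      orientation = character(0), concordant = logical(0),
                      mismatches = integer(0))
  if (nrow(pairs) == 0 || nrow(transcripts) == 0) return(empty)
  txseq <- transcripts$sequence
  txlen <- nchar(txseq)
  index <- data.table::rbindlist(lapply(seq_along(txseq), function(i) {
    if (txlen[i] < seed_len) return(NULL)
    pos <- 0:(txlen[i] - seed_len)
    data.table::data.table(
      kmer = substring(txseq[i], pos + 1L, pos + seed_len),
      tx = i, pos = pos)
  }))
  if (nrow(index) == 0) return(empty)
  data.table::setkey(index, kmer)

  n <- nrow(pairs)
  mate_seq <- c(pairs$mate1_seq, pairs$mate2_seq)
  qid <- rep(seq_len(n), 2L)
  mate <- rep(1:2, each = n)
  # both orientations of every mate
  oriented <- c(mate_seq, revcomp(mate_seq))
  orient <- rep(c("F", "R"), each = 2L * n)
  qid <- c(qid, qid)
  mate <- c(mate, mate)
  qlen <- nchar(oriented)
  offs <- (0:2) * seed_len
  queries <- data.table::rbindlist(lapply(offs, function(o) {
    ok <- qlen >= o + seed_len
    data.table::data.table(
      q = which(ok), soff = o,
      kmer = substring(oriented[ok], o + 1L, o + seed_len))
  }))
  hits <- index[queries, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(empty)
  hits[, start := pos - soff]
  cand <- unique(hits[, list(q, tx, start)])
  cand <- cand[start >= 0 & start + qlen[q] <= txlen[tx]]
  if (nrow(cand) == 0) return(empty)
  cand[, mm := cpp_mismatch_at(txseq, tx, start, oriented[q])]
  cand <- cand[!is.na(mm) & mm <= max_mismatch]
  if (nrow(cand) == 0) return(empty)
  cand[, `:=`(qid = qid[q], mate = mate[q], orient = orient[q],
              end = start + qlen[q])]

  m1 <- cand[mate == 1L]
  m2 <- cand[mate == 2L]
  # inward: the forward mate lies left of the reverse mate's end
  j1 <- merge(m1[orient == "F"], m2[orient == "R"],
              by = c("qid", "tx"), allow.cartesian = TRUE,
              suffixes = c("_f", "_r"))
  j2 <- merge(m2[orient == "F"], m1[orient == "R"],
              by = c("qid", "tx"), allow.cartesian = TRUE,
              suffixes = c("_f", "_r"))
  j1[, orientation := "F"]
  j2[, orientation := "R"]
  frags <- data.table::rbindlist(list(j1, j2), use.names = TRUE)
  if (nrow(frags) == 0) return(empty)
  frags <- frags[start_f <= start_r & end_f <= end_r]
  frags[, `:=`(fragment_start = start_f, fragment_end = end_r,
               mismatches = mm_f + mm_r)]
  frags <- frags[fragment_end > fragment_start]
  if (nrow(frags) == 0) return(empty)
  frags[, concordant := fragment_end - fragment_start <= max_fragment]
  frags <- unique(frags[, list(qid, tx, fragment_start, fragment_end,
                               orientation, concordant, mismatches)])
  frags[, best := min(mismatches), by = "qid"]
  frags <- frags[mismatches == best]
  out <- data.frame(pair_id = pairs$pair_id[frags$qid],
                    transcript_id = transcripts$transcript_id[frags$tx],
                    fragment_start = frags$fragment_start,
                    fragment_end = frags$fragment_end,
                    orientation = frags$orientation,
                    concordant = frags$concordant,
                    mismatches = frags$mismatches)
  out[order(out$pair_id, out$transcript_id, out$fragment_start), ,
      drop = FALSE]
}

#' Estimate transcript abundance (TPM / FPKM)
#'
#' `est_count` is the (possibly fractional) number of concordant pairs
#' assigned to each transcript; `effective_length = max(length -
#' fragment_mean + 1, 1)`. Modes: `unique` drops multi-mapped pairs,
#' `uniform` splits each 1/n, `em` iterates fractional assignment
#' proportional to `theta_t / effective_length_t` (a deliberately
#' simplified resolver: no fragment-length likelihood or quality model)
#' until `max |delta theta| / sum(theta) < 1e-8` or 1000 iterations.
#' `tpm = 1e6 (c/el) / sum(c/el)`; `fpkm = 1e9 c / (el N)` with N the
#' total concordant pairs.
#'
#' @param alignments output of [map_reads()] (concordant records used).
#' @param transcripts data.frame with transcript_id, sequence (or length).
#' @param mode assignment mode for multi-mapped pairs.
#' @param fragment_mean mean fragment length used for effective length.
#' @return data.frame: transcript_id, length, effective_length, est_count,
#'   tpm, fpkm (every transcript present; attribute `n_mapped_pairs`).
#' @export
estimate_abundance <- function(alignments, transcripts,
                               mode = c("em", "unique", "uniform"),
                               fragment_mean = 275) {
  mode <- match.arg(mode)
  len <- if ("length" %in% names(transcripts)) transcripts$length
         else nchar(transcripts$sequence)
  el <- pmax(len - fragment_mean + 1, 1)
  out <- data.frame(transcript_id = transcripts$transcript_id,
                    length = len, effective_length = el,
                    est_count = 0, tpm = 0, fpkm = 0)
  aln <- alignments[alignments$concordant, , drop = FALSE]
  aln <- unique(data.frame(pair_id = aln$pair_id,
                           tx = match(aln$transcript_id,
                                      transcripts$transcript_id)))
  if (any(is.na(aln$tx))) stopf("alignment to unknown transcript")
  if (nrow(aln) == 0) {
    warnf("no concordant pairs; returning all-zero abundances")
    attr(out, "n_mapped_pairs") <- 0L
    return(out)
  }
  nplace <- stats::ave(aln$tx, aln$pair_id, FUN = length)
  n_pairs <- length(unique(aln$pair_id))
  counts <- numeric(nrow(transcripts))
  if (mode == "unique") {
    uni <- aln[nplace == 1L, , drop = FALSE]
    tb <- table(uni$tx)
    counts[as.integer(names(tb))] <- as.numeric(tb)
  } else if (mode == "uniform") {
    w <- 1 / nplace
    agg <- rowsum(w, aln$tx)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  } else {
    pid <- match(aln$pair_id, unique(aln$pair_id))
    utx <- sort(unique(aln$tx))
    txc <- match(aln$tx, utx)   # compact transcript index
    theta <- numeric(nrow(transcripts))
    theta[utx] <- rowsum(1 / nplace, txc)[, 1]
    for (it in seq_len(1000L)) {
      w <- theta[aln$tx] / el[aln$tx]
      denom <- rowsum(w, pid)[pid, 1]   # pid is compact, rows sorted
      w <- ifelse(denom > 0, w / denom, 1 / nplace)
      newtheta <- numeric(length(theta))
      newtheta[utx] <- rowsum(w, txc)[, 1]
      delta <- max(abs(newtheta - theta)) / sum(newtheta)
      theta <- newtheta
      if (delta < 1e-8) break
    }
    counts <- theta
  }
  out$est_count <- counts
  rate <- counts / el
  if (sum(rate) > 0) out$tpm <- 1e6 * rate / sum(rate)
  out$fpkm <- 1e9 * counts / (el * n_pairs)
  attr(out, "n_mapped_pairs") <- n_pairs
  out
}

#' Roll transcript abundances up to Unigenes
#'
#' @param abundance output of [estimate_abundance()].
#' @param grouping data.frame with transcript_id, unigene_id covering every
#'   transcript in `abundance`.
#' @return data.frame: unigene_id, est_count, tpm, fpkm.
#' @export
unigene_abundance <- function(abundance, grouping) {
  uid <- grouping$unigene_id[match(abundance$transcript_id,
                                   grouping$transcript_id)]
  if (any(is.na(uid)))
    stopf("transcript(s) missing from grouping: %s",
          paste(head(abundance$transcript_id[is.na(uid)], 3),
                collapse = ", "))
  agg <- rowsum(abundance[, c("est_count", "tpm", "fpkm")], uid)
  data.frame(unigene_id = rownames(agg), agg, row.names = NULL)
}

#' Library complexity from mapped pairs
#'
#' On a fixed-seed random sample of concordant, uniquely mapped pairs:
#' unpaired (per-read) complexity is the number of unique mate start
#' sites, `(transcript, orientation, start)`, divided by the number of
#' mapped reads (2 per pair); paired complexity is the number of unique
#' fragment `(transcript, start, end)` triples divided by the number of
#' pairs. Low values indicate PCR "jackpot" duplication.
#'
#' @param alignments output of [map_reads()].
#' @param sample_size number of pairs to sample.
#' @param seed RNG seed for the sample.
#' @param multi `"exclude"` drops multi-mapped pairs (default, matching
#'   unique-hits mapping); `"best"` keeps one deterministic placement.
#' @return list of class `complexity_result`: n_sampled_pairs,
#'   n_mapped_pairs, unpaired_complexity, paired_complexity.
#' @export
library_complexity <- function(alignments, sample_size = 2.5e6, seed = 1L,
                               multi = c("exclude", "best")) {
  multi <- match.arg(multi)
  if (sample_size < 1) stopf("sample_size must be >= 1")
  aln <- alignments[alignments$concordant, , drop = FALSE]
  if (nrow(aln) > 0) {
    aln <- aln[order(aln$pair_id, aln$transcript_id, aln$fragment_start,
                     aln$fragment_end), , drop = FALSE]
    nplace <- stats::ave(seq_len(nrow(aln)), aln$pair_id, FUN = length)
    if (multi == "exclude") {
      aln <- aln[nplace == 1L, , drop = FALSE]
    } else {
      aln <- aln[!duplicated(aln$pair_id), , drop = FALSE]
    }
  }
  if (nrow(aln) == 0) {
    warnf("no usable concordant pairs; complexity undefined")
    out <- list(n_sampled_pairs = 0L, n_mapped_pairs = 0L,
                unpaired_complexity = NA_real_,
                paired_complexity = NA_real_, undefined = TRUE)
    class(out) <- "complexity_result"
    return(out)
  }
  set.seed(seed)
  take <- min(nrow(aln), sample_size)
  aln <- aln[sample.int(nrow(aln), take), , drop = FALSE]
  # 5' start site of each mate: fragment_start for the forward mate,
  # fragment_end for the reverse mate
  starts <- c(paste(aln$transcript_id, "F", aln$fragment_start),
              paste(aln$transcript_id, "R", aln$fragment_end))
  fragments <- paste(aln$transcript_id, aln$fragment_start,
                     aln$fragment_end)
  out <- list(n_sampled_pairs = take,
              n_mapped_pairs = take,
              unpaired_complexity = length(unique(starts)) / (2 * take),
              paired_complexity = length(unique(fragments)) / take,
              undefined = FALSE)
  class(out) <- "complexity_result"
  out
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf(
    "Library complexity (%d pairs): unpaired %.3f, paired %.3f\n",
    x$n_sampled_pairs, x$unpaired_complexity, x$paired_complexity))
  invisible(x)
}

#' Write abundance estimates as TSV
#'
#' Columns mirror the conventional estimator output: transcript_id,
#' length, effective_length, expected_count, TPM, FPKM.
#'
#' @param abundance output of [estimate_abundance()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_abundance <- function(abundance, path) {
  df <- data.frame(transcript_id = abundance$transcript_id,
                   length = abundance$length,
                   effective_length = abundance$effective_length,
                   expected_count = abundance$est_count,
                   TPM = abundance$tpm, FPKM = abundance$fpkm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
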