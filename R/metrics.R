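# assembly statistics: N50, ORF detection, Unigene grouping,
# cluster/singleton classification

#' N50 of a set of lengths
#'
#' The largest length L such that the summed length of all sequences of
#' length >= L reaches at least half the total summed length.
#'
#' @param lengths positive integer vector.
#' @return a single length, always an element of `lengths`.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stopf("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) stopf("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

# enumerate ORF candidates in one translated frame: ATG-to-stop,
# edge-to-stop (5'-partial) and ATG-to-edge (3'-partial)
frame_candidates <- function(prot, allow_edge = TRUE) {
  n <- nchar(prot)
  if (n == 0) return(NULL)
  chars <- strsplit(prot, "", fixed = TRUE)[[1]]
  stars <- which(chars == "*")
  ms <- which(chars == "M")
  out <- list()
  for (i in seq_len(length(stars) + 1L)) {
    s0 <- if (i == 1L) 1L else stars[i - 1L] + 1L
    stop_here <- i <= length(stars)
    aa_end <- if (stop_here) stars[i] - 1L else n   # last coding aa
    if (s0 > aa_end) next
    # edge-to-stop: 5'-partial. Only accepted when translation starts at
    # the transcript edge itself (frame 0); when the edge codon is ATG the
    # complete ATG-to-stop candidate is identical and preferred
    if (allow_edge && s0 == 1L && stop_here && chars[1] != "M") {
      out[[length(out) + 1L]] <- list(aa_start = s0, aa_end = aa_end,
                                      stop = TRUE, p5 = TRUE, p3 = FALSE)
    }
    m <- ms[ms >= s0 & ms <= aa_end]
    if (length(m) > 0) {
      out[[length(out) + 1L]] <- list(aa_start = m[1], aa_end = aa_end,
                                      stop = stop_here, p5 = FALSE,
                                      p3 = !stop_here)
    }
  }
  out
}

#' Find the best open reading frame in a transcript
#'
#' Scans all six frames (the library is non-stranded). Candidates are
#' ATG-to-stop, transcript-edge-to-stop (5'-partial) and ATG-to-edge
#' (3'-partial); the longest candidate with at least `min_codons` codons
#' (stop excluded) wins. Ties prefer the plus strand, then the lowest
#' frame, then the smallest start. Coordinates are 0-based half-open on
#' the reported strand and include the stop codon when present.
#'
#' @param sequence a nucleotide string.
#' @param transcript_id identifier carried into the result.
#' @param min_codons minimum ORF length in codons (default 100, the
#'   convention of common ORF extraction tools).
#' @return one-row data.frame (transcript_id, strand, frame, start, end,
#'   n_codons, protein, five_prime_partial, three_prime_partial) or NULL.
#' @export
find_best_orf <- function(sequence, transcript_id = NA_character_,
                          min_codons = 100L) {
  res <- find_orfs(data.frame(transcript_id = transcript_id,
                              sequence = sequence), min_codons)
  if (nrow(res) == 0) NULL else res
}

# translate every transcript in all six frames in one batched call per
# frame (much faster than per-transcript DNAString construction)
six_frame_matrix <- function(sequences) {
  dna <- Biostrings::DNAStringSet(sequences)
  out <- matrix("", nrow = length(sequences), ncol = 6,
                dimnames = list(NULL, c("F0", "F1", "F2",
                                        "R0", "R1", "R2")))
  col <- 1L
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") dna else Biostrings::reverseComplement(dna)
    w <- Biostrings::width(ss)
    for (f in 0:2) {
      len3 <- pmax(((w - f) %/% 3L) * 3L, 0L)
      sub <- Biostrings::subseq(ss, start = pmin(f + 1L, w + 1L),
                                width = len3)
      out[, col] <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X",
                              no.init.codon = TRUE)))
      col <- col + 1L
    }
  }
  out
}

#' Best ORF for every transcript
#'
#' @param transcripts data.frame with transcript_id and sequence.
#' @param min_codons see [find_best_orf()].
#' @return data.frame of ORF records (transcripts without a qualifying ORF
#'   are absent).
#' @export
find_orfs <- function(transcripts, min_codons = 100L) {
  empty <- data.frame(transcript_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), n_codons = integer(0),
                      protein = character(0),
                      five_prime_partial = logical(0),
                      three_prime_partial = logical(0))
  if (nrow(transcripts) == 0) return(empty)
  prots <- six_frame_matrix(transcripts$sequence)
  frames <- data.frame(strand = rep(c("+", "-"), each = 3),
                       frame = rep(0:2, 2))
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    best <- NULL
    for (fr in seq_len(6)) {
      f <- frames$frame[fr]
      for (cand in frame_candidates(prots[i, fr],
                                    allow_edge = (f == 0L))) {
        n_codons <- cand$aa_end - cand$aa_start + 1L
        if (n_codons < min_codons) next
        start <- f + 3L * (cand$aa_start - 1L)
        # ties resolved by scan order: + before -, frame 0..2; for equal
        # strand/frame keep the smaller start
        if (!is.null(best) &&
            (n_codons < best$n_codons ||
             (n_codons == best$n_codons &&
              !(fr == best$fr && start < best$start)))) next
        best <- list(fr = fr, start = start,
                     end = f + 3L * cand$aa_end +
                       if (cand$stop) 3L else 0L,
                     n_codons = n_codons,
                     protein = substr(prots[i, fr], cand$aa_start,
                                      cand$aa_end),
                     p5 = cand$p5, p3 = cand$p3)
      }
    }
    if (!is.null(best)) {
      rows[[i]] <- data.frame(
        transcript_id = transcripts$transcript_id[i],
        strand = frames$strand[best$fr], frame = frames$frame[best$fr],
        start = best$start, end = best$end, n_codons = best$n_codons,
        protein = best$protein, five_prime_partial = best$p5,
        three_prime_partial = best$p3)
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group transcripts into Unigenes
#'
#' The grouping key is an explicit `unigene_id` column when present,
#' otherwise the identifier prefix before the final `_seq<k>` suffix
#' (the way assembler-style hierarchical IDs encode the locus).
#'
#' @param transcripts data.frame with transcript_id (and optionally
#'   unigene_id).
#' @param coding_ids transcript IDs carrying an ORF (from [find_orfs()]).
#' @return data.frame: unigene_id, n_isoforms, n_coding_isoforms, coding,
#'   members (comma-joined transcript IDs), ordered by unigene_id.
#' @export
group_unigenes <- function(transcripts, coding_ids = character(0)) {
  if (nrow(transcripts) == 0)
    return(data.frame(unigene_id = character(0), n_isoforms = integer(0),
                      n_coding_isoforms = integer(0), coding = logical(0),
                      members = character(0)))
  if ("unigene_id" %in% names(transcripts)) {
    uid <- transcripts$unigene_id
  } else {
    uid <- sub("_seq\\d+$", "", transcripts$transcript_id)
    bad <- uid == transcripts$transcript_id
    if (any(bad))
      stopf("cannot infer Unigene for transcript ID(s): %s",
            paste(head(transcripts$transcript_id[bad], 3), collapse = ", "))
  }
  coding <- transcripts$transcript_id %in% coding_ids
  ord <- order(uid, transcripts$transcript_id)
  uid <- uid[ord]
  tid <- transcripts$transcript_id[ord]
  coding <- coding[ord]
  dt <- data.table::data.table(unigene_id = uid, transcript_id = tid,
                               coding = coding)
  res <- dt[, list(n_isoforms = .N,
                   n_coding_isoforms = sum(coding),
                   members = paste(transcript_id, collapse = ",")),
            by = "unigene_id"]
  res <- as.data.frame(res[order(res$unigene_id)])
  res$coding <- res$n_coding_isoforms >= 1L
  res[, c("unigene_id", "n_isoforms", "n_coding_isoforms", "coding",
          "members")]
}

#' Cluster / singleton classification of coding Unigenes
#'
#' A cluster is a Unigene with two or more protein-coding isoforms, a
#' singleton has exactly one; non-coding Unigenes count in neither.
#'
#' @param unigenes output of [group_unigenes()].
#' @return list with n_clusters and n_singletons.
#' @export
classify_clusters <- function(unigenes) {
  list(n_clusters = sum(unigenes$n_coding_isoforms >= 2L),
       n_singletons = sum(unigenes$n_coding_isoforms == 1L))
}

#' Assembly-level summary statistics
#'
#' Computes the full transcriptome report: transcript counts with/without
#' ORFs, mean length, N50, Unigene totals, cluster/singleton breakdown and
#' mean isoforms per coding Unigene.
#'
#' @param transcripts data.frame with transcript_id and sequence.
#' @param orfs output of [find_orfs()].
#' @param unigenes output of [group_unigenes()].
#' @return an object of class `assembly_stats` (a named list).
#' @export
assembly_stats <- function(transcripts, orfs, unigenes) {
  n_tx <- nrow(transcripts)
  n_with <- length(unique(orfs$transcript_id))
  n_uni_with <- sum(unigenes$coding)
  cl <- classify_clusters(unigenes)
  out <- list(
    n_transcripts = n_tx,
    mean_length = if (n_tx > 0) mean(nchar(transcripts$sequence)) else 0,
    n50 = if (n_tx > 0) n50(nchar(transcripts$sequence)) else 0L,
    n_transcripts_with_orf = n_with,
    n_transcripts_without_orf = n_tx - n_with,
    n_unigenes = nrow(unigenes),
    n_unigenes_with_orf = n_uni_with,
    n_unigenes_without_orf = nrow(unigenes) - n_uni_with,
    n_clusters = cl$n_clusters,
    n_singletons = cl$n_singletons,
    mean_isoforms_per_coding_unigene =
      if (n_uni_with > 0) n_with / n_uni_with else 0,
    no_coding_unigenes = n_uni_with == 0)
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Assembly: %d transcripts (mean %.0f nt, N50 %d)\n",
    "  with ORF %d / without %d; %d Unigenes (%d coding, %d non-coding)\n",
    "  clusters %d, singletons %d; %.1f isoforms per coding Unigene\n"),
    x$n_transcripts, x$mean_length, x$n50, x$n_transcripts_with_orf,
    x$n_transcripts_without_orf, x$n_unigenes, x$n_unigenes_with_orf,
    x$n_unigenes_without_orf, x$n_clusters, x$n_singletons,
    x$mean_isoforms_per_coding_unigene))
  invisible(x)
}
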