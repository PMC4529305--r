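# consensus siRNA design: ORF-restricted isoform-conserved 19-mer
# enumeration, pluggable rule-based scoring with >=2-of-3 agreement, and
# off-target screening with the >=18-of-19 / >=16-contiguous discard rules

#' siRNA design parameters
#'
#' @param k siRNA length (nt).
#' @param min_agree number of scorer top lists a candidate must appear in.
#' @param top_n recommendations kept per scorer.
#' @param ham_discard discard when an off-target window matches the
#'   candidate in at least this many of its `k` positions.
#' @param contig_discard discard when a contiguous stretch of at least
#'   this many candidate nucleotides occurs exactly in an off-target.
#' @param search_both_orientations screen the candidate and its reverse
#'   complement against transcript sense strands.
#' @return an object of class `design_params`.
#' @export
design_params <- function(k = 19L, min_agree = 2L, top_n = 10L,
                          ham_discard = 18L, contig_discard = 16L,
                          search_both_orientations = TRUE) {
  p <- list(k = as.integer(k), min_agree = as.integer(min_agree),
            top_n = as.integer(top_n), ham_discard = as.integer(ham_discard),
            contig_discard = as.integer(contig_discard),
            search_both_orientations = isTRUE(search_both_orientations))
  if (p$ham_discard > p$k || p$contig_discard > p$k)
    stopf("discard thresholds cannot exceed k")
  class(p) <- "design_params"
  p
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Enumerate isoform-conserved ORF candidates
#'
#' Every `k`-window of the canonical ORF that occurs verbatim (sense
#' strand) in all isoforms of the target gene, with per-isoform first
#' occurrence positions, ordered by canonical offset.
#'
#' @param isoform_seqs named character vector of the gene's isoform
#'   sequences; the first element (or `canonical`) is the canonical
#'   isoform carrying the ORF.
#' @param orf_span integer length-2: ORF start and end on the canonical
#'   isoform (0-based half-open).
#' @param params a [design_params()].
#' @param canonical name of the canonical isoform.
#' @return data.frame: sequence, canonical_offset, in_orf, plus one
#'   `pos_<isoform>` column per isoform (0-based first occurrence).
#' @export
enumerate_candidates <- function(isoform_seqs, orf_span,
                                 params = design_params(),
                                 canonical = names(isoform_seqs)[1]) {
  stopifnot(length(isoform_seqs) >= 1)
  k <- params$k
  cano <- isoform_seqs[[canonical]]
  orf_len <- orf_span[2] - orf_span[1]
  empty <- data.frame(sequence = character(0),
                      canonical_offset = integer(0), in_orf = logical(0))
  if (orf_len < k) {
    warnf("ORF (%d nt) shorter than k = %d; no candidates", orf_len, k)
    return(empty)
  }
  offs <- orf_span[1]:(orf_span[2] - k)
  windows <- substring(cano, offs + 1L, offs + k)
  pos <- vapply(isoform_seqs, function(s) {
    p <- vapply(windows, function(w) regexpr(w, s, fixed = TRUE)[[1]], 0L)
    as.integer(p) - 1L
  }, integer(length(windows)))
  pos <- matrix(pos, nrow = length(windows),
                dimnames = list(NULL, names(isoform_seqs)))
  keep <- rowSums(pos < 0) == 0
  out <- data.frame(sequence = unname(windows[keep]),
                    canonical_offset = offs[keep],
                    in_orf = rep(TRUE, sum(keep)), row.names = NULL)
  for (nm in colnames(pos)) out[[paste0("pos_", nm)]] <- pos[keep, nm]
  out
}

# --- built-in rule-based scorers (documented stand-ins for external ----
# --- design services; the consensus logic, not the scoring models,  ----
# --- is the procedure under test)                                   ----

#' Built-in siRNA scorers
#'
#' Three documented rule-based scorers. `score_gc` prefers 30-52% GC
#' (score 1 minus the distance from the 41% band midpoint, with an extra
#' penalty outside the band). `score_asymmetry` favours a
#' thermodynamically unstable 3' sense end: the difference in
#' nearest-neighbor stacking free energy (Xia-Turner RNA parameters)
#' between the two terminal stacks of each end, positive when the 3' end
#' is less stable. `score_composition` penalizes single-base runs of
#' four or more and long self-complementary stretches.
#'
#' @param seqs character vector of candidate sequences.
#' @return numeric scores (higher is better).
#' @export
score_gc <- function(seqs) {
  gc <- nchar(gsub("[^GC]", "", seqs)) / nchar(seqs)
  out_dist <- pmax(0, 0.30 - gc, gc - 0.52)
  1 - abs(gc - 0.41) - 5 * out_dist
}

# RNA nearest-neighbor stack dG37 (kcal/mol), Watson-Crick pairs,
# collapsed to DNA letters; value(XY) = value(revcomp(XY))
NN_DG <- c(AA = -0.93, AT = -1.10, TA = -1.33, CT = -2.08, CA = -2.11,
           GT = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42,
           TT = -0.93, AG = -2.08, TG = -2.11, AC = -2.24, TC = -2.35,
           CC = -3.26)

#' @rdname score_gc
#' @export
score_asymmetry <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    d5 <- NN_DG[[substr(s, 1, 2)]] + NN_DG[[substr(s, 2, 3)]]
    d3 <- NN_DG[[substr(s, n - 2, n - 1)]] + NN_DG[[substr(s, n - 1, n)]]
    # stability(5') - stability(3'): positive when the 3' sense end is
    # the less stable duplex end (favoured guide-strand loading)
    d3 - d5
  }, 0)
}

#' @rdname score_gc
#' @export
score_composition <- function(seqs) {
  run_pen <- vapply(seqs, function(s) {
    runs <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    sum(pmax(runs$lengths - 3L, 0L))
  }, 0)
  # self-complementarity: longest substring whose reverse complement
  # also occurs in the candidate
  sc <- cpp_self_complement(seqs)
  unname(-(run_pen + pmax(sc - 7L, 0L)))
}

default_scorers <- function() {
  list(gc = score_gc, asymmetry = score_asymmetry,
       composition = score_composition)
}

#' Score candidates with a panel of scorers
#'
#' @param candidates output of [enumerate_candidates()].
#' @param scorers named list of functions mapping a character vector of
#'   sequences to numeric scores; defaults to the three built-ins.
#' @param params a [design_params()] (uses `top_n`).
#' @return named list of per-scorer data.frames (sequence, score, rank),
#'   each truncated to `top_n`, ties broken by sequence.
#' @export
score_candidates <- function(candidates, scorers = default_scorers(),
                             params = design_params()) {
  if (length(scorers) == 0) stopf("at least one scorer is required")
  if (!all(vapply(scorers, is.function, TRUE)))
    stopf("unknown scorer: scorers must be functions")
  lapply(scorers, function(f) {
    sc <- f(candidates$sequence)
    ord <- order(-sc, candidates$sequence)
    top <- head(ord, params$top_n)
    data.frame(sequence = candidates$sequence[top], score = sc[top],
               rank = seq_along(top), row.names = NULL)
  })
}

#' Consensus selection across scorer lists
#'
#' A candidate is kept iff it appears in at least `min_agree` of the
#' per-scorer top lists; kept candidates are ordered by (number of lists,
#' best rank, sequence).
#'
#' @param scored output of [score_candidates()].
#' @param params a [design_params()].
#' @return data.frame: sequence, n_lists, best_rank.
#' @export
consensus_select <- function(scored, params = design_params()) {
  long <- do.call(rbind, lapply(scored, function(d)
    d[, c("sequence", "rank")]))
  if (is.null(long) || nrow(long) == 0)
    return(data.frame(sequence = character(0), n_lists = integer(0),
                      best_rank = integer(0)))
  agg <- aggregate(rank ~ sequence, long,
                   function(r) c(n = length(r), best = min(r)))
  out <- data.frame(sequence = agg$sequence,
                    n_lists = agg$rank[, "n"],
                    best_rank = agg$rank[, "best"])
  out <- out[out$n_lists >= params$min_agree, , drop = FALSE]
  out <- out[order(-out$n_lists, out$best_rank, out$sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an off-target index over a transcriptome
#'
#' Exact-match postings of every `contig_discard`-mer of every transcript
#' (sense strand), plus two seed tables of lengths floor(k/2) and
#' ceil(k/2) supporting pigeonhole Hamming search at one allowed
#' mismatch.
#'
#' @param transcripts data.frame with transcript_id, sequence.
#' @param params a [design_params()].
#' @return an object of class `offtarget_index`.
#' @export
build_offtarget_index <- function(transcripts, params = design_params()) {
  if (nrow(transcripts) == 0) stopf("transcriptome is empty")
  mk <- function(len) {
    dt <- data.table::rbindlist(lapply(seq_len(nrow(transcripts)),
                                       function(i) {
      km <- all_kmers(transcripts$sequence[i], len)
      if (length(km) == 0) return(NULL)
      data.table::data.table(kmer = km, tx = i,
                             pos = seq_along(km) - 1L)
    }))
    if (nrow(dt) > 0) data.table::setkey(dt, kmer)
    dt
  }
  half <- c(floor(params$k / 2), ceiling(params$k / 2))
  idx <- list(contig = mk(params$contig_discard),
              seed_a = mk(half[1]),
              seed_b = if (half[2] != half[1]) mk(half[2]) else NULL,
              half = half,
              transcripts = transcripts, params = params)
  class(idx) <- "offtarget_index"
  idx
}

#' Off-target screen for one candidate
#'
#' DISCARD iff (a) some window of a non-target transcript matches the
#' candidate (or, by default, its reverse complement) in at least
#' `ham_discard` of `k` positions, or (b) a contiguous substring of the
#' candidate of length at least `contig_discard` occurs exactly in a
#' non-target transcript. Hits to the target Unigene's own isoforms are
#' excluded. All triggering hits are reported.
#'
#' @param candidate a `k`-nt sequence.
#' @param index an [build_offtarget_index()] result.
#' @param target_members transcript IDs belonging to the target Unigene.
#' @param params a [design_params()] (defaults to the index's).
#' @return list: verdict (`"pass"`/`"discard"`), hits (data.frame:
#'   transcript_id, offset, orientation, match_type, matched).
#' @export
offtarget_screen <- function(candidate, index, target_members,
                             params = index$params) {
  k <- params$k
  if (nchar(candidate) != k)
    stopf("candidate length %d != k = %d", nchar(candidate), k)
  txs <- index$transcripts
  txlen <- nchar(txs$sequence)
  member_idx <- which(txs$transcript_id %in% target_members)
  orients <- if (params$search_both_orientations) c("F", "R") else "F"
  hits <- list()
  for (o in orients) {
    q <- if (o == "F") candidate else revcomp(candidate)
    # rule (b): exact contiguous stretch >= contig_discard
    for (km in unique(all_kmers(q, params$contig_discard))) {
      h <- index$contig[list(km), nomatch = NULL]
      h <- h[!(tx %in% member_idx)]
      if (nrow(h) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = txs$transcript_id[h$tx], offset = h$pos,
          orientation = o, match_type = "contiguous_ge",
          matched = params$contig_discard)
      }
    }
    # rule (a): Hamming similarity >= ham_discard over aligned k-windows
    m <- k - params$ham_discard
    cand_windows <- NULL
    if (m <= 1L) {
      # pigeonhole with two half-length seeds
      seeds <- list(list(tab = index$seed_a, off = 0L,
                         len = index$half[1]),
                    list(tab = index$seed_b %||% index$seed_a,
                         off = index$half[1], len = index$half[2]))
      cand_windows <- data.table::rbindlist(lapply(seeds, function(s) {
        h <- s$tab[list(substr(q, s$off + 1L, s$off + s$len)),
                   nomatch = NULL]
        if (nrow(h) == 0) return(NULL)
        data.table::data.table(tx = h$tx, start = h$pos - s$off)
      }))
      if (!is.null(cand_windows) && nrow(cand_windows) > 0) {
        cand_windows <- unique(cand_windows)
        cand_windows <- cand_windows[start >= 0 &
          start + k <= txlen[tx] & !(tx %in% member_idx)]
        if (nrow(cand_windows) > 0) {
          mm <- cpp_mismatch_at(txs$sequence, cand_windows$tx,
                                cand_windows$start, rep(q, nrow(cand_windows)))
          cand_windows[, matches := k - mm]
          cand_windows <- cand_windows[matches >= params$ham_discard]
        }
      }
    } else {
      # general threshold: full Hamming scan
      cw <- cpp_hamming_windows(q, txs$sequence, params$ham_discard)
      cand_windows <- data.table::as.data.table(cw)
      data.table::setnames(cand_windows, "tx_idx", "tx")
      data.table::setnames(cand_windows, "offset", "start")
      cand_windows <- cand_windows[!(tx %in% member_idx)]
    }
    if (!is.null(cand_windows) && nrow(cand_windows) > 0) {
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = txs$transcript_id[cand_windows$tx],
        offset = cand_windows$start, orientation = o,
        match_type = "hamming_ge", matched = cand_windows$matches)
    }
  }
  hits <- if (length(hits) > 0) unique(do.call(rbind, hits)) else
    data.frame(transcript_id = character(0), offset = integer(0),
               orientation = character(0), match_type = character(0),
               matched = integer(0))
  rownames(hits) <- NULL
  list(verdict = if (nrow(hits) > 0) "discard" else "pass", hits = hits)
}

#' End-to-end siRNA design for one target Unigene
#'
#' Enumerates isoform-conserved ORF windows, scores them with the panel,
#' applies the consensus rule, screens survivors for off-targets against
#' the full transcriptome, and reports the ordered shortlist with
#' per-stage attrition.
#'
#' @param transcriptome data.frame with transcript_id, sequence (and
#'   optionally unigene_id).
#' @param target_unigene Unigene ID to design against.
#' @param params a [design_params()].
#' @param scorers scorer panel (see [score_candidates()]).
#' @param min_codons ORF detection threshold for the canonical isoform.
#' @return an object of class `design_report`: candidates, scored,
#'   consensus, screened (per-candidate verdicts + hits), shortlist,
#'   attrition counts.
#' @export
design_sirna <- function(transcriptome, target_unigene,
                         params = design_params(),
                         scorers = default_scorers(),
                         min_codons = 100L) {
  if (!"unigene_id" %in% names(transcriptome))
    transcriptome$unigene_id <- sub("_seq\\d+$", "",
                                    transcriptome$transcript_id)
  members <- transcriptome[transcriptome$unigene_id == target_unigene, ,
                           drop = FALSE]
  if (nrow(members) == 0)
    stopf("target Unigene %s not in transcriptome", target_unigene)
  orfs <- find_orfs(members, min_codons = min_codons)
  orfs <- orfs[orfs$strand == "+", , drop = FALSE]
  if (nrow(orfs) == 0)
    stopf("no plus-strand ORF >= %d codons found for %s", min_codons,
          target_unigene)
  cano <- orfs[order(-orfs$n_codons, orfs$transcript_id), ][1, ]
  iso_seqs <- setNames(members$sequence, members$transcript_id)
  cands <- enumerate_candidates(iso_seqs,
                                c(cano$start, cano$end), params,
                                canonical = cano$transcript_id)
  scored <- if (nrow(cands) > 0)
    score_candidates(cands, scorers, params) else list()
  consensus <- if (length(scored) > 0)
    consensus_select(scored, params)
  else data.frame(sequence = character(0), n_lists = integer(0),
                  best_rank = integer(0))
  index <- build_offtarget_index(transcriptome, params)
  screened <- lapply(consensus$sequence, function(s)
    offtarget_screen(s, index, members$transcript_id, params))
  verdicts <- vapply(screened, `[[`, "", "verdict")
  shortlist <- consensus[verdicts == "pass", , drop = FALSE]
  rownames(shortlist) <- NULL
  out <- list(target_unigene = target_unigene,
              canonical = cano$transcript_id,
              orf_span = c(cano$start, cano$end),
              candidates = cands, scored = scored,
              consensus = consensus,
              screened = setNames(screened, consensus$sequence),
              shortlist = shortlist,
              attrition = c(windows = nrow(cands),
                            consensus = nrow(consensus),
                            shortlist = nrow(shortlist)))
  class(out) <- "design_report"
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf(
    "siRNA design for %s (canonical %s): %d conserved windows -> %d consensus -> %d shortlisted\n",
    x$target_unigene, x$canonical, x$attrition["windows"],
    x$attrition["consensus"], x$attrition["shortlist"]))
  if (nrow(x$shortlist) > 0) {
    cat(paste0("  ", x$shortlist$sequence, collapse = "\n"), "\n")
  }
  invisible(x)
}
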