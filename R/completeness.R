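# cross-species protein identity, core-gene completeness classification
# and most-abundant full-length isoform selection

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Protein alignment and completeness parameters
#'
#' @param matrix name of a standard substitution matrix shipped with
#'   Biostrings (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param seed_len exact-match seed length (aa) for the protein search.
#' @param min_score minimum raw local-alignment score for a reportable hit.
#' @param coverage_threshold reference coverage needed for a `complete`
#'   call (the classical 70% rule).
#' @param identity_denominator `"alignment"` counts identical columns over
#'   the full alignment length including gap columns; `"shorter"` divides
#'   by the shorter sequence length instead.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, seed_len = 4L, min_score = 50,
                           coverage_threshold = 0.70,
                           identity_denominator = c("alignment",
                                                    "shorter")) {
  p <- list(matrix = matrix, submat = get_submatrix(matrix),
            gap_open = gap_open, gap_extend = gap_extend,
            seed_len = as.integer(seed_len), min_score = min_score,
            coverage_threshold = coverage_threshold,
            identity_denominator = match.arg(identity_denominator))
  if (gap_open <= 0 || gap_extend <= 0) stopf("gap penalties must be positive")
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stopf("coverage_threshold must lie in (0, 1]")
  class(p) <- "scoring_params"
  p
}

check_alphabet <- function(x, submat) {
  ok <- rownames(submat)
  chars <- unique(strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, ok)
  if (length(bad) > 0)
    stopf("character(s) not in the %s alphabet: %s",
          "substitution matrix", paste(bad, collapse = ", "))
}

# identity/coverage summary of an alignment given as two gapped strings
alignment_summary <- function(al_a, al_b, len_a, len_b, denominator) {
  ca <- strsplit(al_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & both)
  denom <- if (denominator == "alignment") length(ca) else min(len_a, len_b)
  # aligned span on each sequence: residues between the first and last
  # columns where both sequences carry a residue
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  span_cols <- which(both)
  if (length(span_cols) == 0) {
    return(list(identity_pct = 0, query_cov = 0, target_cov = 0,
                a_span = c(0L, 0L), b_span = c(0L, 0L)))
  }
  a_span <- c(pos_a[span_cols[1]] - 1L, pos_a[span_cols[length(span_cols)]])
  b_span <- c(pos_b[span_cols[1]] - 1L, pos_b[span_cols[length(span_cols)]])
  list(identity_pct = 100 * ident / denom,
       query_cov = (a_span[2] - a_span[1]) / len_a,
       target_cov = (b_span[2] - b_span[1]) / len_b,
       a_span = a_span, b_span = b_span)
}

#' Global protein alignment with percent identity
#'
#' Needleman-Wunsch with affine gaps and deterministic tie-breaking
#' (match preferred over gap, then gap in `b`). Identity is identical
#' columns over the alignment length including gap columns (switchable to
#' the shorter-sequence denominator via `scoring_params`).
#'
#' @param a,b protein strings (query and target).
#' @param params a [scoring_params()].
#' @return list: score, identity_pct, query_cov, target_cov, aligned_a,
#'   aligned_b, a_span, b_span (0-based half-open aligned spans).
#' @export
global_align_identity <- function(a, b, params = scoring_params()) {
  if (nchar(a) == 0 || nchar(b) == 0) stopf("empty protein sequence")
  check_alphabet(c(a, b), params$submat)
  al <- cpp_nw_align(a, b, params$submat, params$gap_open,
                     params$gap_extend)
  s <- alignment_summary(al$aligned_a, al$aligned_b, nchar(a), nchar(b),
                         params$identity_denominator)
  c(list(score = al$score, aligned_a = al$aligned_a,
         aligned_b = al$aligned_b), s)
}

#' Six-frame translation
#'
#' Standard codon table, stops rendered as `*`, trailing partial codons
#' dropped; frames ordered +0, +1, +2, -0, -1, -2.
#'
#' @param nt a nucleotide string.
#' @return named character vector of six protein strings.
#' @export
six_frame_translate <- function(nt) {
  out <- character(6)
  names(out) <- c("F0", "F1", "F2", "R0", "R1", "R2")
  i <- 1L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else revcomp(nt)
    n <- nchar(s)
    for (f in 0:2) {
      len3 <- max(((n - f) %/% 3L) * 3L, 0L)
      out[i] <- if (len3 >= 3) {
        suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, f + 1L, f + len3)),
          if.fuzzy.codon = "X", no.init.codon = TRUE)))
      } else ""
      i <- i + 1L
    }
  }
  out
}

#' Seed-and-extend protein search
#'
#' Local (Smith-Waterman) alignment of the query against every target
#' sharing at least one exact `seed_len`-mer, reporting hits with score
#' at least `min_score`, ranked by score then target id. No low-complexity
#' masking is applied, so short degenerate peptides still hit their
#' verbatim copies.
#'
#' @param query protein string.
#' @param targets named character vector of proteins (e.g. an ORF set or
#'   six-frame translations).
#' @param params a [scoring_params()].
#' @return data.frame: target_id, score, identity_pct, query_cov,
#'   target_cov, q_start, q_end, t_start, t_end (0-based half-open).
#' @export
search_protein <- function(query, targets, params = scoring_params()) {
  empty <- data.frame(target_id = character(0), score = numeric(0),
                      identity_pct = numeric(0), query_cov = numeric(0),
                      target_cov = numeric(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0))
  if (length(targets) == 0) return(empty)
  k <- params$seed_len
  if (nchar(query) < k) return(empty)
  qk <- unique(substring(query, seq_len(nchar(query) - k + 1L),
                         seq_len(nchar(query) - k + 1L) + k - 1L))
  seeded <- vapply(targets, function(t) {
    if (nchar(t) < k) return(FALSE)
    tk <- substring(t, seq_len(nchar(t) - k + 1L),
                    seq_len(nchar(t) - k + 1L) + k - 1L)
    any(tk %in% qk)
  }, TRUE)
  if (!any(seeded)) return(empty)
  rows <- lapply(names(targets)[seeded], function(id) {
    # cheap score-only pass first; traceback only for reportable hits
    if (cpp_sw_score(query, targets[[id]], params$submat,
                     params$gap_open, params$gap_extend) <
        params$min_score) return(NULL)
    al <- cpp_sw_align(query, targets[[id]], params$submat,
                       params$gap_open, params$gap_extend)
    if (al$score < params$min_score) return(NULL)
    s <- alignment_summary(al$aligned_a, al$aligned_b, nchar(query),
                           nchar(targets[[id]]),
                           params$identity_denominator)
    data.frame(target_id = id, score = al$score,
               identity_pct = s$identity_pct, query_cov = s$query_cov,
               target_cov = s$target_cov,
               q_start = as.integer(al$a_start),
               q_end = as.integer(al$a_end),
               t_start = as.integer(al$b_start),
               t_end = as.integer(al$b_end))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$score, out$target_id), , drop = FALSE]
}

#' Completeness call for a reference protein
#'
#' `complete` when some reportable hit covers at least
#' `coverage_threshold` of the reference; `partial` when hits exist but
#' none reaches the threshold; `absent` when no hit reaches `min_score`.
#'
#' @param ref_id reference identifier.
#' @param hits output of [search_protein()] for the reference.
#' @param params a [scoring_params()].
#' @return one-row data.frame: ref_id, status, best_target_id, coverage,
#'   identity_pct.
#' @export
classify_completeness <- function(ref_id, hits,
                                  params = scoring_params()) {
  if (nrow(hits) == 0)
    return(data.frame(ref_id = ref_id, status = "absent",
                      best_target_id = NA_character_, coverage = 0,
                      identity_pct = NA_real_))
  best <- hits[order(-hits$query_cov, -hits$score, hits$target_id), ,
               drop = FALSE][1, ]
  status <- if (best$query_cov >= params$coverage_threshold) "complete"
            else "partial"
  data.frame(ref_id = ref_id, status = status,
             best_target_id = best$target_id, coverage = best$query_cov,
             identity_pct = best$identity_pct)
}

#' Completeness report for a reference protein set
#'
#' @param refs named character vector of reference proteins.
#' @param targets named character vector of target proteins.
#' @param params a [scoring_params()].
#' @return data.frame with one completeness call per reference.
#' @export
completeness_report <- function(refs, targets,
                                params = scoring_params()) {
  do.call(rbind, lapply(names(refs), function(id) {
    classify_completeness(id, search_protein(refs[[id]], targets, params),
                          params)
  }))
}

#' Most abundant full-length isoform for a gene
#'
#' Walks the gene's isoforms by decreasing TPM and accepts the first whose
#' protein is full-length against the reference: protein/reference length
#' ratio within `len_ratio` and a global alignment reaching within
#' `end_slack` residues of both reference termini. The ratio bounds
#' bracket the spread observed across well-assembled ortholog sets
#' (87.7%-106.3%).
#'
#' @param proteins data.frame with transcript_id, protein.
#' @param tpm named numeric vector of transcript TPMs.
#' @param ref reference protein string.
#' @param params a [scoring_params()].
#' @param len_ratio numeric length-2 ratio bounds.
#' @param end_slack maximum unaligned residues tolerated at each reference
#'   terminus (aa).
#' @return list: transcript_id (NA if none qualifies), alignment (the
#'   [global_align_identity()] result or NULL), n_tried, reason.
#' @export
most_abundant_full_length <- function(proteins, tpm, ref,
                                      params = scoring_params(),
                                      len_ratio = c(0.85, 1.20),
                                      end_slack = 15L) {
  if (nrow(proteins) == 0)
    return(list(transcript_id = NA_character_, alignment = NULL,
                n_tried = 0L, reason = "no coding isoform"))
  ord <- order(-tpm[proteins$transcript_id], proteins$transcript_id)
  proteins <- proteins[ord, , drop = FALSE]
  for (i in seq_len(nrow(proteins))) {
    p <- proteins$protein[i]
    ratio <- nchar(p) / nchar(ref)
    if (ratio < len_ratio[1] || ratio > len_ratio[2]) next
    al <- global_align_identity(ref, p, params)
    if (al$a_span[1] <= end_slack &&
        nchar(ref) - al$a_span[2] <= end_slack) {
      return(list(transcript_id = proteins$transcript_id[i],
                  alignment = al, n_tried = i, reason = NA_character_))
    }
  }
  list(transcript_id = NA_character_, alignment = NULL,
       n_tried = nrow(proteins), reason = "no full-length isoform")
}
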