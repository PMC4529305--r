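# annotation-report parsing (tab columns, backtick-delimited lists,
# caret-delimited subfields, '.' for missing) and Fig-style summaries:
# annotation rate by abundance stratum, GO-term frequency, box/whisker
# distribution statistics

ANNOT_COLUMNS <- c("component", "trans_derived", "prot_id", "TopBlastHit",
                   "Pfam", "eggnog", "gene_ontology", "prot_seq")

split_multi <- function(x) {
  if (is.na(x) || x == ".") character(0) else strsplit(x, "`", fixed = TRUE)[[1]]
}

#' Parse an annotation report
#'
#' Reads the eight-column report layout (component, trans_derived,
#' prot_id, TopBlastHit, Pfam, eggnog, gene_ontology, prot_seq): tab
#' separated columns, backtick-delimited multi-hit lists, caret-delimited
#' subfields, and `.` for a missing value. GO entries have the form
#' `GO:NNNNNNN^ASPECT^name` with aspect P, F or C.
#'
#' @param path path to the report file.
#' @return list with `records` (data.frame: unigene_id, transcript_id,
#'   protein_id, n_go_terms, has_goP) and `go_terms` (long data.frame:
#'   unigene_id, term_id, aspect, name).
#' @export
parse_annotation_report <- function(path) {
  if (!file.exists(path)) stopf("annotation report not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && startsWith(lines[1], ANNOT_COLUMNS[1]))
    lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nbad <- which(lengths(fields) != length(ANNOT_COLUMNS))
  if (length(nbad) > 0)
    stopf("line %d has %d columns, expected %d", nbad[1],
          lengths(fields)[nbad[1]], length(ANNOT_COLUMNS))
  recs <- vector("list", length(fields))
  go_rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    names(f) <- ANNOT_COLUMNS
    gos <- split_multi(f[["gene_ontology"]])
    terms <- NULL
    if (length(gos) > 0) {
      parts <- strsplit(gos, "^", fixed = TRUE)
      short <- which(lengths(parts) < 3)
      if (length(short) > 0)
        stopf("line %d: malformed GO entry '%s'", i, gos[short[1]])
      terms <- data.frame(
        unigene_id = f[["component"]],
        term_id = vapply(parts, `[`, "", 1),
        aspect = vapply(parts, `[`, "", 2),
        name = vapply(parts, function(p) paste(p[-(1:2)], collapse = "^"),
                      ""))
      terms <- terms[!duplicated(terms$term_id), , drop = FALSE]
      if (!all(terms$aspect %in% c("P", "F", "C")))
        stopf("line %d: invalid GO aspect", i)
    }
    go_rows[[i]] <- terms
    recs[[i]] <- data.frame(
      unigene_id = f[["component"]],
      transcript_id = if (f[["trans_derived"]] == ".") NA_character_
                      else f[["trans_derived"]],
      protein_id = if (f[["prot_id"]] == ".") NA_character_
                   else f[["prot_id"]],
      n_go_terms = if (is.null(terms)) 0L else nrow(terms),
      has_goP = !is.null(terms) && any(terms$aspect == "P"))
  }
  go_terms <- do.call(rbind, go_rows[!vapply(go_rows, is.null, TRUE)])
  if (is.null(go_terms))
    go_terms <- data.frame(unigene_id = character(0),
                           term_id = character(0), aspect = character(0),
                           name = character(0))
  list(records = do.call(rbind, recs), go_terms = go_terms)
}

#' Write an annotation report
#'
#' Inverse of [parse_annotation_report()] for synthetic records; used for
#' round-trip testing and fixture generation.
#'
#' @param records data.frame: unigene_id, transcript_id, protein_id.
#' @param go_terms long data.frame: unigene_id, term_id, aspect, name.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_annotation_report <- function(records, go_terms, path) {
  dot <- function(x) ifelse(is.na(x) | x == "", ".", x)
  go_str <- vapply(records$unigene_id, function(u) {
    t <- go_terms[go_terms$unigene_id == u, , drop = FALSE]
    if (nrow(t) == 0) return(".")
    paste(paste(t$term_id, t$aspect, t$name, sep = "^"), collapse = "`")
  }, "")
  lines <- paste(records$unigene_id, dot(records$transcript_id),
                 dot(records$protein_id), ".", ".", ".", go_str, ".",
                 sep = "\t")
  writeLines(c(paste(ANNOT_COLUMNS, collapse = "\t"), lines), path)
  invisible(path)
}

#' Annotation rate by abundance stratum
#'
#' Ranks Unigenes by TPM (descending, ties by id), splits them into the
#' top `rank_cutoff` and the remainder, and reports in each stratum the
#' number and fraction carrying at least one GO biological-process term.
#'
#' @param unigene_tpm named numeric vector of Unigene TPMs.
#' @param annotated_ids Unigene IDs with at least one GO:P term.
#' @param rank_cutoff size of the high-abundance stratum.
#' @return data.frame with one row per stratum: stratum, n_total,
#'   n_annotated, fraction.
#' @export
annotation_rate_by_abundance <- function(unigene_tpm, annotated_ids,
                                         rank_cutoff) {
  if (rank_cutoff < 1) stopf("rank_cutoff must be >= 1")
  ids <- names(unigene_tpm)[order(-unigene_tpm, names(unigene_tpm))]
  top <- head(ids, rank_cutoff)
  rest <- tail(ids, max(length(ids) - rank_cutoff, 0))
  row <- function(stratum, set) {
    n_ann <- sum(set %in% annotated_ids)
    data.frame(stratum = stratum, n_total = length(set),
               n_annotated = n_ann,
               fraction = if (length(set) > 0) n_ann / length(set) else 0)
  }
  out <- row("top", top)
  if (length(rest) > 0) out <- rbind(out, row("rest", rest))
  out
}

#' GO-term frequency with cumulative span
#'
#' Ranks terms by the number of Unigenes they annotate (ties by term id)
#' and reports, for the top `top_k`, the per-term Unigene count and the
#' number of unique Unigenes annotated by at least one of the ranked
#' terms so far.
#'
#' @param go_terms long data.frame: unigene_id, term_id, aspect, name.
#' @param top_k number of terms to report.
#' @param aspect GO aspect to count (default biological process).
#' @return list with `terms` (data.frame: term_id, name, n_unigenes,
#'   cumulative_unique_unigenes) and `span` (unique Unigenes covered by
#'   the top `top_k` terms).
#' @export
term_frequency <- function(go_terms, top_k = 30L, aspect = "P") {
  if (top_k < 1) stopf("top_k must be >= 1")
  g <- unique(go_terms[go_terms$aspect == aspect,
                       c("unigene_id", "term_id", "name")])
  if (nrow(g) == 0)
    return(list(terms = data.frame(term_id = character(0),
                                   name = character(0),
                                   n_unigenes = integer(0),
                                   cumulative_unique_unigenes = integer(0)),
                span = 0L))
  counts <- as.data.frame(table(term_id = g$term_id),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n_unigenes"
  counts <- counts[order(-counts$n_unigenes, counts$term_id), ,
                   drop = FALSE]
  counts <- head(counts, top_k)
  counts$name <- g$name[match(counts$term_id, g$term_id)]
  seen <- character(0)
  cum <- integer(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    seen <- union(seen, g$unigene_id[g$term_id == counts$term_id[i]])
    cum[i] <- length(seen)
  }
  counts$cumulative_unique_unigenes <- cum
  rownames(counts) <- NULL
  list(terms = counts[, c("term_id", "name", "n_unigenes",
                          "cumulative_unique_unigenes")],
       span = length(seen))
}

#' Box/whisker summary of a distribution
#'
#' Quartiles by linear interpolation; whiskers are the most extreme data
#' points within 1.5 IQR of the quartiles; outliers are the points beyond
#' the whiskers.
#'
#' @param values numeric vector (n >= 1).
#' @return list: median, q1, q3, whisker_lo, whisker_hi, outliers.
#' @export
tpm_distribution_summary <- function(values) {
  if (length(values) == 0) stopf("cannot summarize an empty distribution")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

#' Generate a synthetic annotation table for testing summaries
#'
#' Assigns GO:P terms to Unigenes with probability increasing in
#' abundance, emulating the abundance bias of real annotation rates.
#'
#' @param unigene_tpm named numeric vector of Unigene TPMs.
#' @param n_terms size of the GO:P term vocabulary.
#' @param seed RNG seed.
#' @return long data.frame usable as `go_terms`.
#' @export
simulate_annotations <- function(unigene_tpm, n_terms = 40L, seed = 1L) {
  set.seed(seed)
  ids <- names(unigene_tpm)
  r <- rank(-unigene_tpm, ties.method = "first")
  p_ann <- 0.85 - 0.6 * (r - 1) / max(length(ids) - 1, 1)
  vocab <- sprintf("GO:%07d", seq_len(n_terms))
  # Zipf-ish term popularity
  wt <- 1 / seq_len(n_terms)
  rows <- lapply(seq_along(ids), function(i) {
    if (runif(1) > p_ann[i]) return(NULL)
    k <- 1L + rpois(1, 2)
    t <- sample(vocab, min(k, n_terms), prob = wt)
    data.frame(unigene_id = ids[i], term_id = t, aspect = "P",
               name = paste("process", sub("GO:", "", t)))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(unigene_id = character(0), term_id = character(0),
                      aspect = character(0), name = character(0)))
  do.call(rbind, rows)
}
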