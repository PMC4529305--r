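# shared fixtures and independent oracles used across test files

small_sim <- function(seed = 1, n_genes = 5, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, ...)
  gen <- generate_genome(cfg)
  iso <- generate_transcriptome(gen, cfg)
  list(cfg = cfg, gen = gen, iso = iso)
}

tx_df <- function(iso) {
  data.frame(transcript_id = iso$isoforms$transcript_id,
             unigene_id = iso$isoforms$gene_id,
             sequence = iso$isoforms$sequence)
}

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- independent oracles ---------------------------------------------------

# N50: sort descending, accumulate, first length reaching half the total
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(lengths) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# exhaustive 6-frame ORF scan enumerating every candidate directly
oracle_best_orf <- function(sequence, min_codons) {
  codon_table <- Biostrings::GENETIC_CODE
  translate_raw <- function(s) {
    n3 <- (nchar(s) %/% 3) * 3
    if (n3 == 0) return("")
    codons <- substring(s, seq(1, n3, 3), seq(3, n3, 3))
    paste(ifelse(codons %in% names(codon_table), codon_table[codons], "X"),
          collapse = "")
  }
  best <- NULL
  consider <- function(strand, f, aa_start, aa_end, has_stop, prot) {
    nc <- aa_end - aa_start + 1L
    if (nc < min_codons) return()
    if (!is.null(best) && nc <= best$n_codons) return()
    best <<- list(strand = strand, frame = f, n_codons = nc,
                  start = f + 3L * (aa_start - 1L),
                  end = f + 3L * aa_end + if (has_stop) 3L else 0L,
                  protein = substr(prot, aa_start, aa_end))
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (f in 0:2) {
      prot <- translate_raw(substr(s, f + 1, nchar(s)))
      chars <- strsplit(prot, "")[[1]]
      n <- length(chars)
      if (n == 0) next
      # edge-to-stop in frame 0 first (tie order matches scan order),
      # unless the edge codon is ATG (covered by the complete candidate)
      if (f == 0 && chars[1] != "M") {
        stop_at <- which(chars == "*")[1]
        if (!is.na(stop_at) && stop_at > 1)
          consider(strand, f, 1L, stop_at - 1L, TRUE, prot)
      }
      # every ATG start
      for (m in which(chars == "M")) {
        rest <- chars[m:n]
        stop_at <- which(rest == "*")[1]
        if (!is.na(stop_at)) {
          consider(strand, f, m, m + stop_at - 2L, TRUE, prot)
        } else {
          consider(strand, f, m, n, FALSE, prot)
        }
      }
    }
  }
  best
}

# quadratic-space textbook global alignment (Gotoh), scores only
oracle_global_score <- function(a, b, submat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Iy[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Ix[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# brute-force library complexity by direct set counting
oracle_complexity <- function(aln) {
  starts <- c(paste(aln$transcript_id, "F", aln$fragment_start),
              paste(aln$transcript_id, "R", aln$fragment_end))
  frags <- paste(aln$transcript_id, aln$fragment_start, aln$fragment_end)
  list(unpaired = length(unique(starts)) / (2 * nrow(aln)),
       paired = length(unique(frags)) / nrow(aln))
}

# brute-force substring-intersection candidate enumeration
oracle_candidates <- function(isoform_seqs, orf_span, k,
                              canonical = names(isoform_seqs)[1]) {
  cano <- isoform_seqs[[canonical]]
  if (orf_span[2] - orf_span[1] < k) return(character(0))
  offs <- orf_span[1]:(orf_span[2] - k)
  win <- substring(cano, offs + 1, offs + k)
  keep <- vapply(win, function(w)
    all(vapply(isoform_seqs, function(s) grepl(w, s, fixed = TRUE), TRUE)),
    TRUE)
  unname(win[keep])
}

# exhaustive off-target screen: every transcript x window x orientation,
# Hamming count and longest-run computation in plain R
oracle_offtarget <- function(candidate, transcripts, members,
                             ham_discard = 18, contig_discard = 16,
                             both = TRUE) {
  k <- nchar(candidate)
  queries <- if (both) c(candidate, revcomp(candidate)) else candidate
  for (q in queries) {
    qc <- strsplit(q, "")[[1]]
    for (i in seq_len(nrow(transcripts))) {
      if (transcripts$transcript_id[i] %in% members) next
      s <- transcripts$sequence[i]
      n <- nchar(s)
      if (n < contig_discard) next
      sc <- strsplit(s, "")[[1]]
      for (p in seq_len(max(n - k + 1, 0))) {
        eq <- sc[p:(p + k - 1)] == qc
        if (sum(eq) >= ham_discard) return("discard")
      }
    }
    # contiguous rule, independent of full k-windows: any substring of
    # length contig_discard occurring verbatim in a non-member transcript
    L <- contig_discard
    subs <- unique(substring(q, seq_len(k - L + 1),
                             seq_len(k - L + 1) + L - 1))
    for (i in seq_len(nrow(transcripts))) {
      if (transcripts$transcript_id[i] %in% members) next
      if (any(vapply(subs, function(x)
        grepl(x, transcripts$sequence[i], fixed = TRUE), TRUE)))
        return("discard")
    }
  }
  "pass"
}
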