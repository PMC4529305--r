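# exon-structure inference: exact-match block chaining of an mRNA against
# genomic sequence, and the exon x isoform comparison matrix

# maximal exact matches (length >= min_block) between mrna and genome,
# found by k-mer anchoring and diagonal run merging
match_blocks <- function(mrna, genome, min_block) {
  k <- min_block
  gk <- all_kmers(genome, k)
  if (length(gk) == 0 || nchar(mrna) < k) return(NULL)
  gidx <- data.table::data.table(kmer = gk, gpos = seq_along(gk) - 1L)
  data.table::setkey(gidx, kmer)
  tk <- all_kmers(mrna, k)
  q <- data.table::data.table(kmer = tk, tpos = seq_along(tk) - 1L)
  hits <- gidx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(NULL)
  hits[, diag := gpos - tpos]
  data.table::setorder(hits, diag, tpos)
  # consecutive k-mer hits on one diagonal form one maximal exact match
  brk <- c(TRUE, diff(hits$tpos) != 1L | diff(hits$diag) != 0L)
  run <- cumsum(brk)
  blocks <- hits[, list(tx_start = min(tpos), tx_end = max(tpos) + k,
                        g_start = min(gpos), g_end = max(gpos) + k),
                 by = list(run_id = run)]
  blocks[, run_id := NULL]
  unique(blocks)
}

# chain of collinear blocks maximizing total transcript coverage.
# Maximal exact matches may extend a few chance bases across a splice
# junction, making adjacent exons' blocks overlap in transcript
# coordinates; chaining therefore tolerates overlaps (scoring covered
# bases, not block sums) and the reconstruction step picks the junction
# split, preferring one flanked by a canonical splice motif.
chain_blocks <- function(blocks) {
  b <- as.data.frame(blocks)
  b <- b[order(b$tx_start, b$g_start), , drop = FALSE]
  n <- nrow(b)
  w <- b$tx_end - b$tx_start
  diag <- b$g_start - b$tx_start
  score <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (b$tx_start[j] >= b$tx_start[i] || b$tx_end[j] >= b$tx_end[i] ||
          diag[j] >= diag[i]) next
      ov <- max(b$tx_end[j] - b$tx_start[i], 0L)
      if (ov >= min(w[i], w[j])) next
      s <- score[j] + w[i] - ov
      if (s > score[i]) {
        score[i] <- s
        prev[i] <- j
      }
    }
  }
  best <- which.max(score)
  chain <- integer(0)
  while (!is.na(best)) {
    chain <- c(best, chain)
    best <- prev[chain[1]]
  }
  list(blocks = b[chain, , drop = FALSE], coverage = max(score))
}

splice_motif_ok <- function(genome, don_start, acc_end) {
  don <- substring(genome, don_start + 1L, don_start + 2L)
  acc <- substring(genome, acc_end - 1L, acc_end)
  (don == "GT" && acc == "AG") || (don == "CT" && acc == "AC")
}

# resolve transcript-coordinate overlaps between consecutive chained
# blocks: the junction may sit anywhere inside the overlap; prefer the
# split flanked by a canonical splice motif (GT..AG, or CT..AC for a
# gene on the genomic minus strand), falling back to the maximal
# upstream block
resolve_overlaps <- function(b, genome) {
  if (nrow(b) < 2) return(b)
  for (i in seq_len(nrow(b) - 1L)) {
    ov <- b$tx_end[i] - b$tx_start[i + 1L]
    if (ov <= 0) next
    ts <- (b$tx_end[i] - ov):b$tx_end[i]   # candidate junction positions
    pick <- b$tx_end[i]
    for (t in ts) {
      don <- b$g_start[i] + (t - b$tx_start[i])
      acc <- b$g_start[i + 1L] + (t - b$tx_start[i + 1L])
      if (splice_motif_ok(genome, don, acc)) {
        pick <- t
        break
      }
    }
    b$tx_end[i] <- pick
    b$g_end[i] <- b$g_start[i] + (pick - b$tx_start[i])
    b$g_start[i + 1L] <- b$g_start[i + 1L] + (pick - b$tx_start[i + 1L])
    b$tx_start[i + 1L] <- pick
  }
  b
}

#' Infer exon blocks by aligning an mRNA to genomic sequence
#'
#' Finds exact match blocks (length >= `min_block`) between the mRNA and
#' the genome, chains the collinear subset maximizing total transcript
#' coverage, merges blocks adjacent in both coordinate systems, and
#' reports the chained blocks as putative exons; genomic gaps between
#' them are putative introns (annotated with their terminal dinucleotides
#' so canonical GT-AG splice sites are visible, but never enforced).
#' Both the given mRNA and its reverse complement are tried; the
#' orientation with greater coverage wins (ties prefer the given one).
#'
#' @param mrna,genome nucleotide strings.
#' @param min_block minimum exact-match block length (nt).
#' @param min_intron genomic gaps at least this long count as introns.
#' @return data.frame of class `exon_chain`: exon_index, genome_start,
#'   genome_end, tx_start, tx_end (0-based half-open; transcript
#'   coordinates on the aligned orientation). Attributes: `strand`,
#'   `coverage`, `uncovered` (transcript nt outside blocks), `introns`
#'   (data.frame with genomic gaps and motifs).
#' @export
infer_exons <- function(mrna, genome, min_block = 20L, min_intron = 30L) {
  stopifnot(nchar(mrna) > 0, nchar(genome) > 0)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") mrna else revcomp(mrna)
    bl <- match_blocks(s, genome, min_block)
    if (is.null(bl) || nrow(bl) == 0) next
    ch <- chain_blocks(bl)
    if (is.null(best) || ch$coverage > best$coverage)
      best <- c(ch, strand = strand)
  }
  empty <- data.frame(exon_index = integer(0), genome_start = integer(0),
                      genome_end = integer(0), tx_start = integer(0),
                      tx_end = integer(0))
  if (is.null(best)) {
    warnf("no exact match block >= %d nt between mRNA and genome",
          min_block)
    attr(empty, "strand") <- NA_character_
    attr(empty, "coverage") <- 0L
    attr(empty, "uncovered") <- nchar(mrna)
    class(empty) <- c("exon_chain", class(empty))
    return(empty)
  }
  b <- resolve_overlaps(best$blocks, genome)
  # merge blocks with zero gap in both coordinate systems
  merged <- b[1, , drop = FALSE]
  for (i in seq_len(nrow(b))[-1]) {
    last <- nrow(merged)
    if (b$tx_start[i] == merged$tx_end[last] &&
        b$g_start[i] == merged$g_end[last]) {
      merged$tx_end[last] <- b$tx_end[i]
      merged$g_end[last] <- b$g_end[i]
    } else {
      merged <- rbind(merged, b[i, , drop = FALSE])
    }
  }
  out <- data.frame(exon_index = seq_len(nrow(merged)),
                    genome_start = merged$g_start,
                    genome_end = merged$g_end,
                    tx_start = merged$tx_start,
                    tx_end = merged$tx_end)
  introns <- NULL
  if (nrow(out) > 1) {
    gap_start <- out$genome_end[-nrow(out)]
    gap_end <- out$genome_start[-1]
    introns <- data.frame(
      after_exon = out$exon_index[-nrow(out)],
      g_start = gap_start, g_end = gap_end,
      width = gap_end - gap_start,
      is_intron = gap_end - gap_start >= min_intron,
      motif = paste0(substring(genome, gap_start + 1L, gap_start + 2L),
                     "..",
                     substring(genome, gap_end - 1L, gap_end)))
  }
  attr(out, "strand") <- best$strand
  attr(out, "coverage") <- best$coverage
  attr(out, "uncovered") <- nchar(mrna) - best$coverage
  attr(out, "introns") <- introns
  class(out) <- c("exon_chain", class(out))
  out
}

#' Exon x isoform comparison table
#'
#' Assigns exon ordinals by clustering the genomic intervals of all
#' isoforms' blocks (intervals overlapping by at least 1 nt share an
#' ordinal, ordered by genomic start) and tabulates each isoform's block
#' length per ordinal (NA = absent). Exons whose length varies or that
#' are absent in some isoform are flagged.
#'
#' @param chains named list of [infer_exons()] results aligned to the
#'   same genomic sequence.
#' @return list: `lengths` (isoform x ordinal matrix of block lengths),
#'   `ordinals` (data.frame: exon_index, genome_start, genome_end),
#'   `variant` (logical per ordinal).
#' @export
compare_exon_tables <- function(chains) {
  stopifnot(length(chains) >= 1, !is.null(names(chains)))
  allb <- do.call(rbind, lapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    if (nrow(ch) == 0) return(NULL)
    data.frame(isoform = nm, genome_start = ch$genome_start,
               genome_end = ch$genome_end)
  }))
  if (is.null(allb)) stopf("no exon blocks to compare")
  ir <- IRanges::IRanges(start = allb$genome_start + 1L,
                         end = allb$genome_end)
  red <- IRanges::reduce(ir)
  red <- red[order(IRanges::start(red))]
  ord <- IRanges::findOverlaps(ir, red, select = "first")
  ordinals <- data.frame(exon_index = seq_along(red),
                         genome_start = IRanges::start(red) - 1L,
                         genome_end = IRanges::end(red))
  mat <- matrix(NA_integer_, nrow = length(chains), ncol = length(red),
                dimnames = list(names(chains),
                                paste0("exon", seq_along(red))))
  len <- allb$genome_end - allb$genome_start
  for (i in seq_len(nrow(allb))) {
    r <- allb$isoform[i]
    if (!is.na(mat[r, ord[i]]))
      mat[r, ord[i]] <- mat[r, ord[i]] + len[i]
    else mat[r, ord[i]] <- len[i]
  }
  variant <- apply(mat, 2, function(col) {
    any(is.na(col)) || length(unique(col[!is.na(col)])) > 1
  })
  list(lengths = mat, ordinals = ordinals, variant = variant)
}

#' Write exon chains as BED12-style lines
#'
#' One line per isoform: chrom, chromStart, chromEnd, name, blockCount,
#' blockSizes, blockStarts (relative to chromStart).
#'
#' @param chains named list of [infer_exons()] results.
#' @param path output path.
#' @param chrom chromosome name to print.
#' @return invisibly, the path.
#' @export
write_exon_bed <- function(chains, path, chrom = "chr1") {
  lines <- vapply(names(chains), function(nm) {
    ch <- chains[[nm]]
    if (nrow(ch) == 0) return(sprintf("%s\t0\t0\t%s\t0\t\t", chrom, nm))
    cs <- min(ch$genome_start)
    paste(chrom, cs, max(ch$genome_end), nm, nrow(ch),
          paste(ch$genome_end - ch$genome_start, collapse = ","),
          paste(ch$genome_start - cs, collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
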