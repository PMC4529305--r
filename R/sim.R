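# synthetic genome / transcriptome / read generator
#
# Produces a ground-truthed chromosome with spliced multi-isoform genes,
# coding and non-coding loci, a bimodal abundance distribution over coding
# loci, and paired-end reads with insert-size variation, adapter
# read-through, quality decay and quality-implied substitution errors.
# Every downstream stage of the package is exercised against this truth.

# 33-nt prefix of the standard Illumina TruSeq read-through adapter; any
# string is accepted, adapter identity is irrelevant to the algorithms
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic data generator. Defaults emulate
#' the sequencing design the pipeline assumes: ~275 bp inserts, 150 nt
#' paired-end reads, a non-stranded library, quality decaying from Phred 38
#' to 30 along the read, and a two-component log-normal abundance mixture
#' over coding loci (log10-TPM 0.5*N(0.3,0.4) + 0.5*N(1.5,0.5)) with
#' non-coding loci drawn from the low component N(0,0.4), reproducing the
#' qualitative bimodality seen in deeply sequenced poly(A) libraries.
#'
#' @param n_genes number of gene loci to place on the chromosome.
#' @param coding_fraction fraction of loci carrying an ORF.
#' @param isoform_mean mean isoforms per locus (1 + geometric).
#' @param max_isoforms cap on isoforms per locus.
#' @param variant_types isoform variant kinds: exon skipping and/or
#'   alternative terminal-exon length.
#' @param exon_count_range,exon_len_range,intron_len_range integer ranges
#'   (nt) for gene structure.
#' @param min_intron minimum intron length (nt).
#' @param intergenic_range range of intergenic gap lengths (nt).
#' @param orf_min_codons minimum ORF length (codons, excluding the stop) for
#'   coding loci.
#' @param abundance_mixture list with `coding` (means, sds, weight on the
#'   low component, all on log10-TPM scale) and `noncoding` (mean, sd).
#' @param fragment_mean,fragment_sd insert size distribution (nt).
#' @param read_len read length (nt).
#' @param adapter adapter string appended when a fragment is shorter than
#'   the read (read-through).
#' @param quality_model list: `q_start`, `q_end` (mean Phred at first/last
#'   cycle, linear decay), `jitter_sd`, `q_floor`.
#' @param inject_errors inject substitution errors at the rate implied by
#'   each base's quality.
#' @param n_pairs default number of read pairs for [simulate_reads()].
#' @param seed master seed; each generator derives a stage seed from it, so
#'   a fixed config yields byte-identical outputs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 60,
                       coding_fraction = 0.7,
                       isoform_mean = 3.7,
                       max_isoforms = 6,
                       variant_types = c("skip", "trunc"),
                       exon_count_range = c(3L, 8L),
                       exon_len_range = c(100L, 400L),
                       intron_len_range = c(60L, 400L),
                       min_intron = 30L,
                       intergenic_range = c(200L, 800L),
                       orf_min_codons = 100L,
                       abundance_mixture = list(
                         coding = list(means = c(0.3, 1.5),
                                       sds = c(0.4, 0.5),
                                       weight = 0.5),
                         noncoding = list(mean = 0.0, sd = 0.4)),
                       fragment_mean = 275,
                       fragment_sd = 25,
                       read_len = 150L,
                       adapter = DEFAULT_ADAPTER,
                       quality_model = list(q_start = 38, q_end = 30,
                                            jitter_sd = 3, q_floor = 2),
                       inject_errors = TRUE,
                       n_pairs = 50000L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              coding_fraction = coding_fraction,
              isoform_mean = isoform_mean,
              max_isoforms = as.integer(max_isoforms),
              variant_types = match.arg(variant_types,
                                        c("skip", "trunc"),
                                        several.ok = TRUE),
              exon_count_range = as.integer(exon_count_range),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              min_intron = as.integer(min_intron),
              intergenic_range = as.integer(intergenic_range),
              orf_min_codons = as.integer(orf_min_codons),
              abundance_mixture = abundance_mixture,
              fragment_mean = fragment_mean,
              fragment_sd = fragment_sd,
              read_len = as.integer(read_len),
              adapter = toupper(adapter),
              quality_model = quality_model,
              inject_errors = isTRUE(inject_errors),
              n_pairs = as.integer(n_pairs),
              seed = as.integer(seed))
  if (cfg$n_genes < 0) stopf("n_genes must be >= 0")
  if (cfg$coding_fraction < 0 || cfg$coding_fraction > 1)
    stopf("coding_fraction must lie in [0, 1]")
  if (cfg$intron_len_range[1] < cfg$min_intron)
    stopf("intron_len_range lower bound (%d) is below min_intron (%d)",
          cfg$intron_len_range[1], cfg$min_intron)
  if (!all(is.finite(c(cfg$fragment_mean, cfg$fragment_sd,
                       unlist(abundance_mixture)))))
    stopf("all distribution parameters must be finite")
  class(cfg) <- "sim_config"
  cfg
}

# sample a stop-free ORF: ATG + (n_codons - 1) sense codons + stop
random_orf <- function(n_codons) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(sense, n_codons - 1, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

sample_range <- function(rng, n = 1) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, TRUE)
}

#' Generate a synthetic chromosome with placed gene models
#'
#' Genes are laid down sequentially (no overlap) with random intergenic
#' gaps. Coding genes carry a stop-free ORF spanning most of the mature
#' transcript; minus-strand genes are stored as plus-strand exon intervals
#' with a strand flag, the mature transcript being the reverse complement
#' of the concatenated exon slices. All coordinates are 0-based, half-open.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `genes` (data.frame: gene_id, strand, coding, n_exons,
#'   orf_start, orf_end in mature-transcript coordinates, mature_len) and
#'   `exons` (data.frame: gene_id, exon_rank, start, end in genomic
#'   coordinates).
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$n_genes
  if (n == 0) {
    chrom <- random_dna(1000L)
    return(list(genome = c(chr1 = chrom),
                genes = data.frame(gene_id = character(0),
                                   strand = character(0),
                                   coding = logical(0),
                                   n_exons = integer(0),
                                   orf_start = integer(0),
                                   orf_end = integer(0),
                                   mature_len = integer(0)),
                exons = data.frame(gene_id = character(0),
                                   exon_rank = integer(0),
                                   start = integer(0), end = integer(0)),
                config = config))
  }
  coding <- runif(n) < config$coding_fraction
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%03d", seq_len(n))

  pieces <- character(0)
  offset <- 0L
  exon_rows <- vector("list", n)
  orf_start <- orf_end <- rep(NA_integer_, n)
  mature_len <- integer(n)
  for (i in seq_len(n)) {
    gap <- sample_range(config$intergenic_range)
    pieces <- c(pieces, random_dna(gap))
    offset <- offset + gap
    k <- sample_range(config$exon_count_range)
    elens <- sample_range(config$exon_len_range, k)
    if (coding[i]) {
      utr5 <- sample(5:25, 1)
      utr3 <- sample(5:25, 1)
      need <- 3L * (config$orf_min_codons + 1L) + utr5 + utr3
      while (sum(elens) < need) elens[k] <- elens[k] + 50L
      L <- sum(elens)
      orf_len <- ((L - utr5 - utr3) %/% 3L) * 3L
      mature <- paste0(random_dna(utr5),
                       random_orf(orf_len / 3L - 1L),
                       random_dna(L - utr5 - orf_len))
      orf_start[i] <- utr5
      orf_end[i] <- utr5 + orf_len
    } else {
      L <- sum(elens)
      mature <- random_dna(L)
    }
    mature_len[i] <- L
    # split the mature transcript into exons, interleave random introns
    cum <- cumsum(c(0L, elens))
    exon_seqs <- substring(mature, cum[-length(cum)] + 1L, cum[-1])
    ilens <- if (k > 1) sample_range(config$intron_len_range, k - 1L)
             else integer(0)
    # canonical GT..AG splice sites (on the gene's strand)
    intron_seqs <- vapply(ilens, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), "")
    region <- paste0(paste0(exon_seqs, c(intron_seqs, "")), collapse = "")
    rlen <- nchar(region)
    starts <- cum[-length(cum)] +
      c(0L, cumsum(ilens))[seq_len(k)]
    ends <- starts + elens
    if (strand[i] == "-") {
      region <- revcomp(region)
      new_starts <- rlen - ends
      ends <- rlen - starts
      starts <- new_starts
      ord <- order(starts)
      starts <- starts[ord]; ends <- ends[ord]
    }
    exon_rows[[i]] <- data.frame(gene_id = gene_id[i],
                                 exon_rank = seq_len(k),
                                 start = offset + as.integer(starts),
                                 end = offset + as.integer(ends))
    pieces <- c(pieces, region)
    offset <- offset + rlen
  }
  pieces <- c(pieces, random_dna(sample_range(config$intergenic_range)))
  chrom <- paste0(pieces, collapse = "")
  genes <- data.frame(gene_id = gene_id, strand = strand, coding = coding,
                      n_exons = vapply(exon_rows, nrow, 0L),
                      orf_start = orf_start, orf_end = orf_end,
                      mature_len = mature_len)
  list(genome = c(chr1 = chrom), genes = genes,
       exons = do.call(rbind, exon_rows), config = config)
}

# mature transcript from genomic exon intervals (0-based half-open),
# reverse-complemented on the minus strand
splice_exons <- function(chrom, exon_df, strand) {
  s <- paste0(substring(chrom, exon_df$start + 1L, exon_df$end),
              collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Generate isoforms with ground-truth abundances
#'
#' Each locus emits one canonical isoform (all exons) plus variants formed
#' by skipping an internal exon or shortening the 3'-terminal exon.
#' Locus-level abundance is drawn from the configured log-normal mixture
#' (two components for coding loci, the low component for non-coding),
#' split across isoforms, and renormalized so TPM sums to 1e6.
#'
#' @param gen output of [generate_genome()].
#' @param config a [sim_config()]; defaults to the one stored in `gen`.
#' @return list with `isoforms` (data.frame: transcript_id, gene_id,
#'   exon_ranks, sequence, length, coding, true_tpm) and `iso_exons`
#'   (per-isoform genomic exon intervals).
#' @export
generate_transcriptome <- function(gen, config = gen$config) {
  set.seed(derive_seed(config$seed, "transcriptome"))
  genes <- gen$genes
  chrom <- gen$genome[[1]]
  iso_rows <- list()
  iso_exon_rows <- list()
  p_extra <- 1 / config$isoform_mean   # mean of 1 + Geom(p) = isoform_mean
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- gen$exons[gen$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    n_iso <- min(1L + rgeom(1, p_extra), config$max_isoforms)
    variants <- list(ex)  # canonical: all exons, full length
    if (n_iso > 1) {
      # distinct variant structures: each internal exon can be skipped at
      # most once, truncation offsets are spaced and used at most once
      avail_skip <- if ("skip" %in% config$variant_types && nrow(ex) >= 3)
        ex$exon_rank[-c(1, nrow(ex))] else integer(0)
      term <- if (g$strand == "+") which.max(ex$end) else which.min(ex$start)
      wterm <- ex$end[term] - ex$start[term]
      avail_trunc <- if ("trunc" %in% config$variant_types && wterm >= 50)
        seq(20L, wterm - 30L, by = 23L) else integer(0)
      if (length(avail_skip) + length(avail_trunc) == 0) {
        warnf("gene %s (%d exons) supports no %s variant; emitting an identical isoform",
              g$gene_id, nrow(ex),
              paste(config$variant_types, collapse = "/"))
      } else {
        n_iso <- min(n_iso, 1L + length(avail_skip) + length(avail_trunc))
      }
      for (v in seq_len(n_iso - 1L)) {
        kinds <- c(if (length(avail_skip) > 0) "skip",
                   if (length(avail_trunc) > 0) "trunc")
        if (length(kinds) == 0) {
          variants[[v + 1L]] <- ex
          next
        }
        kind <- kinds[sample.int(length(kinds), 1)]
        if (kind == "skip") {
          drop_rank <- avail_skip[sample.int(length(avail_skip), 1)]
          avail_skip <- setdiff(avail_skip, drop_rank)
          variants[[v + 1L]] <- ex[ex$exon_rank != drop_rank, , drop = FALSE]
        } else {
          d <- avail_trunc[sample.int(length(avail_trunc), 1)]
          avail_trunc <- setdiff(avail_trunc, d)
          exv <- ex
          if (g$strand == "+") exv$end[term] <- exv$end[term] - d
          else exv$start[term] <- exv$start[term] + d
          variants[[v + 1L]] <- exv
        }
      }
    }
    for (v in seq_along(variants)) {
      exv <- variants[[v]]
      tid <- sprintf("%s_seq%d", g$gene_id, v)
      seqv <- splice_exons(chrom, exv, g$strand)
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = g$gene_id,
        exon_ranks = paste(exv$exon_rank, collapse = ","),
        sequence = seqv, length = nchar(seqv), coding = g$coding)
      iso_exon_rows[[length(iso_exon_rows) + 1L]] <-
        data.frame(transcript_id = tid, gene_id = g$gene_id,
                   exon_rank = exv$exon_rank, start = exv$start,
                   end = exv$end)
    }
  }
  isoforms <- do.call(rbind, iso_rows)
  # locus-level abundance mixture (log10 TPM), split across isoforms
  mix <- config$abundance_mixture
  lw <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (genes$coding[i]) {
      comp <- 1L + (runif(1) >= mix$coding$weight)
      lw[i] <- rnorm(1, mix$coding$means[comp], mix$coding$sds[comp])
    } else {
      lw[i] <- rnorm(1, mix$noncoding$mean, mix$noncoding$sd)
    }
  }
  gene_w <- setNames(10^lw, genes$gene_id)
  prop <- stats::ave(rexp(nrow(isoforms)), isoforms$gene_id,
                     FUN = function(x) x / sum(x))
  w <- gene_w[isoforms$gene_id] * prop
  isoforms$true_tpm <- 1e6 * w / sum(w)
  rownames(isoforms) <- NULL
  list(isoforms = isoforms, iso_exons = do.call(rbind, iso_exon_rows),
       config = config)
}

QCHARS <- strsplit(intToUtf8(33:126), "")[[1]]

#' Simulate paired-end reads with truth coordinates
#'
#' Fragments are allocated to isoforms by a multinomial with probability
#' proportional to `true_tpm * max(length - fragment_mean + 1, 1)`;
#' fragment lengths are Normal(fragment_mean, fragment_sd) truncated to
#' `[read_len/2, transcript length]`; mates read inward from the fragment
#' ends, running into the adapter when the fragment is shorter than a read;
#' fragment orientation is flipped with probability 0.5 (non-stranded
#' library); substitution errors are injected at the rate implied by each
#' base's quality.
#'
#' @param iso output of [generate_transcriptome()], or its `isoforms`
#'   data.frame.
#' @param config a [sim_config()].
#' @param n_pairs number of read pairs.
#' @return data.frame with pair_id, mate sequences/qualities (Phred+33) and
#'   truth columns transcript_id, fragment_start, fragment_end (transcript
#'   coordinates, 0-based half-open) and flipped.
#' @export
simulate_reads <- function(iso, config = iso$config,
                           n_pairs = config$n_pairs) {
  isoforms <- if (is.data.frame(iso)) iso else iso$isoforms
  set.seed(derive_seed(config$seed, "reads"))
  rl <- config$read_len
  min_frag <- as.integer(ceiling(rl / 2))
  usable <- isoforms$length >= min_frag & isoforms$true_tpm > 0
  if (any(!usable & isoforms$true_tpm > 0))
    warnf("%d isoform(s) shorter than the minimum fragment (%d nt) excluded from sampling",
          sum(!usable & isoforms$true_tpm > 0), min_frag)
  isoforms <- isoforms[usable, , drop = FALSE]
  if (nrow(isoforms) == 0 || sum(isoforms$true_tpm) <= 0)
    stopf("no isoforms available for read sampling")
  w <- isoforms$true_tpm *
    pmax(isoforms$length - config$fragment_mean + 1, 1)
  counts <- as.vector(rmultinom(1, n_pairs, w / sum(w)))
  idx <- rep.int(seq_len(nrow(isoforms)), counts)
  idx <- sample(idx)  # interleave isoforms in stream order
  tlen <- isoforms$length[idx]
  flen <- as.integer(round(rnorm(n_pairs, config$fragment_mean,
                                 config$fragment_sd)))
  flen <- pmin(pmax(flen, min_frag), tlen)
  fstart <- as.integer(floor(runif(n_pairs) * (tlen - flen + 1)))
  fend <- fstart + flen
  seqs <- isoforms$sequence[idx]
  take <- pmin(rl, flen)
  left <- substring(seqs, fstart + 1L, fstart + take)
  right <- revcomp(substring(seqs, fend - take + 1L, fend))
  pad <- rl - take
  if (any(pad > 0)) {
    ad <- paste0(config$adapter, strrep("A", rl))
    ext <- substring(ad, 1L, pad)
    left <- paste0(left, ext)
    right <- paste0(right, ext)
  }
  flip <- runif(n_pairs) < 0.5
  m1 <- ifelse(flip, right, left)
  m2 <- ifelse(flip, left, right)

  qm <- config$quality_model
  mean_q <- qm$q_start + (qm$q_end - qm$q_start) *
    (seq_len(rl) - 1) / (rl - 1)
  make_quals <- function(n) {
    Q <- matrix(rep(mean_q, each = n), nrow = n) +
      matrix(rnorm(n * rl, 0, qm$jitter_sd), nrow = n)
    Q <- pmin(pmax(round(Q), qm$q_floor), 41)
    Q
  }
  apply_errors <- function(seqs, Q) {
    if (!config$inject_errors) return(seqs)
    n <- length(seqs)
    err <- matrix(runif(n * rl), nrow = n) < 10^(-Q / 10)
    rows <- which(rowSums(err) > 0)
    if (length(rows) == 0) return(seqs)
    mat <- matrix(unlist(strsplit(seqs[rows], "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(rows), byrow = TRUE)
    hit <- which(err[rows, , drop = FALSE])
    mat[hit] <- vapply(mat[hit],
                       function(b) sample(setdiff(DNA_BASES, b), 1), "")
    seqs[rows] <- do.call(paste0, asplit(mat, 2))
    seqs
  }
  collapse_quals <- function(Q) {
    do.call(paste0, asplit(matrix(QCHARS[Q + 1L], nrow = nrow(Q)), 2))
  }
  Q1 <- make_quals(n_pairs)
  Q2 <- make_quals(n_pairs)
  m1 <- apply_errors(m1, Q1)
  m2 <- apply_errors(m2, Q2)
  data.frame(pair_id = sprintf("pair%07d", seq_len(n_pairs)),
             mate1_seq = m1, mate2_seq = m2,
             mate1_qual = collapse_quals(Q1),
             mate2_qual = collapse_quals(Q2),
             transcript_id = isoforms$transcript_id[idx],
             fragment_start = fstart, fragment_end = fend,
             flipped = flip)
}

#' Write a full synthetic data set to disk
#'
#' Emits genome FASTA, transcripts FASTA (headers `<gene>_seq<k>`), paired
#' FASTQ (Phred+33), truth tables as TSV and the configuration as YAML.
#'
#' @param gen output of [generate_genome()].
#' @param iso output of [generate_transcriptome()].
#' @param reads output of [simulate_reads()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(gen, iso, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             transcripts = file.path(dir, "transcripts.fasta"),
             reads1 = file.path(dir, "reads_1.fastq"),
             reads2 = file.path(dir, "reads_2.fastq"),
             isoforms = file.path(dir, "isoforms.tsv"),
             truth = file.path(dir, "read_truth.tsv"),
             config = file.path(dir, "config.yaml"))
  g <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(g, paths[["genome"]])
  tx <- Biostrings::DNAStringSet(setNames(iso$isoforms$sequence,
                                          iso$isoforms$transcript_id))
  Biostrings::writeXStringSet(tx, paths[["transcripts"]])
  write_fastq(reads$mate1_seq, reads$mate1_qual, reads$pair_id,
              paths[["reads1"]])
  write_fastq(reads$mate2_seq, reads$mate2_qual, reads$pair_id,
              paths[["reads2"]])
  write.table(iso$isoforms[, c("transcript_id", "gene_id", "exon_ranks",
                               "length", "coding", "true_tpm")],
              paths[["isoforms"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(reads[, c("pair_id", "transcript_id", "fragment_start",
                        "fragment_end", "flipped")],
              paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- gen$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Minimal FASTQ I/O (Phred+33)
#'
#' @param seqs,quals,ids parallel character vectors.
#' @param path file path.
#' @return `read_fastq` returns a data.frame (id, seq, qual).
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  stopifnot(length(seqs) == length(quals), length(seqs) == length(ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stopf("truncated FASTQ: %s", path)
  i <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             seq = lines[i + 1], qual = lines[i + 3])
}
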