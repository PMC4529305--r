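# configuration-driven orchestration: synthetic generation (or user
# FASTQ/FASTA) -> QC -> assembly metrics -> abundance -> complexity ->
# completeness -> siRNA design, with a transcriptome-wide report

#' Pipeline configuration
#'
#' One flat configuration with a single master seed; each stochastic
#' stage derives its own seed by stable hashing of the stage name, so a
#' fixed configuration yields an identical run report.
#'
#' @param sim a [sim_config()] for the synthetic input (ignored when
#'   `transcripts_fasta`/`reads_fastq` are given).
#' @param trim a [trim_params()].
#' @param design a [design_params()].
#' @param scoring a [scoring_params()].
#' @param stages character vector of enabled stages, in dependency order.
#' @param n_pairs read pairs to simulate.
#' @param min_codons ORF detection threshold (codons).
#' @param complexity_sample pairs sampled for library complexity.
#' @param rank_cutoff,top_k annotation summary parameters.
#' @param sirna_target Unigene for the design stage (default: the coding
#'   Unigene with the most isoforms, ties by abundance).
#' @param transcripts_fasta,reads_fastq optional paths to user input
#'   replacing the synthetic stage.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            trim = trim_params(),
                            design = design_params(),
                            scoring = scoring_params(),
                            stages = c("synthetic", "qc", "normalize",
                                       "metrics", "abundance",
                                       "complexity", "completeness",
                                       "sirna"),
                            n_pairs = 20000L,
                            min_codons = 100L,
                            complexity_sample = 1e6,
                            rank_cutoff = 10000L,
                            top_k = 30L,
                            sirna_target = NULL,
                            transcripts_fasta = NULL,
                            reads_fastq = NULL,
                            seed = 1L) {
  known <- c("synthetic", "qc", "normalize", "metrics", "abundance",
             "complexity", "completeness", "sirna")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  for (p in c(transcripts_fasta, reads_fastq))
    if (!is.null(p) && !file.exists(p)) stopf("input path missing: %s", p)
  cfg <- list(sim = sim, trim = trim, design = design, scoring = scoring,
              stages = stages, n_pairs = as.integer(n_pairs),
              min_codons = as.integer(min_codons),
              complexity_sample = complexity_sample,
              rank_cutoff = as.integer(rank_cutoff),
              top_k = as.integer(top_k),
              sirna_target = sirna_target,
              transcripts_fasta = transcripts_fasta,
              reads_fastq = reads_fastq,
              seed = as.integer(seed))
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "pipeline_config"
  cfg
}

stage_on <- function(config, stage) stage %in% config$stages

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on synthetic input
#' (default) or user FASTA/FASTQ, re-checking the partition identities of
#' the assembly statistics at report time. Deterministic under a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  report <- list(seed = config$seed, stages = config$stages,
                 timings = c())
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    report$timings[name] <<- round(t1 - tick_t0, 3)
    tick_t0 <<- t1
  }
  tick_t0 <- t0

  transcripts <- NULL
  reads <- NULL
  truth <- NULL
  if (stage_on(config, "synthetic")) {
    gen <- generate_genome(config$sim)
    iso <- generate_transcriptome(gen, config$sim)
    reads <- simulate_reads(iso, config$sim, n_pairs = config$n_pairs)
    transcripts <- data.frame(transcript_id = iso$isoforms$transcript_id,
                              unigene_id = iso$isoforms$gene_id,
                              sequence = iso$isoforms$sequence)
    truth <- iso$isoforms
    report$synthetic <- list(n_genes = nrow(gen$genes),
                             n_isoforms = nrow(iso$isoforms),
                             n_pairs = nrow(reads))
    tick("synthetic")
  } else {
    if (!is.null(config$transcripts_fasta)) {
      fa <- Biostrings::readDNAStringSet(config$transcripts_fasta)
      transcripts <- data.frame(
        transcript_id = sub("\\s.*$", "", names(fa)),
        sequence = as.character(fa))
    }
    if (!is.null(config$reads_fastq)) {
      stopifnot(length(config$reads_fastq) == 2)
      r1 <- read_fastq(config$reads_fastq[1])
      r2 <- read_fastq(config$reads_fastq[2])
      reads <- data.frame(pair_id = r1$id,
                          mate1_seq = r1$seq, mate2_seq = r2$seq,
                          mate1_qual = r1$qual, mate2_qual = r2$qual)
    }
  }

  if (stage_on(config, "qc")) {
    if (is.null(reads)) stopf("stage 'qc' requires reads")
    n_raw <- nrow(reads)
    trimmed <- trim_read_pairs(reads, config$trim)
    reads <- trimmed$pairs
    report$qc <- list(
      stats = base_stats(c(reads$mate1_seq, reads$mate2_seq),
                         c(reads$mate1_qual, reads$mate2_qual),
                         n_raw_reads = 2L * n_raw),
      n_raw_pairs = n_raw,
      n_clean_pairs = nrow(reads),
      rejection_reasons = table(trimmed$rejected$reason))
    tick("qc")
  }

  if (stage_on(config, "normalize")) {
    if (is.null(reads)) stopf("stage 'normalize' requires reads")
    n_in <- nrow(reads)
    reads <- normalize_by_kmer_coverage(reads, config$trim)
    report$normalize <- list(n_in = n_in, n_retained = nrow(reads))
    tick("normalize")
  }

  orfs <- NULL
  unigenes <- NULL
  if (stage_on(config, "metrics")) {
    if (is.null(transcripts)) stopf("stage 'metrics' requires transcripts")
    orfs <- find_orfs(transcripts, min_codons = config$min_codons)
    unigenes <- group_unigenes(transcripts, orfs$transcript_id)
    report$assembly <- assembly_stats(transcripts, orfs, unigenes)
    tick("metrics")
  }

  abundance <- NULL
  alignments <- NULL
  if (stage_on(config, "abundance")) {
    if (is.null(reads) || is.null(transcripts))
      stopf("stage 'abundance' requires reads and transcripts")
    alignments <- map_reads(reads, transcripts)
    abundance <- estimate_abundance(alignments, transcripts, mode = "em",
                                    fragment_mean = config$sim$fragment_mean)
    grouping <- data.frame(
      transcript_id = transcripts$transcript_id,
      unigene_id = if ("unigene_id" %in% names(transcripts))
        transcripts$unigene_id
      else sub("_seq\\d+$", "", transcripts$transcript_id))
    report$abundance <- list(
      n_alignments = nrow(alignments),
      n_concordant_pairs = length(unique(
        alignments$pair_id[alignments$concordant])),
      transcript = abundance,
      unigene = unigene_abundance(abundance, grouping))
    if (!is.null(truth)) {
      m <- match(truth$transcript_id, abundance$transcript_id)
      report$abundance$tpm_spearman <-
        cor(truth$true_tpm, abundance$tpm[m], method = "spearman")
    }
    tick("abundance")
  }

  if (stage_on(config, "complexity")) {
    if (is.null(alignments)) stopf("stage 'complexity' requires abundance")
    report$complexity <- library_complexity(
      alignments, sample_size = config$complexity_sample,
      seed = derive_seed(config$seed, "complexity"))
    tick("complexity")
  }

  if (stage_on(config, "completeness")) {
    if (is.null(orfs)) stopf("stage 'completeness' requires metrics")
    # reference set: the proteins of the coding loci themselves (a
    # fixture-scale core set with known truth)
    refs <- setNames(orfs$protein, orfs$transcript_id)
    refs <- refs[!duplicated(sub("_seq\\d+$", "", names(refs)))]
    names(refs) <- paste0("ref_", sub("_seq\\d+$", "", names(refs)))
    targets <- setNames(orfs$protein, orfs$transcript_id)
    report$completeness <- if (length(refs) > 0)
      completeness_report(refs, targets, config$scoring)
    else data.frame()
    tick("completeness")
  }

  if (stage_on(config, "sirna")) {
    if (is.null(transcripts)) stopf("stage 'sirna' requires transcripts")
    target <- config$sirna_target
    if (is.null(target)) {
      if (is.null(unigenes) || !any(unigenes$coding))
        stopf("stage 'sirna' requires a coding Unigene")
      cand <- unigenes[unigenes$coding, , drop = FALSE]
      cand <- cand[order(-cand$n_coding_isoforms, cand$unigene_id), ]
      target <- cand$unigene_id[1]
    }
    report$sirna <- design_sirna(transcripts, target,
                                 params = config$design,
                                 min_codons = config$min_codons)
    tick("sirna")
  }

  # re-check partition identities at report time
  if (!is.null(report$assembly)) {
    a <- report$assembly
    stopifnot(
      a$n_transcripts_with_orf + a$n_transcripts_without_orf ==
        a$n_transcripts,
      a$n_clusters + a$n_singletons == a$n_unigenes_with_orf,
      a$n_unigenes_with_orf + a$n_unigenes_without_orf == a$n_unigenes)
  }
  report$total_elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  if (!is.null(x$qc)) print(x$qc$stats)
  if (!is.null(x$assembly)) print(x$assembly)
  if (!is.null(x$complexity)) print(x$complexity)
  if (!is.null(x$sirna)) print(x$sirna)
  invisible(x)
}

report_rows <- function(report) {
  rows <- list()
  add <- function(label, value) {
    rows[[length(rows) + 1L]] <<- data.frame(statistic = label,
                                             value = value)
  }
  if (!is.null(report$qc)) {
    s <- report$qc$stats
    add("Total raw reads", s$total_raw_reads)
    add("Total clean reads", s$total_clean_reads)
    add("Total nucleotides", s$total_nucleotides)
    add("Q20 percentage", round(s$q20_pct, 1))
    add("GC percentage", round(s$gc_pct, 1))
  }
  if (!is.null(report$assembly)) {
    a <- report$assembly
    add("Mean length of Trinity transcripts", round(a$mean_length, 1))
    add("N50 of Trinity transcripts", a$n50)
    add("Total Trinity transcripts assembled", a$n_transcripts)
    add("Trinity transcripts without open reading frames",
        a$n_transcripts_without_orf)
    add("Trinity transcripts with open reading frames",
        a$n_transcripts_with_orf)
    add("Total Unigenes", a$n_unigenes)
    add("Unigenes without open reading frames", a$n_unigenes_without_orf)
    add("Unigenes with open reading frames", a$n_unigenes_with_orf)
    add("Distinct protein coding clusters", a$n_clusters)
    add("Distinct protein coding singletons", a$n_singletons)
  }
  if (!is.null(report$complexity)) {
    add("Unpaired library complexity",
        round(report$complexity$unpaired_complexity, 3))
    add("Paired library complexity",
        round(report$complexity$paired_complexity, 3))
  }
  do.call(rbind, rows)
}

#' Write the run report
#'
#' Emits a summary-statistics text table (published row labels), a TSV,
#' and a JSON serialization of the full report.
#'
#' @param report a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_reports <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(outdir, "summary_table.txt"),
             tsv = file.path(outdir, "summary_table.tsv"),
             json = file.path(outdir, "run_report.json"))
  rows <- report_rows(report)
  if (!is.null(rows)) {
    writeLines(sprintf("%-55s %s", rows$statistic,
                       format(rows$value, big.mark = ",",
                              scientific = FALSE, trim = TRUE)),
               paths[["table"]])
    write.table(rows, paths[["tsv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  ser <- report
  ser$timings <- NULL        # wall-clock noise; kept in the R object only
  ser$total_elapsed <- NULL
  ser$sirna <- if (!is.null(report$sirna)) {
    list(target = report$sirna$target_unigene,
         shortlist = report$sirna$shortlist,
         attrition = as.list(report$sirna$attrition))
  }
  ser <- rapply(unclass(ser), unclass, how = "replace")
  jsonlite::write_json(ser, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(paths)
}
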