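# synthetic genome / transcriptome / read generator

test_that("genome generation: empty case, determinism, intron floor", {
  cfg0 <- sim_config(n_genes = 0, seed = 3)
  g0 <- generate_genome(cfg0)
  expect_equal(nrow(g0$genes), 0)
  expect_gt(nchar(g0$genome[[1]]), 0)

  cfg <- sim_config(n_genes = 10, seed = 9)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$exons, g2$exons)

  # exhaustive scan: every intron (gap between consecutive exons of a
  # gene) is at least min_intron
  cfg50 <- sim_config(n_genes = 50, seed = 12)
  g50 <- generate_genome(cfg50)
  for (gid in g50$genes$gene_id) {
    ex <- g50$exons[g50$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) {
      gaps <- ex$start[-1] - ex$end[-nrow(ex)]
      expect_true(all(gaps >= cfg50$min_intron))
    }
  }
  # exons non-overlapping and sorted
  expect_true(all(g50$exons$end > g50$exons$start))
})

test_that("gene models satisfy ORF and strand invariants", {
  s <- small_sim(seed = 21, n_genes = 12)
  chrom <- s$gen$genome[[1]]
  for (i in seq_len(nrow(s$gen$genes))) {
    g <- s$gen$genes[i, ]
    ex <- s$gen$exons[s$gen$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    mature <- paste0(substring(chrom, ex$start + 1, ex$end), collapse = "")
    if (g$strand == "-") mature <- revcomp(mature)
    expect_equal(nchar(mature), g$mature_len)
    if (g$coding) {
      orf <- substr(mature, g$orf_start + 1, g$orf_end)
      expect_equal((g$orf_end - g$orf_start) %% 3, 0)
      expect_equal(substr(orf, 1, 3), "ATG")
      expect_true(substr(orf, nchar(orf) - 2, nchar(orf)) %in%
                    c("TAA", "TAG", "TGA"))
      # stop-free interior
      codons <- substring(orf, seq(1, nchar(orf) - 3, 3),
                          seq(3, nchar(orf) - 3, 3))
      expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("isoform sequences equal spliced exon concatenation; TPM conserved", {
  s <- small_sim(seed = 5, n_genes = 10)
  chrom <- s$gen$genome[[1]]
  strands <- setNames(s$gen$genes$strand, s$gen$genes$gene_id)
  for (i in seq_len(nrow(s$iso$isoforms))) {
    rec <- s$iso$isoforms[i, ]
    ex <- s$iso$iso_exons[s$iso$iso_exons$transcript_id ==
                            rec$transcript_id, ]
    ex <- ex[order(ex$start), ]
    seq <- paste0(substring(chrom, ex$start + 1, ex$end), collapse = "")
    if (strands[[rec$gene_id]] == "-") seq <- revcomp(seq)
    expect_identical(seq, rec$sequence)
  }
  expect_equal(sum(s$iso$isoforms$true_tpm), 1e6, tolerance = 1e-9)
})

test_that("skip variant of a 3-exon gene concatenates exons 1 and 3", {
  # hand-built gene: exons [0,30), [60,90), [120,150) on a plus strand
  chrom <- strrep("A", 0)
  set.seed(1)
  e1 <- random_dna(30); i1 <- random_dna(30)
  e2 <- random_dna(30); i2 <- random_dna(30)
  e3 <- random_dna(30)
  chrom <- paste0(e1, i1, e2, i2, e3)
  ex <- data.frame(gene_id = "g", exon_rank = 1:3,
                   start = c(0, 60, 120), end = c(30, 90, 150))
  skip <- ex[ex$exon_rank != 2, ]
  got <- paste0(substring(chrom, skip$start + 1, skip$end), collapse = "")
  expect_identical(got, paste0(e1, e3))
})

test_that("bimodal abundance mixture is recoverable from generated TPMs", {
  cfg <- sim_config(n_genes = 600, coding_fraction = 1, isoform_mean = 1,
                    max_isoforms = 1, exon_count_range = c(3, 3),
                    exon_len_range = c(100, 120), seed = 8)
  gen <- generate_genome(cfg)
  iso <- generate_transcriptome(gen, cfg)
  lg <- log10(iso$isoforms$true_tpm)
  # two-Gaussian mixture fit on log10 TPM
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this by name
  fit <- suppressWarnings(mclust::Mclust(lg, G = 2, verbose = FALSE))
  mu <- sort(fit$parameters$mean)
  # renormalization shifts both components by a common constant; the
  # separation of the two means is what the mixture fixes
  sep_true <- cfg$abundance_mixture$coding$means[2] -
    cfg$abundance_mixture$coding$means[1]
  n_comp <- pmax(table(fit$classification), 1)
  se <- sqrt(sum(cfg$abundance_mixture$coding$sds^2 / n_comp))
  expect_lt(abs((mu[2] - mu[1]) - sep_true), 3 * se + 0.2)
  # clear bimodality: antimode density below both component modes
  d <- stats::density(lg)
  mid <- mean(mu)
  expect_lt(d$y[which.min(abs(d$x - mid))],
            0.8 * max(d$y))
})

test_that("read sampling follows the stated fragment law", {
  # degenerate sd: all fragments equal fragment_mean (clipped)
  iso1 <- data.frame(transcript_id = "t1", gene_id = "g1",
                     exon_ranks = "1", sequence = random_dna(2000),
                     length = 2000, coding = TRUE, true_tpm = 1e6)
  cfg <- sim_config(fragment_sd = 0, seed = 4)
  rd <- simulate_reads(iso1, cfg, n_pairs = 1000)
  expect_true(all(rd$fragment_end - rd$fragment_start == 275))

  # TPM ratio 3:1 at equal length: fragment counts within binomial 99% CI
  set.seed(2)
  iso2 <- data.frame(transcript_id = c("a", "b"), gene_id = c("ga", "gb"),
                     exon_ranks = "1",
                     sequence = c(random_dna(2000), random_dna(2000)),
                     length = 2000, coding = TRUE,
                     true_tpm = c(7.5e5, 2.5e5))
  n <- 20000
  rd2 <- simulate_reads(iso2, sim_config(seed = 6), n_pairs = n)
  ka <- sum(rd2$transcript_id == "a")
  ci <- qbinom(c(0.005, 0.995), n, 0.75)
  expect_gte(ka, ci[1])
  expect_lte(ka, ci[2])

  # multinomial sampling law: chi-square goodness of fit p > 0.001
  s <- small_sim(seed = 13, n_genes = 8)
  rd3 <- simulate_reads(s$iso, s$cfg, n_pairs = 50000)
  w <- s$iso$isoforms$true_tpm *
    pmax(s$iso$isoforms$length - s$cfg$fragment_mean + 1, 1)
  usable <- s$iso$isoforms$length >= 75
  counts <- table(factor(rd3$transcript_id,
                         levels = s$iso$isoforms$transcript_id[usable]))
  p <- w[usable] / sum(w[usable])
  keep <- p > 1e-6
  gof <- suppressWarnings(chisq.test(as.vector(counts[keep]), p = p[keep],
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
})

test_that("error-free mates are exact transcript slices; adapter read-through", {
  cfg <- sim_config(n_genes = 4, seed = 17, inject_errors = FALSE)
  gen <- generate_genome(cfg)
  iso <- generate_transcriptome(gen, cfg)
  rd <- simulate_reads(iso, cfg, n_pairs = 400)
  tx <- setNames(iso$isoforms$sequence, iso$isoforms$transcript_id)
  rl <- cfg$read_len
  for (i in seq_len(nrow(rd))) {
    s <- tx[[rd$transcript_id[i]]]
    fs <- rd$fragment_start[i]; fe <- rd$fragment_end[i]
    take <- min(rl, fe - fs)
    left <- substr(s, fs + 1, fs + take)
    right <- revcomp(substr(s, fe - take + 1, fe))
    pad <- substr(paste0(cfg$adapter, strrep("A", rl)), 1, rl - take)
    exp1 <- paste0(if (rd$flipped[i]) right else left, pad)
    exp2 <- paste0(if (rd$flipped[i]) left else right, pad)
    expect_identical(rd$mate1_seq[i], exp1)
    expect_identical(rd$mate2_seq[i], exp2)
  }

  # forced read-through: fragment (120 nt) shorter than the 150 nt read
  cfga <- sim_config(n_genes = 2, seed = 19, inject_errors = FALSE,
                     fragment_mean = 120, fragment_sd = 0)
  gena <- generate_genome(cfga)
  isoa <- generate_transcriptome(gena, cfga)
  rda <- simulate_reads(isoa, cfga, n_pairs = 50)
  flen <- rda$fragment_end - rda$fragment_start
  short <- which(flen < 150)
  expect_gt(length(short), 0)
  for (i in short) {
    expect_identical(substr(rda$mate1_seq[i], flen[i] + 1, 150),
                     substr(cfga$adapter, 1, 150 - flen[i]))
  }
})

test_that("written outputs are byte-identical under a fixed config", {
  cfg <- sim_config(n_genes = 6, seed = 23)
  run <- function(dir) {
    gen <- generate_genome(cfg)
    iso <- generate_transcriptome(gen, cfg)
    rd <- simulate_reads(iso, cfg, n_pairs = 300)
    write_simulation(gen, iso, rd, dir)
  }
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- run(d1); p2 <- run(d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
  }
  # FASTQ round trip
  fq <- read_fastq(p1[["reads1"]])
  expect_equal(nrow(fq), 300)
  expect_true(all(nchar(fq$seq) == nchar(fq$qual)))
})
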