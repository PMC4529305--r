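# read mapping, TPM/FPKM estimation, Unigene roll-up, library complexity

test_that("map_reads recovers truth coordinates and multi-maps shared regions", {
  cfg <- sim_config(n_genes = 4, seed = 71, inject_errors = FALSE)
  gen <- generate_genome(cfg)
  iso <- generate_transcriptome(gen, cfg)
  rd <- simulate_reads(iso, cfg, n_pairs = 300)
  tx <- tx_df(iso)
  aln <- map_reads(rd, tx)
  conc <- aln[aln$concordant, ]
  # every pair's truth placement is among its reported placements
  key_truth <- paste(rd$pair_id, rd$transcript_id, rd$fragment_start,
                     rd$fragment_end)
  key_aln <- paste(conc$pair_id, conc$transcript_id, conc$fragment_start,
                   conc$fragment_end)
  expect_true(all(key_truth %in% key_aln))

  # a region shared verbatim by two isoforms yields two records
  shared <- random_dna(500)
  two <- data.frame(transcript_id = c("x_seq1", "x_seq2"),
                    sequence = c(paste0(shared, random_dna(300)),
                                 paste0(shared, random_dna(200))))
  p <- data.frame(pair_id = "p1",
                  mate1_seq = substr(shared, 1, 150),
                  mate2_seq = revcomp(substr(shared, 251, 400)))
  a2 <- map_reads(p, two)
  expect_equal(nrow(a2), 2)
  expect_setequal(a2$transcript_id, c("x_seq1", "x_seq2"))

  # fragment longer than the ceiling is reported discordant
  long_tx <- data.frame(transcript_id = "t", sequence = random_dna(1200))
  pl <- data.frame(pair_id = "p1",
                   mate1_seq = substr(long_tx$sequence, 1, 150),
                   mate2_seq = revcomp(substr(long_tx$sequence, 751, 900)))
  a3 <- map_reads(pl, long_tx, max_fragment = 800)
  expect_equal(nrow(a3), 1)
  expect_false(a3$concordant)
  expect_equal(a3$fragment_end - a3$fragment_start, 900)
})

test_that("abundance closed forms, EM symmetry and conservation", {
  # single transcript: TPM = 1e6 regardless of counts
  tx1 <- data.frame(transcript_id = "t", sequence = random_dna(1500))
  aln1 <- data.frame(pair_id = c("a", "b"), transcript_id = "t",
                     fragment_start = 0, fragment_end = 275,
                     orientation = "F", concordant = TRUE)
  ab1 <- estimate_abundance(aln1, tx1)
  expect_equal(ab1$tpm, 1e6)

  # closed form: counts 10/10, effective lengths 1000 and 2000
  tx2 <- data.frame(transcript_id = c("a", "b"),
                    length = c(1274, 2274))  # el = len - 275 + 1
  aln2 <- data.frame(
    pair_id = c(sprintf("pa%d", 1:10), sprintf("pb%d", 1:10)),
    transcript_id = rep(c("a", "b"), each = 10),
    fragment_start = 0, fragment_end = 100,
    orientation = "F", concordant = TRUE)
  ab2 <- estimate_abundance(aln2, tx2, mode = "uniform")
  expect_equal(ab2$effective_length, c(1000, 2000))
  expect_equal(ab2$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-7)
  expect_equal(ab2$fpkm, 1e9 * 10 / (c(1000, 2000) * 20))

  # two identical transcripts, all pairs multi-mapped: EM splits 50/50
  s <- random_dna(1000)
  tx3 <- data.frame(transcript_id = c("u", "v"), sequence = c(s, s))
  aln3 <- do.call(rbind, lapply(1:40, function(i)
    data.frame(pair_id = paste0("p", i), transcript_id = c("u", "v"),
               fragment_start = i, fragment_end = i + 275,
               orientation = "F", concordant = TRUE)))
  ab3 <- estimate_abundance(aln3, tx3, mode = "em")
  expect_equal(ab3$est_count, c(20, 20), tolerance = 1e-6)
  expect_equal(ab3$tpm, c(5e5, 5e5), tolerance = 1e-3)

  # unique mode drops multi-mappers entirely
  ab3u <- estimate_abundance(aln3, tx3, mode = "unique")
  expect_equal(ab3u$est_count, c(0, 0))
  expect_warning(
    ab0 <- estimate_abundance(aln3[0, ], tx3),
    "no concordant")
  expect_equal(ab0$tpm, c(0, 0))

  # TPM conservation across modes on synthetic data
  cfg <- sim_config(n_genes = 6, seed = 73)
  gen <- generate_genome(cfg)
  iso <- generate_transcriptome(gen, cfg)
  rd <- simulate_reads(iso, cfg, n_pairs = 2000)
  aln <- map_reads(trim_read_pairs(rd)$pairs, tx_df(iso))
  for (mode in c("em", "uniform", "unique")) {
    ab <- estimate_abundance(aln, tx_df(iso), mode = mode)
    expect_equal(sum(ab$tpm), 1e6, tolerance = 1e-6)
    expect_true(all((ab$est_count == 0) == (ab$tpm == 0)))
  }
})

test_that("EM log-likelihood is non-decreasing", {
  # small instance traced by hand-rolled EM with the same model
  set.seed(9)
  tx <- data.frame(transcript_id = c("a", "b", "c"),
                   length = c(500, 800, 1100))
  el <- pmax(tx$length - 275 + 1, 1)
  placements <- list(c(1), c(1, 2), c(2, 3), c(3), c(1, 3), c(2), c(2, 3))
  aln <- do.call(rbind, lapply(seq_along(placements), function(i)
    data.frame(pair_id = paste0("p", i),
               transcript_id = tx$transcript_id[placements[[i]]],
               fragment_start = 0, fragment_end = 100,
               orientation = "F", concordant = TRUE)))
  loglik <- function(theta) {
    sum(vapply(placements, function(pl)
      log(sum(theta[pl] / el[pl] / sum(theta))), 0))
  }
  theta <- rep(1, 3)
  lls <- numeric(30)
  for (it in 1:30) {
    w <- lapply(placements, function(pl) {
      x <- theta[pl] / el[pl]
      x / sum(x)
    })
    theta <- vapply(1:3, function(t)
      sum(unlist(Map(function(pl, ww) sum(ww[pl == t]), placements, w))), 0)
    lls[it] <- loglik(theta)
  }
  expect_true(all(diff(lls) >= -1e-10))
  # package EM lands on the same fixed point
  ab <- estimate_abundance(aln, tx, mode = "em")
  expect_equal(ab$est_count, theta, tolerance = 1e-4)
})

test_that("unigene roll-up sums and preserves TPM", {
  ab <- data.frame(transcript_id = c("g1_seq1", "g1_seq2", "g1_seq3"),
                   est_count = c(1, 2, 3), tpm = c(10, 20, 30),
                   fpkm = c(1, 2, 3))
  gr <- data.frame(transcript_id = ab$transcript_id, unigene_id = "g1")
  u <- unigene_abundance(ab, gr)
  expect_equal(u$tpm, 60)
  # identity grouping returns the input values
  gr2 <- data.frame(transcript_id = ab$transcript_id,
                    unigene_id = ab$transcript_id)
  u2 <- unigene_abundance(ab, gr2)
  expect_equal(sort(u2$tpm), sort(ab$tpm))
  expect_error(unigene_abundance(ab, gr[1:2, ]), "missing from grouping")

  s <- small_sim(seed = 77, n_genes = 5)
  rd <- simulate_reads(s$iso, s$cfg, n_pairs = 1500)
  aln <- map_reads(rd, tx_df(s$iso))
  abx <- estimate_abundance(aln, tx_df(s$iso))
  ug <- unigene_abundance(abx, data.frame(
    transcript_id = s$iso$isoforms$transcript_id,
    unigene_id = s$iso$isoforms$gene_id))
  expect_equal(sum(ug$tpm), 1e6, tolerance = 1e-6)
})

test_that("library complexity equals brute-force set counting", {
  mk <- function(tx, s, e) data.frame(
    pair_id = sprintf("p%d", seq_along(tx)), transcript_id = tx,
    fragment_start = s, fragment_end = e, orientation = "F",
    concordant = TRUE)
  # hand count: mate start keys {(t1,F,10) x2, (t1,F,20), (t2,F,10)}
  a <- mk(c("t1", "t1", "t1", "t2"), c(10, 10, 20, 10),
          c(200, 200, 210, 150))
  r <- library_complexity(a, sample_size = 10, seed = 1)
  o <- oracle_complexity(a)
  expect_equal(r$unpaired_complexity, o$unpaired)
  expect_equal(r$paired_complexity, o$paired)
  # the four forward starts contribute 3 distinct of 4
  expect_equal(length(unique(paste(a$transcript_id, a$fragment_start))) /
                 nrow(a), 0.75)

  # all distinct -> paired 1.0; all identical -> paired 1/n
  b <- mk(rep("t", 5), 1:5, 101:105)
  expect_equal(library_complexity(b, 10, 1)$paired_complexity, 1)
  c2 <- mk(rep("t", 5), rep(3, 5), rep(103, 5))
  expect_equal(library_complexity(c2, 10, 1)$paired_complexity, 1 / 5)

  # random fixtures vs oracle (sample covers everything)
  set.seed(15)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- mk(sample(c("t1", "t2", "t3"), n, TRUE),
            sample(1:20, n, TRUE), sample(100:120, n, TRUE))
    r <- library_complexity(a, sample_size = n, seed = i)
    o <- oracle_complexity(a)
    expect_equal(r$unpaired_complexity, o$unpaired)
    expect_equal(r$paired_complexity, o$paired)
    expect_gte(r$unpaired_complexity, 0)
    expect_lte(r$paired_complexity, 1)
  }

  expect_warning(library_complexity(a[0, ], 10, 1), "no usable")
  expect_error(library_complexity(a, 0, 1), "sample_size")
})
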