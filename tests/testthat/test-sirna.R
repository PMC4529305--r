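# siRNA design: candidate enumeration, scoring, consensus, off-target screen

test_that("candidate enumeration: counts, isoform conservation, oracle", {
  params <- design_params()
  set.seed(3)
  orf <- paste0("ATG", paste(sample(c("GCT", "AAA", "CCG", "GAA"), 7,
                                    TRUE), collapse = ""), "TAA")  # 25 nt
  iso <- c(i1 = orf)
  cands <- enumerate_candidates(iso, c(0, 25), params)
  expect_equal(nrow(cands), 25 - 19 + 1)
  expect_equal(cands$canonical_offset, 0:6)

  # skipped exon upstream of the ORF leaves the candidate set unchanged
  up <- random_dna(120)
  cano <- paste0(up, orf, random_dna(40))
  skip <- paste0(substr(up, 1, 40), orf, random_dna(40))
  c2 <- enumerate_candidates(c(a = cano, b = skip),
                             c(120, 145), params, canonical = "a")
  c1 <- enumerate_candidates(c(a = cano), c(120, 145), params,
                             canonical = "a")
  expect_identical(c2$sequence, c1$sequence)

  # ORF shorter than k: empty with warning
  expect_warning(c0 <- enumerate_candidates(c(x = "ATGAAATAA"), c(0, 9),
                                            params), "shorter")
  expect_equal(nrow(c0), 0)

  # ORF-internal exon missing from one isoform: windows overlapping it
  # vanish; equals the brute-force substring-intersection oracle
  set.seed(13)
  e1 <- random_dna(60); e2 <- random_dna(45); e3 <- random_dna(60)
  cano2 <- paste0(e1, e2, e3)
  skip2 <- paste0(e1, e3)
  span <- c(0, nchar(cano2))
  got <- enumerate_candidates(c(full = cano2, skip = skip2), span, params)
  want <- oracle_candidates(c(full = cano2, skip = skip2), span, 19)
  expect_identical(got$sequence, want)
  # windows strictly inside e2 are gone
  expect_false(any(got$canonical_offset > 60 &
                     got$canonical_offset + 19 <= 105))
  # random-isoform property check against the oracle
  for (i in 1:10) {
    n_iso <- sample(1:3, 1)
    isoforms <- setNames(random_dna(sample(80:150, n_iso, TRUE)),
                         paste0("v", seq_len(n_iso)))
    isoforms[1] <- paste0(isoforms[1])
    span <- c(5, nchar(isoforms[1]) - 5)
    got <- enumerate_candidates(isoforms, span, params)
    expect_identical(got$sequence,
                     oracle_candidates(isoforms, span, 19))
  }
})

test_that("built-in scorers follow their documented rules", {
  # degenerate poly-G candidate takes the composition minimum
  set.seed(21)
  cands <- data.frame(sequence = c(strrep("G", 19),
                                   random_dna(rep(19, 12))))
  sc <- score_composition(cands$sequence)
  expect_equal(which.min(sc), 1)

  # identical candidates except an A/U 3' end: asymmetry prefers A/U
  a <- paste0(random_dna(17), "AA")
  g <- paste0(substr(a, 1, 17), "GG")
  sa <- score_asymmetry(c(a, g))
  expect_gt(sa[1], sa[2])

  # GC scorer peaks inside the 30-52% band
  lo <- strrep("A", 19)                        # 0% GC
  mid <- paste0(strrep("A", 11), strrep("G", 8))  # 42% GC
  hi <- strrep("G", 19)                        # 100% GC
  sg <- score_gc(c(lo, mid, hi))
  expect_equal(which.max(sg), 2)

  # deterministic tie order: equal scores ranked by sequence
  two <- data.frame(sequence = c("TTTTTTTTTTTTTTTTTTT",
                                 "AAAAAAAAAAAAAAAAAAA"))
  ranked <- score_candidates(two, list(const = function(s)
    rep(1, length(s))), design_params(top_n = 2))
  expect_identical(ranked$const$sequence,
                   c("AAAAAAAAAAAAAAAAAAA", "TTTTTTTTTTTTTTTTTTT"))
  expect_error(score_candidates(two, list(bad = "notafun")), "scorer")
})

test_that("consensus selection implements the >=2-of-3 rule", {
  lists <- list(
    s1 = data.frame(sequence = c("A", "B"), score = c(2, 1), rank = 1:2),
    s2 = data.frame(sequence = c("A", "C"), score = c(2, 1), rank = 1:2),
    s3 = data.frame(sequence = c("C"), score = 1, rank = 1L))
  cons <- consensus_select(lists, design_params(min_agree = 2))
  expect_setequal(cons$sequence, c("A", "C"))
  # ordered by number of lists then best rank
  expect_identical(cons$sequence[1], "A")

  # min_agree = 1: union of the lists
  u <- consensus_select(lists, design_params(min_agree = 1))
  expect_setequal(u$sequence, c("A", "B", "C"))
  # threshold above the number of scorers: empty
  expect_equal(nrow(consensus_select(lists, design_params(min_agree = 4))),
               0)
})

test_that("off-target index postings and screen discard rules", {
  params <- design_params()
  set.seed(41)
  L <- 400
  tx <- data.frame(transcript_id = c("g1_seq1", "off_seq1"),
                   sequence = random_dna(c(L, L)))
  idx <- build_offtarget_index(tx, params)
  expect_equal(sum(idx$contig$tx == 1), L - 16 + 1)
  # planted 16-mer is recovered
  km <- substr(tx$sequence[2], 101, 116)
  h <- idx$contig[list(km)]
  expect_true(any(h$tx == 2 & h$pos == 100))

  cand <- substr(tx$sequence[1], 51, 69)
  # candidate occurring only in its own gene: pass
  r <- offtarget_screen(cand, idx, "g1_seq1", params)
  expect_identical(r$verdict, "pass")

  # rule (a) only: off-target carries the candidate with one central
  # substitution -> 18 matching positions, longest run 9 and 9
  cand_mut <- cand
  mid <- substr(cand, 10, 10)
  substr(cand_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  tx_a <- rbind(tx, data.frame(transcript_id = "bad_seq1",
                               sequence = paste0(random_dna(40), cand_mut,
                                                 random_dna(40))))
  idx_a <- build_offtarget_index(tx_a, params)
  ra <- offtarget_screen(cand, idx_a, "g1_seq1", params)
  expect_identical(ra$verdict, "discard")
  expect_true(any(ra$hits$match_type == "hamming_ge" &
                    ra$hits$transcript_id == "bad_seq1"))
  expect_false(any(ra$hits$match_type == "contiguous_ge"))

  # rule (b) only: verbatim 16-mer embedded with the rest scrambled ->
  # Hamming over any window < 18
  frag16 <- substr(cand, 2, 17)
  tx_b <- rbind(tx, data.frame(transcript_id = "bad2_seq1",
                               sequence = paste0(random_dna(60), frag16,
                                                 random_dna(60))))
  idx_b <- build_offtarget_index(tx_b, params)
  rb <- offtarget_screen(cand, idx_b, "g1_seq1", params)
  expect_identical(rb$verdict, "discard")
  expect_true(any(rb$hits$match_type == "contiguous_ge"))

  # reverse-complement orientation is screened by default
  tx_r <- rbind(tx, data.frame(transcript_id = "rc_seq1",
                               sequence = paste0(random_dna(30),
                                                 revcomp(cand),
                                                 random_dna(30))))
  idx_r <- build_offtarget_index(tx_r, params)
  expect_identical(offtarget_screen(cand, idx_r, "g1_seq1",
                                    params)$verdict, "discard")
  expect_identical(offtarget_screen(
    cand, idx_r, "g1_seq1",
    design_params(search_both_orientations = FALSE))$verdict, "pass")

  expect_error(offtarget_screen("ACGT", idx, "g1_seq1", params),
               "length")
})

test_that("screen equals the exhaustive oracle and is monotone", {
  set.seed(51)
  params <- design_params()
  for (i in 1:12) {
    n_tx <- sample(3:6, 1)
    tx <- data.frame(transcript_id = paste0("t", seq_len(n_tx), "_seq1"),
                     sequence = random_dna(sample(150:500, n_tx, TRUE)))
    idx <- build_offtarget_index(tx, params)
    # candidates: a window of t1 plus planted decoys
    cand <- substr(tx$sequence[1], 20, 38)
    members <- "t1_seq1"
    got <- offtarget_screen(cand, idx, members, params)$verdict
    want <- oracle_offtarget(cand, tx, members)
    expect_identical(got, want, label = paste("case", i))

    # monotone: adding transcripts never converts discard -> pass
    extra <- rbind(tx, data.frame(transcript_id = "x_seq1",
                                  sequence = paste0(random_dna(20), cand,
                                                    random_dna(20))))
    got2 <- offtarget_screen(cand, build_offtarget_index(extra, params),
                             members, params)$verdict
    expect_identical(got2, "discard")
  }

  # general (non-pigeonhole) threshold path agrees with the oracle
  p17 <- design_params(ham_discard = 17)
  set.seed(52)
  for (i in 1:5) {
    tx <- data.frame(transcript_id = c("t1_seq1", "t2_seq1"),
                     sequence = random_dna(c(300, 300)))
    cand <- substr(tx$sequence[1], 100, 118)
    got <- offtarget_screen(cand, build_offtarget_index(tx, p17),
                            "t1_seq1", p17)$verdict
    want <- oracle_offtarget(cand, tx, "t1_seq1", ham_discard = 17)
    expect_identical(got, want)
  }
})

test_that("end-to-end design: planted clean region, saturation, determinism", {
  s <- small_sim(seed = 101, n_genes = 10)
  trx <- tx_df(s$iso)
  coding <- unique(s$iso$isoforms$gene_id[s$iso$isoforms$coding])
  rep1 <- design_sirna(trx, coding[1])
  rep2 <- design_sirna(trx, coding[1])
  expect_identical(rep1$shortlist, rep2$shortlist)  # determinism
  expect_true(all(rep1$shortlist$sequence %in% rep1$consensus$sequence))
  expect_true(all(rep1$consensus$sequence %in% rep1$candidates$sequence))
  # no shortlisted candidate has a discarding hit
  for (sq in rep1$shortlist$sequence) {
    expect_identical(rep1$screened[[sq]]$verdict, "pass")
  }

  # transcriptome made of copies of the target under different Unigene
  # ids: everything off-targets, zero survivors
  dup <- trx[trx$unigene_id == coding[1], ]
  clone <- dup
  clone$transcript_id <- sub("^g", "c", clone$transcript_id)
  clone$unigene_id <- sub("^g", "c", clone$unigene_id)
  both <- rbind(dup, clone)
  rep3 <- design_sirna(both, coding[1])
  expect_equal(nrow(rep3$shortlist), 0)

  expect_error(design_sirna(trx, "nosuchgene"), "not in transcriptome")
})

test_that("the validated PRC1 siRNA has the design default length", {
  expect_equal(nchar(prc1_sirna()), design_params()$k)
})
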