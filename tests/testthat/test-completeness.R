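# protein alignment, six-frame translation, search and completeness calls

test_that("global identity matches hand examples and the textbook oracle", {
  p <- scoring_params()
  al <- global_align_identity("MKVL", "MKVL", p)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$query_cov, 1)
  expect_equal(al$target_cov, 1)

  expect_equal(global_align_identity("ACDE", "ACDW", p)$identity_pct, 75)
  expect_error(global_align_identity("AC1E", "ACDE", p), "alphabet")

  # score equivalence against a quadratic-space textbook implementation
  # and against Biostrings::pairwiseAlignment, on random pairs
  set.seed(33)
  submat <- p$submat
  for (i in 1:40) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    got <- global_align_identity(a, b, p)
    expect_equal(got$score,
                 oracle_global_score(a, b, submat, p$gap_open,
                                     p$gap_extend),
                 label = paste("textbook oracle", i))
    bio <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62",
      gapOpening = p$gap_open, gapExtension = p$gap_extend,
      type = "global")
    expect_equal(got$score, Biostrings::score(bio),
                 label = paste("Biostrings oracle", i))
    # the aligned strings really realize the reported score
    ca <- strsplit(got$aligned_a, "")[[1]]
    cb <- strsplit(got$aligned_b, "")[[1]]
    sc <- 0
    run_a <- run_b <- 0
    for (j in seq_along(ca)) {
      if (ca[j] != "-" && cb[j] != "-") {
        sc <- sc + submat[ca[j], cb[j]]; run_a <- run_b <- 0
      } else if (ca[j] == "-") {
        sc <- sc - p$gap_extend - if (run_a == 0) p$gap_open else 0
        run_a <- run_a + 1; run_b <- 0
      } else {
        sc <- sc - p$gap_extend - if (run_b == 0) p$gap_open else 0
        run_b <- run_b + 1; run_a <- 0
      }
    }
    expect_equal(sc, got$score, label = paste("alignment realizes score", i))
  }
})

test_that("six-frame translation follows the stated frame conventions", {
  fr <- six_frame_translate("ATGAAA")
  expect_identical(fr[["F0"]], "MK")
  # reverse-complement frames equal translation of the reverse complement
  nt <- "ATGAAACCCGGGTTTACG"
  fr2 <- six_frame_translate(nt)
  rc <- revcomp(nt)
  for (f in 0:2) {
    n3 <- ((nchar(rc) - f) %/% 3) * 3
    expect_identical(
      fr2[[paste0("R", f)]],
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(rc, f + 1, f + n3)),
        no.init.codon = TRUE)))
  }
  # frame lengths floor((n - f)/3)
  expect_equal(nchar(fr2), setNames(
    rep(floor((nchar(nt) - 0:2) / 3), 2),
    c("F0", "F1", "F2", "R0", "R1", "R2")))
  # stops rendered as '*'
  expect_true(grepl("\\*", six_frame_translate("ATGTAAATG")[["F0"]]))
})

test_that("protein search: planted hits, empty cases, no masking", {
  p <- scoring_params(min_score = 30)
  set.seed(44)
  core <- random_protein(40)
  targets <- c(t1 = paste0(random_protein(25), core, random_protein(30)),
               t2 = random_protein(60))
  hits <- search_protein(core, targets, p)
  expect_equal(hits$target_id[1], "t1")
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$query_cov[1], 1)
  # target coverage spans exactly the planted copy
  expect_equal(hits$t_start[1], 25)
  expect_equal(hits$t_end[1], 65)

  expect_equal(nrow(search_protein(core, character(0), p)), 0)
  # no shared 4-mer: empty result
  expect_equal(nrow(search_protein("WWWWWWWW",
                                   c(a = "GGGGGGGG"), p)), 0)

  # arginine/lysine-rich degenerate peptide still hits its verbatim copy
  degen <- paste0("RRKRKRRKRK", "RRRKKKARSM", "RKRKA")
  t3 <- c(host = paste0(random_protein(20), degen, random_protein(20)))
  h3 <- search_protein(degen, t3, p)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$identity_pct[1], 100)

  # top-hit score equals full Smith-Waterman (Biostrings oracle)
  for (i in 1:15) {
    q <- random_protein(sample(10:60, 1))
    t <- paste0(random_protein(10), substr(q, 3, 25), random_protein(15))
    h <- search_protein(q, c(x = t), scoring_params(min_score = 1))
    if (nrow(h) > 0) {
      bio <- Biostrings::pairwiseAlignment(
        q, t, substitutionMatrix = "BLOSUM62", gapOpening = 11,
        gapExtension = 1, type = "local")
      expect_equal(h$score[1], Biostrings::score(bio))
    }
  }
})

test_that("completeness classification applies the 70% coverage rule", {
  p <- scoring_params()
  hits <- data.frame(target_id = "t", score = 100, identity_pct = 90,
                     query_cov = 1.0, target_cov = 0.8,
                     q_start = 0L, q_end = 10L, t_start = 0L, t_end = 10L)
  expect_identical(classify_completeness("r", hits, p)$status, "complete")
  hits$query_cov <- 0.5
  expect_identical(classify_completeness("r", hits, p)$status, "partial")
  expect_identical(classify_completeness("r", hits[0, ], p)$status,
                   "absent")
  # monotone: increasing coverage never demotes the status
  rank <- c(absent = 0, partial = 1, complete = 2)
  prev <- -1
  for (cov in c(0.1, 0.5, 0.69, 0.7, 0.9, 1.0)) {
    hits$query_cov <- cov
    st <- rank[[classify_completeness("r", hits, p)$status]]
    expect_gte(st, prev)
    prev <- st
  }

  # a proteome containing every reference verbatim: all complete, cov 1.0
  set.seed(55)
  refs <- setNames(vapply(1:8, function(i) random_protein(80), ""),
                   paste0("ref", 1:8))
  targets <- setNames(paste0(vapply(1:8, function(i) random_protein(10), ""),
                             refs, vapply(1:8, function(i)
                               random_protein(12), "")),
                      paste0("t", 1:8))
  rep <- completeness_report(refs, targets, p)
  expect_true(all(rep$status == "complete"))
  expect_true(all(rep$coverage == 1.0))
})

test_that("most abundant full-length isoform selection walks by TPM", {
  p <- scoring_params()
  set.seed(66)
  ref <- random_protein(120)
  full <- ref                               # identical, full-length
  trunc <- substr(ref, 1, 60)               # 50% truncated
  proteins <- data.frame(transcript_id = c("i1", "i2"),
                         protein = c(full, trunc))
  tpm <- c(i1 = 5, i2 = 10)
  # i2 is more abundant but truncated: i1 must be chosen
  sel <- most_abundant_full_length(proteins, tpm, ref, p)
  expect_identical(sel$transcript_id, "i1")
  expect_equal(sel$n_tried, 2)

  # single full-length isoform chosen trivially
  sel2 <- most_abundant_full_length(proteins[1, ], tpm["i1"], ref, p)
  expect_identical(sel2$transcript_id, "i1")

  # no coding isoform
  sel3 <- most_abundant_full_length(proteins[0, ], tpm, ref, p)
  expect_true(is.na(sel3$transcript_id))
  expect_match(sel3$reason, "no coding")

  # length-ratio bounds bracket the published spread (87.7%-106.3%)
  near <- substr(ref, 1, 106)   # ratio 0.883
  sel4 <- most_abundant_full_length(
    data.frame(transcript_id = "i3", protein = near), c(i3 = 1), ref, p)
  expect_identical(sel4$transcript_id, "i3")
  short <- substr(ref, 1, 90)   # ratio 0.75, out of bounds
  sel5 <- most_abundant_full_length(
    data.frame(transcript_id = "i4", protein = short), c(i4 = 1), ref, p)
  expect_true(is.na(sel5$transcript_id))
})
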