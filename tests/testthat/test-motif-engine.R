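# PFM construction, the information-weighted similarity score, and scanning.

test_that("matrix similarity reproduces the hand-computed toy example", {
  f <- cbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.4, 0.3, 0.2, 0.1),
             c(0.1, 0.1, 0.1, 0.7))
  pfm <- stat1mod:::new_pfm(f, n_seqs = 10, id = "toy")
  # w = 2 + sum f log2 f, computed by hand for these columns
  expect_equal(pfm$w, c(0.643220350553, 0.153560655329, 0.643220350553),
               tolerance = 1e-9)
  # consensus ("ATT") scores exactly 1
  expect_equal(pfm_consensus(pfm), "AAT")
  expect_equal(matrix_similarity(pfm, "AAT"), 1)
  # hand-computed ratio for "AGT":
  # (w1*0.7 + w2*0.2 + w3*0.7) / (w1*0.7 + w2*0.4 + w3*0.7)
  expect_equal(matrix_similarity(pfm, "AGT"), 0.968072475989,
               tolerance = 1e-9)
  # N contributes the position minimum
  byhand <- (pfm$w[1] * 0.7 + pfm$w[2] * 0.1 + pfm$w[3] * 0.7) /
    (pfm$w[1] * 0.7 + pfm$w[2] * 0.4 + pfm$w[3] * 0.7)
  expect_equal(matrix_similarity(pfm, "ANT"), byhand, tolerance = 1e-12)

  expect_error(matrix_similarity(pfm, "AATT"), "width")
  uniform <- stat1mod:::new_pfm(matrix(0.25, 4, 3), n_seqs = 1)
  expect_error(matrix_similarity(uniform, "AAT"), "zero-information")
})

test_that("identical seeds give a near-one-hot, high-information matrix", {
  pfm <- pfm_from_alignment(rep("TTCCCGGAA", 50))
  expect_true(all(pfm$w > 1.8))
  expect_true(all(pfm$w <= 2))
  expect_equal(matrix_similarity(pfm, "TTCCCGGAA"), 1)
  expect_true(all(abs(apply(pfm$f, 2, max) - 50.25 / 51) < 1e-12))
})

test_that("seed-based matrix building reproduces the worked 10-seed
           example", {
  seeds <- c(rep("TTCCAGGAAA", 6), rep("TTCCTGGAAA", 4))
  pfm <- build_matrix_from_seeds(seeds)
  # the qualifying shared 8-mers tie; lexicographic order picks CCAGGAAA
  expect_equal(pfm$tuple, "CCAGGAAA")
  expect_equal(pfm$width, 10)
  # the one-mismatch variants score ~0.904 against the provisional matrix
  # and are retained at the 0.9 inclusion threshold, so the final column 5
  # frequencies are the 6:4 base mixture up to pseudocounts
  expect_equal(pfm$n_seqs, 10)
  expect_equal(unname(pfm$f["A", 5]), 6.25 / 11, tolerance = 1e-12)
  expect_equal(unname(pfm$f["T", 5]), 4.25 / 11, tolerance = 1e-12)
  expect_equal(unname(pfm$f["A", 9]), 10.25 / 11, tolerance = 1e-12)

  # input order does not matter
  set.seed(31)
  pfm2 <- build_matrix_from_seeds(sample(seeds))
  expect_equal(pfm2$f, pfm$f)

  # raising the inclusion threshold excludes the variants again
  strict <- build_matrix_from_seeds(seeds, include_threshold = 0.95)
  expect_equal(strict$n_seqs, 6)
  expect_equal(unname(strict$f["A", 5]), 6.25 / 7, tolerance = 1e-12)
})

test_that("unrelated seeds fail with the best achieved fraction reported", {
  set.seed(37)
  rnd <- vapply(1:10, function(i) random_dna_string(20), character(1))
  # independent census: confirm no 8-mer reaches 60% presence
  km <- lapply(rnd, function(s) unique(substring(s, 1:13, 8:20)))
  best <- max(table(unlist(km)))
  expect_lt(best / 10, 0.6)
  expect_error(build_matrix_from_seeds(rnd), "no 8-mer")
  expect_error(build_matrix_from_seeds(rnd), "best")
})

test_that("consensus maximality and score bounds hold for random matrices", {
  set.seed(41)
  for (i in 1:10) {
    pfm <- random_pfm()
    expect_equal(matrix_similarity(pfm, pfm_consensus(pfm)), 1)
    for (j in 1:20) {
      s <- matrix_similarity(pfm, random_dna_string(pfm$width))
      expect_gt(s, 0)
      expect_lte(s, 1)
    }
  }
})

test_that("scanning finds a planted consensus and respects strand
           symmetry", {
  # a decidedly non-palindromic consensus: its reverse complement scores
  # far below threshold, so exactly one (+) call is expected
  pfm <- pfm_from_alignment(rep("GGGACTTTCC", 20), id = "NFKB")
  bg <- paste(rep("C", 1200), collapse = "")
  seq1 <- bg
  tss <- 1000L
  substr(seq1, tss - 100 + 1, tss - 100 + 10) <- "GGGACTTTCC"  # start -100
  ps <- promoter_set("g1", seq1, tss)
  calls <- scan_promoters(ps, pfm, threshold = 0.8)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, -100)
  expect_equal(calls$end, -90)
  expect_equal(calls$strand, "+")
  expect_equal(calls$score, 1)

  # the reverse-complemented promoter yields the mirrored call
  ps_rc <- promoter_set("g1", revcomp(seq1), nchar(seq1) - tss - 1L)
  calls_rc <- scan_promoters(ps_rc, pfm, threshold = 0.8,
                             upstream = 50, downstream = 950)
  expect_equal(nrow(calls_rc), 1)
  expect_equal(calls_rc$strand, "-")
  expect_equal(calls_rc$score, 1)
  # mirrored interval: start_rc = 1 - end relative to the mirrored TSS
  expect_equal(calls_rc$start, 1 - calls$end)
})

test_that("the compiled scan kernel matches the reference R scorer", {
  set.seed(43)
  pfms <- seed_pfms()
  sim <- simulate_promoters(promoter_sim_config(
    n_promoters = 6, length = 300, tss_offset = 200,
    plant_window = c(-150, 50), target_set_size = 3, seed = 43))
  for (id in c("GAS", "NFKB")) {
    got <- scan_promoters(sim$promoters, pfms[[id]], threshold = 0.6,
                          upstream = 150, downstream = 50)
    want <- reference_scan(sim$promoters, pfms[[id]], threshold = 0.6,
                           upstream = 150, downstream = 50)
    key <- function(d) d[order(d$gene, d$start, d$strand),
                         c("gene", "start", "end", "strand")]
    expect_equal(key(got), key(want), ignore_attr = TRUE)
    expect_equal(got$score[order(got$gene, got$start, got$strand)],
                 want$score[order(want$gene, want$start, want$strand)],
                 tolerance = 1e-12)
  }
})

test_that("threshold monotonicity: stricter thresholds give nested call
           sets", {
  set.seed(47)
  sim <- simulate_promoters(promoter_sim_config(
    n_promoters = 40, target_set_size = 10, seed = 47))
  pfms <- seed_pfms()
  loose <- scan_promoters(sim$promoters, pfms, threshold = 0.75)
  strict <- scan_promoters(sim$promoters, pfms, threshold = 0.85)
  keyset <- function(d) paste(d$gene, d$matrix, d$start, d$strand)
  expect_true(all(keyset(strict) %in% keyset(loose)))
  expect_true(all(strict$score >= 0.85))
  expect_true(all(loose$score >= 0.75))
})

test_that("score-1.0 calls coincide with planted exact-consensus
           positions", {
  sim <- simulate_promoters(promoter_sim_config(n_promoters = 50,
                                                target_set_size = 10,
                                                seed = 53))
  consensus <- default_motif_consensus()
  # matrices straight from the planted consensus: every planted instance
  # must come back as a score-1.0 call at its manifest position
  pfms <- lapply(consensus, function(s) pfm_from_alignment(rep(s, 20)))
  calls <- scan_promoters(sim$promoters, pfms)
  perfect <- calls[abs(calls$score - 1) < 1e-9, ]
  st <- sim$truth$sites
  manifest_keys <- paste(st$promoter, st$class, st$rel_start, st$strand)
  call_keys <- paste(perfect$gene, perfect$matrix, perfect$start,
                     perfect$strand)
  expect_true(all(manifest_keys %in% call_keys))
})

test_that("scan window errors when shorter than the matrix", {
  pfm <- pfm_from_alignment(rep("TTCCCGGAA", 5))
  ps <- promoter_set("g1", paste(rep("A", 30), collapse = ""), 25L)
  expect_error(scan_promoters(ps, pfm, upstream = 2, downstream = 2),
               "window shorter")
})

test_that("PFM TSV round-trip and JASPAR-like count input", {
  pfm <- seed_pfms()$GAS
  tf <- tempfile(fileext = ".tsv")
  write_pfm_tsv(pfm, tf)
  back <- read_pfm_tsv(tf, id = "GAS")
  expect_equal(back$f, pfm$f, tolerance = 1e-8)
  expect_equal(back$w, pfm$w, tolerance = 1e-7)
  unlink(tf)

  cf <- tempfile(fileext = ".tsv")
  counts <- data.frame(A = c(8, 0), C = c(2, 0), G = c(0, 10), T = c(0, 0))
  write.table(counts, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  jp <- read_pfm_tsv(cf)
  expect_equal(jp$width, 2)
  expect_equal(unname(jp$f["A", 1]), 8.25 / 11, tolerance = 1e-12)
  expect_equal(unname(jp$f["G", 2]), 10.25 / 11, tolerance = 1e-12)
  unlink(cf)
})
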