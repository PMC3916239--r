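# PWM construction, file round-trip, window scoring and consensus.

test_that("log-odds weights match the hand-evaluated formula", {
  # Identity case: three identical sites, no pseudocount.
  pwm <- build_pwm(site_set(c("GCCGAAA", "GCCGAAA", "GCCGAAA")),
                   pseudocount = 0)
  expect_identical(pwm_consensus(pwm), "GCCGAAA")
  # Observed base: log2((3/3)/0.25) = 2 at every position.
  expect_equal(pwm_max_score(pwm), 14)
  expect_equal(score_at(pwm, "GCCGAAA", 1), 14)
  # Unobserved bases with pseudocount 0 are -Inf sentinels.
  expect_identical(unname(pwm$weights[1, "A"]), -Inf)

  # Hand evaluation: T at position 4 of {ACGT, ACGT, ACGA}, pseudocount 1.
  pwm2 <- build_pwm(site_set(c("ACGT", "ACGT", "ACGA")), pseudocount = 1)
  expect_equal(unname(pwm2$weights[4, "T"]), log2(((2 + 0.25) / (3 + 1)) / 0.25))
  expect_equal(unname(pwm2$weights[4, "A"]), log2(((1 + 0.25) / 4) / 0.25))
  expect_equal(unname(pwm2$weights[4, "C"]), log2((0.25 / 4) / 0.25))
})

test_that("site sets validate their alignment invariants", {
  expect_error(site_set(c("ACGT", "ACG")), "ragged")
  expect_error(site_set(character(0)), "at least one")
  expect_error(site_set("ACNT"), "alphabet")
  expect_error(site_set("ACG"), "at least 4")
  expect_error(build_pwm(site_set("ACGT"), pseudocount = -1), "non-negative")
  expect_error(build_pwm(site_set("ACGT"), background = c(1, 1, 1, 1)),
               "sum to 1")
})

test_that("matrix files round-trip bit-exactly and reject malformed input", {
  pw <- default_pwms()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(pw$helper, f)
  m <- load_matrix(f)
  expect_identical(m$weights, pw$helper$weights)
  expect_identical(m$cutoff, pw$helper$cutoff)
  expect_identical(m$motif, "HELPER")
  # Saving the loaded matrix reproduces the file byte-for-byte.
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f2)
  expect_identical(readLines(f), readLines(f2))

  # Single-position matrix: width 1, max score 1.
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# motif=HMG cutoff=0.5", "pos\tA\tC\tG\tT", "1\t1\t0\t0\t0"), f3)
  m1 <- load_matrix(f3)
  expect_identical(m1$width, 1L)
  expect_equal(pwm_max_score(m1), 1)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# motif=HMG cutoff=1", "pos\tA\tC\tG\tT", "1\t1\tx\t0\t0"), f4)
  expect_error(load_matrix(f4), "non-numeric cell.*column C")
  f5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# motif=HMG cutoff=1", "pos\tA\tC\tG"), f5)
  expect_error(load_matrix(f5), "")
  f6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# motif=HMG cutoff=1", "pos\tA\tC\tG\tT"), f6)
  expect_error(load_matrix(f6), "width 0")
  # A cutoff above the maximum attainable score can never fire.
  f7 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# motif=HMG cutoff=5", "pos\tA\tC\tG\tT", "1\t1\t0\t0\t0"), f7)
  expect_error(load_matrix(f7), "never fire")
})

test_that("window scoring handles strands, N and bounds", {
  pwm <- toy_helper_pwm()
  expect_equal(score_at(pwm, pwm_consensus(pwm), 1), pwm_max_score(pwm))
  # Strand symmetry: a minus-strand score equals the plus-strand score of
  # the reverse-complemented sequence at the mirrored offset.
  withr::with_seed(11, {
    for (i in 1:20) {
      seq <- random_dna(40)
      s <- sample.int(40 - pwm$width + 1, 1)
      mirrored <- nchar(seq) - s - pwm$width + 2
      expect_equal(score_at(pwm, seq, s, "+"),
                   score_at(pwm, brute_revcomp(seq), mirrored, "-"))
    }
  })
  expect_identical(score_at(pwm, "GCCNAAA", 1), -Inf)
  expect_error(score_at(pwm, "GCCGAAA", 2), "out of range")
  expect_error(score_at(pwm, "GCCGAAA", 0), "out of range")
})

test_that("scan matches exhaustive enumeration and a reference scorer", {
  pwm <- toy_helper_pwm()
  withr::with_seed(23, {
    for (i in 1:40) {
      seq <- random_dna(sample(60:300, 1))
      cutoff <- sample(c(2, 4, 6), 1)
      got <- scan_pwm(pwm, seq, cutoff = cutoff)
      want <- brute_scan(pwm, seq, cutoff = cutoff)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score)
    }
  })
  # Independent reference: Biostrings window scores on the plus strand.
  seq <- withr::with_seed(5, random_dna(200))
  bs <- Biostrings::PWMscoreStartingAt(
    t(pwm$weights), Biostrings::DNAString(seq),
    starting.at = 1:(200 - pwm$width + 1))
  mine <- vapply(1:(200 - pwm$width + 1),
                 function(s) score_at(pwm, seq, s, "+"), numeric(1))
  expect_equal(mine, unname(bs))
})

test_that("scan respects cutoff monotonicity and strand symmetry of scores", {
  pwm <- toy_helper_pwm()
  withr::with_seed(31, {
    for (i in 1:10) {
      seq <- random_dna(400)
      cuts <- c(1, 3, 5, 7)
      hits <- lapply(cuts, function(ct) scan_pwm(pwm, seq, cutoff = ct))
      for (k in 2:length(cuts)) {
        lo <- hits[[k - 1]]; hi <- hits[[k]]
        # Raising the cutoff never adds hits: hit sets are nested.
        expect_true(all(paste(hi$start, hi$strand) %in%
                          paste(lo$start, lo$strand)))
      }
      # Multiset of hit scores is invariant under reverse complement.
      fwd <- scan_pwm(pwm, seq, cutoff = 3)
      rev <- scan_pwm(pwm, brute_revcomp(seq), cutoff = 3)
      expect_equal(sort(fwd$score), sort(rev$score))
      # Positions map by x -> L - x - width + 2.
      expect_setequal(nchar(seq) - fwd$start - pwm$width + 2, rev$start)
    }
  })
})

test_that("scanning degenerate regions behaves", {
  pwm <- toy_helper_pwm()
  expect_identical(nrow(scan_pwm(pwm, strrep("N", 100))), 0L)
  expect_identical(nrow(scan_pwm(pwm, "ACG")), 0L)  # shorter than the motif
})

test_that("consensus derivation follows the degeneracy rule", {
  expect_identical(derive_consensus("GCCGAAA")$iupac, "GCCGAAA")
  expect_identical(derive_consensus(c("AAAA", "CCCC", "GGGG", "TTTT"))$iupac,
                   "nnnn")
  # The eight-site Helper alignment yields the two-letter R/W codes and one
  # fully degenerate position.
  expect_identical(derive_consensus(helper_sites_synthetic(FALSE))$iupac,
                   "GCCRAnW")
  # Idempotence: the consensus of a PWM, fed back as a single site,
  # returns itself.
  pwm <- toy_helper_pwm()
  expect_identical(derive_consensus(pwm_consensus(pwm))$iupac,
                   pwm_consensus(pwm))
  # Majority fraction above 1/2 drops minority bases instead of extending
  # the code.
  cm <- derive_consensus(c("AAAA", "AAAA", "AAAT"), majority_fraction = 0.5)
  expect_identical(cm$iupac, "AAAA")
  expect_equal(unname(cm$per_position_counts[4, "T"]), 1L)
})

test_that("site files parse as FASTA or plain text", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "GCCGAAA site one", "GCCAATT site two"), f)
  ss <- read_sites(f, motif = "HELPER")
  expect_identical(ss$sites, c("GCCGAAA", "GCCAATT"))
  expect_identical(ss$labels, c("site one", "site two"))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "GCCGAAA", ">b", "GCCAATT"), fa)
  expect_identical(read_sites(fa, motif = "HELPER")$sites,
                   c("GCCGAAA", "GCCAATT"))
})
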