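test_that("build_pwm computes pseudocounted frequencies and log-odds", {
  pwm <- build_pwm(c("ACG", "ACG", "ACT"), pseudocount = 0)
  expect_equal(unname(pwm$frequencies[3, c("G", "T")]), c(2 / 3, 1 / 3))
  expect_equal(unname(pwm$log_odds[1, "A"]), 2)
  expect_equal(pwm$consensus, "ACG")
  expect_equal(rowSums(pwm$frequencies), rep(1, 3), tolerance = 1e-9)

  homo <- build_pwm(rep("AAAA", 5), pseudocount = 0)
  expect_equal(homo$consensus, "AAAA")
  expect_equal(score_window(homo, "AAAA"), 8)
  # unseen bases get -Inf log-odds at zero pseudocount (documented)
  expect_true(all(is.infinite(homo$log_odds[, "C"])))

  single <- build_pwm("A", pseudocount = 0.25)
  expect_equal(unname(single$frequencies[1, "A"]), 0.625)

  expect_error(build_pwm(character()), "empty training set")
  expect_error(build_pwm(c("AC", "ACG")), "same length")
  expect_error(build_pwm("ACGN"), "non-ACGT")
})

test_that("pseudocounted frequency rows always sum to one", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    w <- sample(1:12, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), w,
                                      replace = TRUE), collapse = ""))
    pwm <- build_pwm(seqs, pseudocount = runif(1, 0, 2))
    expect_equal(rowSums(pwm$frequencies), rep(1, w), tolerance = 1e-9)
  }
})

test_that("score_window matches the independent oracle on both strands", {
  set.seed(5)
  training <- replicate(12, paste(sample(c("A", "C", "G", "T"), 6,
                                         replace = TRUE), collapse = ""))
  pwm <- build_pwm(training)
  for (i in 1:20) {
    win <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                 collapse = "")
    expect_equal(score_window(pwm, win, "+"), oracle_score(training, win))
    # minus-strand score is the plus-strand score of the reverse complement
    expect_equal(score_window(pwm, win, "-"),
                 oracle_score(training, oracle_revcomp(win)))
  }
  # consensus achieves the maximum possible score
  cons_score <- score_window(pwm, pwm$consensus)
  expect_equal(cons_score, sum(apply(pwm$log_odds, 1, max)))
  # palindromic window scores equal on both strands
  pal <- "ACGCGT"
  expect_equal(score_window(pwm, pal, "+"), score_window(pwm, pal, "-"))
  expect_error(score_window(pwm, "ACG"), "width")
  expect_error(score_window(pwm, "ACGTNN"), "non-ACGT")
})

test_that("calibrate_threshold implements the nearest-rank percentile", {
  # four training sequences spanning a range of scores (one interior tie)
  training <- c("AAAA", "AAAT", "AATT", "ATTT")
  pwm <- build_pwm(training, pseudocount = 0.25)
  scores <- sort(vapply(training, function(s) score_window(pwm, s),
                        numeric(1), USE.NAMES = FALSE), decreasing = TRUE)
  expect_equal(calibrate_threshold(pwm, training, 100)$score, scores[4])
  expect_equal(calibrate_threshold(pwm, training, 50)$score, scores[2])
  expect_equal(calibrate_threshold(pwm, training, 25)$score, scores[1])
  expect_error(calibrate_threshold(pwm, character(), 50),
               "empty training set")

  # contract: admitted fraction >= percentile/100, threshold is the largest
  # score with that property
  set.seed(9)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    train <- replicate(n, paste(sample(c("A", "C", "G", "T"), 5,
                                       replace = TRUE), collapse = ""))
    p <- runif(1, 1, 100)
    pw <- build_pwm(train)
    thr <- calibrate_threshold(pw, train, p)
    sc <- vapply(train, function(s) score_window(pw, s), numeric(1))
    frac <- mean(sc >= thr$score)
    expect_gte(frac, p / 100)
    higher <- sort(unique(sc[sc > thr$score]))
    if (length(higher) > 0) {
      expect_lt(mean(sc >= higher[1]), p / 100)
    }
    expect_equal(thr$n_training, n)
  }
})

test_that("scan_sequence reports thresholded hits on both strands", {
  pwm <- build_pwm("AAC", pseudocount = 0)
  cons <- score_window(pwm, "AAC")
  hits <- scan_sequence(pwm, "AACGTT", cons)
  expect_equal(hits$start, c(1, 4))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$matched_seq, c("AAC", "GTT"))

  expect_equal(nrow(scan_sequence(pwm, "CCCCCC", cons)), 0)
  # threshold -Inf admits every window on both strands
  expect_equal(nrow(scan_sequence(pwm, "ACGTACGT", -Inf)), 2 * (8 - 3 + 1))
  expect_equal(nrow(scan_sequence(pwm, "ACGTACGT", -Inf,
                                  strands = "forward")), 8 - 3 + 1)
  expect_error(scan_sequence(pwm, "AC", 0), "shorter")
})

test_that("scan_sequence agrees with exhaustive window enumeration", {
  set.seed(21)
  for (i in 1:6) {
    training <- replicate(8, paste(sample(c("A", "C", "G", "T"), 4,
                                          replace = TRUE), collapse = ""))
    pwm <- build_pwm(training)
    seqn <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
    thr <- calibrate_threshold(pwm, training, 50)$score
    got <- scan_sequence(pwm, seqn, thr)
    want <- oracle_scan(training, seqn, thr)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score)
  }
})

test_that("scanning the reverse complement mirrors starts and strands", {
  set.seed(33)
  training <- replicate(10, paste(sample(c("A", "C", "G", "T"), 5,
                                         replace = TRUE), collapse = ""))
  pwm <- build_pwm(training)
  for (i in 1:8) {
    L <- sample(20:60, 1)
    seqn <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    thr <- sort(vapply(training, function(s) score_window(pwm, s),
                       numeric(1)))[3]
    fwd <- scan_sequence(pwm, seqn, thr)
    rev <- scan_sequence(pwm, oracle_revcomp(seqn), thr)
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(fwd$score), sort(rev$score))
    mirrored <- sort(L - pwm$width + 2 - rev$start)
    expect_equal(sort(fwd$start), mirrored)
    flipped <- table(factor(rev$strand, levels = c("+", "-")))
    expect_equal(unname(flipped[["+"]]), sum(fwd$strand == "-"))
  }
})

test_that("site counts are non-increasing in the threshold", {
  set.seed(14)
  training <- replicate(10, paste(sample(c("A", "C", "G", "T"), 5,
                                         replace = TRUE), collapse = ""))
  pwm <- build_pwm(training)
  seqn <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  thresholds <- seq(-10, 10, by = 2)
  counts <- vapply(thresholds,
                   function(t) nrow(scan_sequence(pwm, seqn, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  means <- vapply(thresholds[c(3, 6, 9)], function(t) {
    scramble_null(pwm, seqn, t, n_scrambles = 20, seed = 2)$scramble_mean
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("scramble_null preserves composition and degenerate cases", {
  polyA <- build_pwm(rep("AAAA", 3), pseudocount = 0)
  # permuting a homopolymer is a no-op: always 17 forward windows, and the
  # minus strand needs TTTT which scores -Inf
  null <- scramble_null(polyA, strrep("A", 20), threshold = 0,
                        n_scrambles = 10, seed = 4)
  expect_equal(null$scramble_mean, 17)
  expect_equal(unique(null$scramble_counts), 17)
  expect_equal(null$n_scrambles, 10)
  expect_equal(null$rng_seed, 4)

  # a motif requiring G can never hit a sequence of only A/C (no G for the
  # forward strand, no T to complement into one on the minus strand)
  needG <- build_pwm(c("AG", "AG"), pseudocount = 0)
  thr <- score_window(needG, "AG")
  n2 <- scramble_null(needG, "AACCAACCAC", thr, n_scrambles = 15, seed = 1)
  expect_equal(n2$scramble_mean, 0)

  # identical seed gives identical draws; caller RNG is untouched
  a <- scramble_null(polyA, "AAACCC", -Inf, n_scrambles = 5, seed = 7)
  b <- scramble_null(polyA, "AAACCC", -Inf, n_scrambles = 5, seed = 7)
  expect_identical(a$scramble_counts, b$scramble_counts)
  set.seed(99); before <- runif(1)
  set.seed(99); scramble_null(polyA, "AAACCC", 0, 3, seed = 1)
  expect_identical(runif(1), before)
})

test_that("scramble mean matches exact permutation expectation (toy case)", {
  # two-letter alphabet, width 2, L = 6: enumerate all distinct orderings of
  # the multiset and compute the exact expected hit count
  pwm <- build_pwm("AA", pseudocount = 0)
  thr <- score_window(pwm, "AA")
  chars <- c("A", "A", "A", "C", "C", "C")
  perms <- distinct_perms(chars)
  exact <- mean(vapply(perms, function(p) {
    seqn <- paste(p, collapse = "")
    nrow(oracle_scan("AA", seqn, thr, pseudocount = 0))
  }, numeric(1)))
  null <- scramble_null(pwm, paste(chars, collapse = ""), thr,
                        n_scrambles = 1000, seed = 11)
  se <- sd(null$scramble_counts) / sqrt(null$n_scrambles)
  expect_lt(abs(null$scramble_mean - exact), 3 * se)
})

test_that("enrichment_report tabulates counts per factor reproducibly", {
  set.seed(2)
  pwms <- list(
    fx = build_pwm(replicate(10, paste(sample(c("A", "C", "G", "T"), 4,
                                              TRUE), collapse = ""))),
    fy = build_pwm(replicate(10, paste(sample(c("A", "C", "G", "T"), 4,
                                              TRUE), collapse = ""))))
  enh <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  thr <- c(fx = 1, fy = 1.5)
  rep1 <- enrichment_report(pwms, enh, thr, control = enh,
                            n_scrambles = 25, seed = 3)
  expect_equal(rep1$tf, c("fx", "fy"))
  # enhancer identical to control region gives identical counts
  expect_equal(rep1$enhancer_count, rep1$control_count)
  expect_equal(rep1$n_scrambles, c(25, 25))
  # factors scramble independently with derived child seeds
  expect_equal(rep1$rng_seed, c(3, 4))
  rep2 <- enrichment_report(pwms, enh, thr, control = enh,
                            n_scrambles = 25, seed = 3)
  expect_identical(rep1, rep2)
  expect_error(enrichment_report(pwms, enh, c(zz = 1)), "missing PWM")
})

test_that("sequence readers parse FASTA, aligned sets and MEME minimal", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(enh = "ACGTACGTAA", ctrl = "TTTTACGTCC"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs[["enh"]], "ACGTACGTAA")
  expect_equal(names(seqs), c("enh", "ctrl"))

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# one-hybrid selections", "ACGT", "", "acgt"), txt)
  expect_equal(read_aligned_sequences(txt), c("ACGT", "ACGT"))
  writeLines(c("ACGT", "ACG"), txt)
  expect_error(read_aligned_sequences(txt), "same length")

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.30 C 0.20 G 0.20 T 0.30", "",
    "MOTIF toymotif",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.50 0.25 0.20 0.05",
    " 0.10 0.10 0.70 0.10",
    " 0.25 0.25 0.25 0.25"), meme)
  pwm <- read_meme_motif(meme)
  expect_s3_class(pwm, "pwm")
  expect_equal(pwm$name, "toymotif")
  expect_equal(pwm$width, 3)
  expect_equal(unname(pwm$frequencies[2, "G"]), 0.7)
  expect_equal(unname(pwm$background["A"]), 0.3)
  expect_equal(unname(pwm$log_odds[1, "A"]), log2(0.5 / 0.3))
  expect_equal(pwm$consensus, "AGA")
  expect_error(read_meme_motif(meme, motif = "nope"), "not found")
})
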