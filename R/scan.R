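# Encode an ACGT string as integer indices into DNA_BASES.
encode_seq <- function(sequence) {
  sequence <- toupper(sequence)
  check_acgt(sequence)
  match(strsplit(sequence, "")[[1]], DNA_BASES)
}

# Log-odds scores for every window start on one strand, as a numeric vector
# indexed by the forward-strand start. Both strands accumulate motif rows in
# the same order 1..w, so a minus-strand score is bit-identical to the
# forward score of the reverse-complemented window (complement index of base
# b is 5 - b in A,C,G,T order).
window_scores <- function(pwm, x, strand) {
  w <- pwm$width
  n <- length(x) - w + 1
  lo <- pwm$log_odds
  scores <- numeric(n)
  for (i in seq_len(w)) {
    bases <- if (strand == "+") {
      x[i:(i + n - 1)]
    } else {
      5L - x[(w - i + 1):(w - i + n)]
    }
    scores <- scores + lo[i, bases]
  }
  scores
}

#' Scan a sequence for predicted binding sites
#'
#' Slides the PWM over every window of the sequence (both strands by
#' default) and reports each window scoring at or above the threshold.
#' Overlapping hits are all reported; no masking or greedy suppression is
#' applied. Starts are 1-based positions of the leftmost window base on the
#' forward strand for hits on either strand, and `matched_seq` always gives
#' the forward-strand bases of the window.
#'
#' @param pwm A [build_pwm()] object.
#' @param sequence A/C/G/T string at least as long as the motif.
#' @param threshold Minimum log-odds score, e.g. from
#'   [calibrate_threshold()] (a `calibrated_threshold` object is accepted).
#' @param strands `"both"` or `"forward"`.
#' @return Data frame of site hits: `start`, `strand`, `score`,
#'   `matched_seq`, sorted by start then strand.
#' @export
scan_sequence <- function(pwm, sequence, threshold, strands = "both") {
  strands <- match.arg(strands, c("both", "forward"))
  if (inherits(threshold, "calibrated_threshold")) {
    threshold <- threshold$score
  }
  x <- encode_seq(sequence)
  if (length(x) < pwm$width) {
    stop("sequence is shorter than the PWM width")
  }
  sequence <- toupper(sequence)
  hits <- list()
  for (strand in if (strands == "both") c("+", "-") else "+") {
    s <- window_scores(pwm, x, strand)
    keep <- which(s >= threshold)
    if (length(keep) > 0) {
      hits[[strand]] <- data.frame(
        start = keep,
        strand = strand,
        score = s[keep],
        matched_seq = substring(sequence, keep, keep + pwm$width - 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), matched_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Scrambled-sequence null for motif site counts
#'
#' Estimates the expected number of predicted sites in sequences with the
#' same length and exact mononucleotide composition as the input: the
#' sequence's characters are uniformly permuted (Fisher-Yates, via
#' `sample()`), the permuted sequence is rescanned, and the site count is
#' averaged over `n_scrambles` independent scrambles.
#'
#' @inheritParams scan_sequence
#' @param n_scrambles Number of independent scrambles; default 100.
#' @param seed Integer seed for the scramble generator (recorded in the
#'   result; the caller's RNG state is left untouched).
#' @return List with `scramble_mean`, `scramble_counts` (per-scramble site
#'   counts), `n_scrambles` and `rng_seed`.
#' @export
scramble_null <- function(pwm, sequence, threshold, n_scrambles = 100,
                          seed = 1, strands = "both") {
  stopifnot(n_scrambles >= 1)
  if (inherits(threshold, "calibrated_threshold")) {
    threshold <- threshold$score
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  check_acgt(sequence)
  counts <- with_seed(seed, {
    vapply(seq_len(n_scrambles), function(i) {
      scrambled <- paste(sample(chars), collapse = "")
      nrow(scan_sequence(pwm, scrambled, threshold, strands))
    }, numeric(1))
  })
  list(scramble_mean = mean(counts),
       scramble_counts = counts,
       n_scrambles = n_scrambles,
       rng_seed = seed)
}

#' Site-count enrichment report for a set of transcription factors
#'
#' For each factor, counts predicted sites on the enhancer, on an optional
#' control region (e.g. the adjacent genomic interval of equal length), and
#' under the scrambled-sequence null. Each factor's scramble run uses its own
#' deterministic child seed (`seed`, `seed + 1`, ...), so the factors are
#' scrambled independently and the whole report is reproducible from `seed`.
#'
#' @param pwms Named list of [build_pwm()] objects.
#' @param enhancer Enhancer sequence (A/C/G/T string, or a single-record
#'   named character vector as returned by [read_fasta()]).
#' @param thresholds Named numeric vector (or named list of
#'   `calibrated_threshold` objects) giving the scan threshold per factor;
#'   names select which PWMs are scanned.
#' @param control Optional control sequence, same form as `enhancer`.
#' @param n_scrambles Scrambles per factor; default 100.
#' @param seed Base integer seed.
#' @param strands `"both"` or `"forward"`.
#' @return Data frame with one row per factor: `tf`, `threshold`,
#'   `enhancer_count`, `control_count` (`NA` without a control),
#'   `scramble_mean`, `n_scrambles`, `rng_seed`.
#' @export
enrichment_report <- function(pwms, enhancer, thresholds, control = NULL,
                              n_scrambles = 100, seed = 1,
                              strands = "both") {
  stopifnot(!is.null(names(thresholds)), all(names(thresholds) != ""))
  missing_pwm <- setdiff(names(thresholds), names(pwms))
  if (length(missing_pwm) > 0) {
    stop("missing PWM for factor(s): ", paste(missing_pwm, collapse = ", "))
  }
  enhancer <- unname(enhancer[[1]])
  if (!is.null(control)) control <- unname(control[[1]])
  rows <- lapply(seq_along(thresholds), function(i) {
    tf <- names(thresholds)[i]
    thr <- thresholds[[i]]
    if (inherits(thr, "calibrated_threshold")) thr <- thr$score
    pwm <- pwms[[tf]]
    null <- scramble_null(pwm, enhancer, thr, n_scrambles = n_scrambles,
                          seed = seed + i - 1, strands = strands)
    data.frame(
      tf = tf,
      threshold = thr,
      enhancer_count = nrow(scan_sequence(pwm, enhancer, thr, strands)),
      control_count = if (is.null(control)) NA_integer_ else {
        nrow(scan_sequence(pwm, control, thr, strands))
      },
      scramble_mean = null$scramble_mean,
      n_scrambles = n_scrambles,
      rng_seed = null$rng_seed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
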