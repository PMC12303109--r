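DNA_BASES <- c("A", "C", "G", "T")

check_acgt <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("sequence contains non-ACGT character(s); ambiguity codes are ",
         "not supported")
  }
  invisible(seqs)
}

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Build a position weight matrix from aligned binding sequences
#'
#' Counts base occurrences per alignment column, converts counts to
#' pseudocounted frequencies `(count + pseudocount) / (n + 4 * pseudocount)`
#' and to log-odds scores `log2(frequency / background)`. With a zero
#' pseudocount, bases unseen in the training set get `-Inf` log-odds and any
#' window containing them scores `-Inf`.
#'
#' @param aligned_seqs Character vector of equal-length A/C/G/T sequences
#'   (e.g. a bacterial one-hybrid training set).
#' @param pseudocount Non-negative count added per base per column;
#'   default 0.25.
#' @param background Background base probabilities over A,C,G,T summing to 1;
#'   default uniform.
#' @param name Optional motif name.
#' @return Object of class `pwm`: list with `name`, `width`, `n_seqs`,
#'   `counts`, `frequencies`, `log_odds` (each a width x 4 matrix over
#'   A,C,G,T), `background`, `pseudocount` and `consensus` (row-wise argmax
#'   sequence, which attains the maximum possible score).
#' @examples
#' pwm <- build_pwm(c("ACG", "ACG", "ACT"), pseudocount = 0)
#' pwm$consensus
#' @export
build_pwm <- function(aligned_seqs, pseudocount = 0.25,
                      background = c(0.25, 0.25, 0.25, 0.25),
                      name = "motif") {
  if (length(aligned_seqs) == 0) {
    stop("empty training set")
  }
  aligned_seqs <- toupper(aligned_seqs)
  check_acgt(aligned_seqs)
  if (length(unique(nchar(aligned_seqs))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  stopifnot(pseudocount >= 0, length(background) == 4,
            all(background >= 0), abs(sum(background) - 1) < 1e-9)
  width <- nchar(aligned_seqs[1])
  chars <- matrix(unlist(strsplit(aligned_seqs, "")),
                  nrow = length(aligned_seqs), byrow = TRUE)
  counts <- t(apply(chars, 2, function(col) {
    tabulate(match(col, DNA_BASES), nbins = 4)
  }))
  if (width == 1) counts <- matrix(counts, nrow = 1)
  colnames(counts) <- DNA_BASES
  pwm_from_counts(counts, pseudocount, background, name,
                  n_seqs = length(aligned_seqs))
}

pwm_from_counts <- function(counts, pseudocount, background, name, n_seqs) {
  background <- setNames(as.numeric(background), DNA_BASES)
  freq <- (counts + pseudocount) / (n_seqs + 4 * pseudocount)
  log_odds <- log2(sweep(freq, 2, background, "/"))
  consensus <- paste(DNA_BASES[apply(freq, 1, which.max)], collapse = "")
  structure(list(name = name,
                 width = nrow(counts),
                 n_seqs = n_seqs,
                 counts = counts,
                 frequencies = freq,
                 log_odds = log_odds,
                 background = background,
                 pseudocount = pseudocount,
                 consensus = consensus),
            class = "pwm")
}

# Build a pwm object directly from a frequency matrix (MEME import path).
pwm_from_frequencies <- function(freq, background, name, n_seqs,
                                 pseudocount = 0) {
  colnames(freq) <- DNA_BASES
  counts <- freq * n_seqs
  pwm_from_counts(counts, pseudocount = pseudocount,
                  background = background, name = name, n_seqs = n_seqs)
}

#' @export
print.pwm <- function(x, ...) {
  cat("Position weight matrix '", x$name, "' (width ", x$width,
      ", ", x$n_seqs, " training sequences, pseudocount ",
      x$pseudocount, ")\n", sep = "")
  cat("  consensus: ", x$consensus, " (max score ",
      format(max_pwm_score(x), digits = 4), ")\n", sep = "")
  invisible(x)
}

# Maximum attainable log-odds score (the consensus score).
max_pwm_score <- function(pwm) {
  sum(apply(pwm$log_odds, 1, max))
}

#' Score one window against a PWM
#'
#' Sums per-position log-odds for a window of the motif's width. On the minus
#' strand the reverse complement of the window is scored, so the score is the
#' site's score as read on the other strand.
#'
#' @param pwm A [build_pwm()] object.
#' @param window A/C/G/T string of length `pwm$width`.
#' @param strand `"+"` or `"-"`.
#' @return The log-odds score.
#' @export
score_window <- function(pwm, window, strand = "+") {
  window <- toupper(window)
  check_acgt(window)
  if (nchar(window) != pwm$width) {
    stop("window length must equal the PWM width (", pwm$width, ")")
  }
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "-") {
    window <- revcomp(window)
  }
  idx <- match(strsplit(window, "")[[1]], DNA_BASES)
  sum(pwm$log_odds[cbind(seq_len(pwm$width), idx)])
}

#' Calibrate a percentile score threshold from training sequences
#'
#' Scores every training sequence with the PWM and returns the nearest-rank
#' percentile threshold: the k-th highest training score with
#' `k = ceiling(percentile/100 * n)`. A 100th-percentile cutoff therefore
#' admits every training sequence (threshold = minimum training score), the
#' 50th admits the top half, and smaller percentiles are more stringent.
#'
#' @param pwm A [build_pwm()] object.
#' @param training_seqs Character vector of sequences of the motif's width
#'   (typically the set the PWM was built from).
#' @param percentile Value in (0, 100].
#' @return Object of class `calibrated_threshold`: list with `percentile`,
#'   `score` and `n_training`.
#' @export
calibrate_threshold <- function(pwm, training_seqs, percentile) {
  if (length(training_seqs) == 0) {
    stop("empty training set")
  }
  stopifnot(percentile > 0, percentile <= 100)
  scores <- vapply(training_seqs, function(s) score_window(pwm, s, "+"),
                   numeric(1), USE.NAMES = FALSE)
  k <- ceiling(percentile / 100 * length(scores))
  thr <- unname(sort(scores, decreasing = TRUE)[k])
  structure(list(percentile = percentile,
                 score = thr,
                 n_training = length(scores)),
            class = "calibrated_threshold")
}

#' @export
print.calibrated_threshold <- function(x, ...) {
  cat("Calibrated threshold: score >= ", format(x$score, digits = 4),
      " (", x$percentile, "th percentile of ", x$n_training,
      " training sequences)\n", sep = "")
  invisible(x)
}
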