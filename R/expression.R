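#' Transcripts-per-million normalisation
#'
#' Converts raw read counts to TPM: each gene's count is first divided by its
#' transcript length (reads per base), and the per-length rates are rescaled to
#' sum to one million. TPM values are therefore comparable across libraries of
#' different depth and across genes of different length.
#'
#' @param read_counts Numeric vector of non-negative read counts (fractional
#'   counts, as produced by multi-mapping-aware quantifiers, are allowed).
#' @param lengths Numeric vector of positive transcript lengths in bases,
#'   parallel to `read_counts`.
#' @return Numeric vector of TPM values summing to `1e6`.
#' @examples
#' compute_tpm(c(10, 90), c(100, 300))  # 250000, 750000
#' @export
compute_tpm <- function(read_counts, lengths) {
  if (length(read_counts) != length(lengths)) {
    stop("read_counts and lengths must have equal length")
  }
  if (any(is.na(read_counts)) || any(read_counts < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("transcript lengths must be positive")
  }
  rate <- read_counts / lengths
  total <- sum(rate)
  if (total == 0) {
    stop("no expressed genes")
  }
  rate / total * 1e6
}

#' Fold difference between two read counts
#'
#' The ratio of the higher to the lower read count, rounded half-up to two
#' decimals — the precision used when reporting fold differences between the
#' Kc and S2 cell lines.
#'
#' @param high_reads Non-negative read count (numerator).
#' @param low_reads Positive read count (denominator).
#' @return The ratio rounded to 2 decimals.
#' @examples
#' fold_difference(773, 6)  # 128.83
#' @export
fold_difference <- function(high_reads, low_reads) {
  stopifnot(is.numeric(high_reads), is.numeric(low_reads))
  if (any(low_reads == 0)) {
    stop("undefined fold difference")
  }
  if (any(high_reads < 0) || any(low_reads < 0)) {
    stop("read counts must be non-negative")
  }
  round_half_up(high_reads / low_reads, 2)
}

#' Pseudocounted log2 TPM ratio
#'
#' `log2((tpm_a + pseudocount) / (tpm_b + pseudocount))`. The symmetric
#' pseudocount keeps the ratio finite for genes silent in one condition and
#' makes the statistic exactly antisymmetric under swapping the conditions.
#'
#' @param tpm_a,tpm_b Non-negative TPM values (vectorised).
#' @param pseudocount Positive value added to both TPMs; default 0.01.
#' @return log2 ratio(s).
#' @export
log2_tpm_ratio <- function(tpm_a, tpm_b, pseudocount = 0.01) {
  stopifnot(length(pseudocount) == 1, pseudocount > 0)
  if (any(tpm_a < 0, na.rm = TRUE) || any(tpm_b < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative")
  }
  # difference of logs rather than log of ratio: antisymmetry under
  # swapping a and b then holds bit-exactly
  log2(tpm_a + pseudocount) - log2(tpm_b + pseudocount)
}

#' Threshold classification of differential expression
#'
#' Labels each measured gene `up` when its log2 Kc/S2 ratio exceeds
#' `threshold`, `down` when it is below `-threshold`, and `neutral` otherwise;
#' genes without expression data are labelled `unmeasured`. This is a
#' threshold classification of the magnitude of change only — it carries no
#' replicate-based significance statement.
#'
#' If the table carries a published `log2_kc_s2` column it is used directly
#' (so classes match the printed ratios); otherwise the ratio is recomputed
#' from the TPM columns with [log2_tpm_ratio()].
#'
#' @param records Expression data frame as returned by
#'   [read_expression_table()]: columns `gene_symbol`, `kc_tpm`, `s2_tpm`,
#'   `measured`, optionally `log2_kc_s2`.
#' @param threshold Positive log2 threshold; default 2.
#' @param pseudocount Passed to [log2_tpm_ratio()] when ratios are recomputed.
#' @return Data frame with columns `gene_symbol`, `log2_ratio`, `direction`
#'   (factor: up/down/neutral/unmeasured) and `rank_in_class` (`NA` until
#'   [rank_within_class()] is applied).
#' @export
classify_differential <- function(records, threshold = 2,
                                  pseudocount = 0.01) {
  stopifnot(threshold > 0)
  if (nrow(records) == 0) {
    return(data.frame(gene_symbol = character(), log2_ratio = numeric(),
                      direction = character(), rank_in_class = integer(),
                      stringsAsFactors = FALSE))
  }
  measured <- if ("measured" %in% names(records)) {
    records$measured
  } else {
    !is.na(records$kc_tpm) & !is.na(records$s2_tpm)
  }
  lr <- rep(NA_real_, nrow(records))
  if ("log2_kc_s2" %in% names(records)) {
    lr <- records$log2_kc_s2
  }
  need <- measured & is.na(lr)
  lr[need] <- log2_tpm_ratio(records$kc_tpm[need], records$s2_tpm[need],
                             pseudocount)
  direction <- rep("unmeasured", nrow(records))
  direction[measured & !is.na(lr) & lr > threshold] <- "up"
  direction[measured & !is.na(lr) & lr < -threshold] <- "down"
  direction[measured & !is.na(lr) & abs(lr) <= threshold] <- "neutral"
  lr[!measured] <- NA_real_
  data.frame(gene_symbol = records$gene_symbol,
             log2_ratio = lr,
             direction = direction,
             rank_in_class = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Rank genes within their differential class
#'
#' Within each of the `up` and `down` classes, genes are ranked 1..k by
#' decreasing absolute log2 ratio; ties are broken by gene symbol
#' (lexicographic). Neutral and unmeasured genes keep `NA` ranks.
#'
#' @param calls Data frame from [classify_differential()].
#' @return The same data frame with `rank_in_class` filled for up/down genes.
#' @export
rank_within_class <- function(calls) {
  stopifnot(all(c("gene_symbol", "log2_ratio", "direction") %in% names(calls)))
  for (cls in c("up", "down")) {
    idx <- which(calls$direction == cls)
    if (length(idx) == 0) next
    ord <- idx[order(-abs(calls$log2_ratio[idx]),
                     calls$gene_symbol[idx], method = "radix")]
    calls$rank_in_class[ord] <- seq_along(ord)
  }
  calls
}
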