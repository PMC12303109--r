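# Merge the expression columns of the two network tables into one expression
# table keyed by gene symbol, preferring rows that carry data.
merge_network_expression <- function(ey_tbl, toy_tbl) {
  cols <- c("gene_symbol", "gene_id", "kc_reads", "s2_reads",
            "kc_tpm", "s2_tpm", "log2_kc_s2", "measured")
  both <- rbind(ey_tbl[intersect(cols, names(ey_tbl))],
                toy_tbl[intersect(cols, names(toy_tbl))])
  both <- both[order(!both$measured), ]  # measured rows win
  both[!duplicated(both$gene_symbol), ]
}

#' Run the full candidate screen and summarise it
#'
#' End-to-end driver over the two seed-network tables: merges their
#' expression columns, applies [screen_candidates()] and
#' [classify_specificity()], and reports the intermediate counts alongside
#' the candidate table. With no arguments it runs on the packaged published
#' tables.
#'
#' @param ey_path,toy_path Paths to the ey/toy network tables; defaults are
#'   the packaged published tables.
#' @param conn_min,reads_min,tpm_min Screen thresholds, see
#'   [screen_candidates()].
#' @return Object of class `screen_report`: list with
#'   \describe{
#'     \item{candidates}{data frame of the passing genes with both
#'       connectivities, expression and specificity, sorted by maximum
#'       connectivity;}
#'     \item{report}{the full per-gene table over all non-seed network
#'       members;}
#'     \item{counts}{named list of intermediate tallies: per-network member
#'       counts, non-RDGN genes at the connectivity cutoff, how many of
#'       those pass the expression cutoff, candidate total, and
#'       shared/specific tallies;}
#'     \item{config}{the resolved thresholds and input paths.}
#'   }
#' @examples
#' \donttest{
#' rep <- run_screen()
#' rep$counts$n_candidates  # 16
#' }
#' @export
run_screen <- function(ey_path = rdgn_fixture("ey_network.tsv"),
                       toy_path = rdgn_fixture("toy_network.tsv"),
                       conn_min = 14, reads_min = 8, tpm_min = 0.15) {
  ey_tbl <- read_network_table(ey_path)
  toy_tbl <- read_network_table(toy_path)
  expr <- merge_network_expression(ey_tbl, toy_tbl)
  report <- screen_candidates(ey_tbl, toy_tbl, expr,
                              conn_min = conn_min, reads_min = reads_min,
                              tpm_min = tpm_min,
                              ey_seed = ey_tbl$gene_symbol[1],
                              toy_seed = toy_tbl$gene_symbol[1])
  report <- classify_specificity(report)
  candidates <- report[report$passes_screen, , drop = FALSE]
  rownames(candidates) <- NULL

  count_at_cutoff <- function(tbl) {
    non_seed <- tbl[-1, , drop = FALSE]
    hit <- non_seed[non_seed$node_conn >= conn_min & !non_seed$rdgn, ,
                    drop = FALSE]
    expr_ok <- hit$measured &
      pmax(hit$kc_reads, hit$s2_reads, na.rm = TRUE) >= reads_min
    list(n_members = nrow(non_seed),
         n_conn_min_nonrdgn = nrow(hit),
         n_expressed = sum(expr_ok, na.rm = TRUE))
  }
  ey_counts <- count_at_cutoff(ey_tbl)
  toy_counts <- count_at_cutoff(toy_tbl)
  spec_tab <- table(factor(candidates$specificity,
                           levels = c("shared", "ey_specific",
                                      "toy_specific")))
  counts <- list(
    ey_members = ey_counts$n_members,
    toy_members = toy_counts$n_members,
    ey_conn_min_nonrdgn = ey_counts$n_conn_min_nonrdgn,
    ey_conn_min_expressed = ey_counts$n_expressed,
    toy_conn_min_nonrdgn = toy_counts$n_conn_min_nonrdgn,
    toy_conn_min_expressed = toy_counts$n_expressed,
    n_candidates = nrow(candidates),
    n_shared = as.integer(spec_tab[["shared"]]),
    n_ey_specific = as.integer(spec_tab[["ey_specific"]]),
    n_toy_specific = as.integer(spec_tab[["toy_specific"]]))
  structure(list(candidates = candidates,
                 report = report,
                 counts = counts,
                 config = list(ey_path = ey_path, toy_path = toy_path,
                               conn_min = conn_min, reads_min = reads_min,
                               tpm_min = tpm_min)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cts <- x$counts
  cat("Candidate screen (conn >= ", x$config$conn_min,
      ", reads >= ", x$config$reads_min, " in either cell line, ",
      "known members excluded)\n", sep = "")
  cat("  ey network:  ", cts$ey_members, " members; ",
      cts$ey_conn_min_nonrdgn, " non-RDGN at cutoff, ",
      cts$ey_conn_min_expressed, " expressed\n", sep = "")
  cat("  toy network: ", cts$toy_members, " members; ",
      cts$toy_conn_min_nonrdgn, " non-RDGN at cutoff, ",
      cts$toy_conn_min_expressed, " expressed\n", sep = "")
  cat("  candidates:  ", cts$n_candidates, " (", cts$n_shared, " shared, ",
      cts$n_ey_specific, " ey-specific, ", cts$n_toy_specific,
      " toy-specific)\n", sep = "")
  cat("\n")
  show <- x$candidates[c("gene_symbol", "ey_conn", "toy_conn",
                         "kc_tpm", "s2_tpm", "specificity")]
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a screen report to TSV
#'
#' Writes the candidate table (and optionally the full per-gene report) in
#' the same tab-separated dialect the package reads.
#'
#' @param x A `screen_report` from [run_screen()].
#' @param path Output path for the candidate table.
#' @param full Write all screened genes rather than only the passing ones.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(x, path, full = FALSE) {
  tbl <- if (full) x$report else x$candidates
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
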