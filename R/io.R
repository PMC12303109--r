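#' Path to a packaged data file
#'
#' Convenience accessor for the tab-separated tables shipped with the package:
#' the published Pax6 cell-line expression profile (`"pax6_expression.tsv"`),
#' the two seed PPI network tables (`"ey_network.tsv"`, `"toy_network.tsv"`)
#' and the reference candidate list (`"novel_candidates.tsv"`).
#'
#' @param file File name; with no argument, lists available files.
#' @return Absolute path to the file (or a character vector of file names).
#' @export
rdgn_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "rdgnscreen", mustWork = TRUE)
  if (is.null(file)) {
    return(list.files(dir))
  }
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop("no packaged file named '", file, "'")
  }
  path
}

read_tsv_commented <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("", "NA"), strip.white = TRUE)
}

#' Read a two-condition expression table
#'
#' Reads a tab-separated table with (at least) columns `gene_symbol`,
#' `gene_id`, `kc_reads`, `s2_reads`, `kc_tpm`, `s2_tpm`. Blank expression
#' fields mark a gene as having no expression data: the row is kept with
#' `measured = FALSE`, never coerced to zero. Lines starting with `#` are
#' treated as comments.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the input columns plus a logical `measured` column.
#' @export
read_expression_table <- function(path) {
  tbl <- read_tsv_commented(path)
  needed <- c("gene_symbol", "gene_id", "kc_reads", "s2_reads",
              "kc_tpm", "s2_tpm")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("expression table is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         " (expected: ", paste(needed, collapse = ", "), ")")
  }
  validate_expression_table(tbl, path)
}

# Shared validation for tables carrying expression columns.
validate_expression_table <- function(tbl, path = "<table>") {
  if (any(is.na(tbl$gene_symbol) | tbl$gene_symbol == "")) {
    stop("empty gene_symbol in ", path)
  }
  if (anyDuplicated(tbl$gene_id)) {
    dup <- tbl$gene_id[duplicated(tbl$gene_id)][1]
    stop("duplicate gene_id ", dup, " in ", path)
  }
  for (col in c("kc_reads", "s2_reads", "kc_tpm", "s2_tpm")) {
    tbl[[col]] <- as.numeric(tbl[[col]])
    if (any(tbl[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in column ", col, " of ", path)
    }
  }
  tbl$measured <- !is.na(tbl$kc_reads) & !is.na(tbl$s2_reads) &
    !is.na(tbl$kc_tpm) & !is.na(tbl$s2_tpm)
  tbl
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: tab-separated, `NA` written as a
#' blank field, no quoting or row names.
#'
#' @param tbl Expression data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tbl, path) {
  out <- tbl[setdiff(names(tbl), "measured")]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a seed-network connectivity table
#'
#' Reads the published per-gene subnetwork tables: `gene_symbol`, `gene_id`,
#' `node_conn` (the gene's degree within the seed subnetwork), the four
#' expression columns and an `rdgn` yes/no flag. The first row is expected to
#' be the seed gene, whose connectivity equals the number of other rows.
#'
#' @param path Path to the TSV file.
#' @return Data frame with `rdgn` parsed to logical and a `measured` column.
#' @export
read_network_table <- function(path) {
  tbl <- read_tsv_commented(path)
  needed <- c("gene_symbol", "gene_id", "node_conn")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("network table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl$node_conn <- as.integer(tbl$node_conn)
  if (any(is.na(tbl$node_conn)) || any(tbl$node_conn < 0)) {
    stop("node_conn must be a non-negative integer in ", path)
  }
  if ("rdgn" %in% names(tbl)) {
    tbl$rdgn <- tolower(tbl$rdgn) %in% c("yes", "true", "1")
  }
  validate_expression_table(tbl, path)
}

#' Read an interaction edge list
#'
#' Tab-separated `node_a`, `node_b`, `score` with scores on the STRING-export
#' 0-1000 combined-confidence scale. Edges are undirected: duplicate unordered
#' pairs are collapsed keeping the maximum score; self-loops are rejected.
#'
#' @param path Path to the TSV file.
#' @return Data frame `node_a`, `node_b`, `score`.
#' @export
read_edge_list <- function(path) {
  tbl <- read_tsv_commented(path)
  needed <- c("node_a", "node_b", "score")
  if (!all(needed %in% names(tbl))) {
    stop("edge list must have columns: ", paste(needed, collapse = ", "))
  }
  as_edge_list(tbl[needed])
}

# Normalise an in-memory edge data frame: validate, undirect, deduplicate.
as_edge_list <- function(edges) {
  edges$score <- as.numeric(edges$score)
  if (any(is.na(edges$score)) || any(edges$score < 0 | edges$score > 1000)) {
    stop("edge scores must lie in [0, 1000]")
  }
  if (any(edges$node_a == edges$node_b)) {
    stop("self-loop edge(s) not allowed")
  }
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(edges$score, key, max)
  keep <- !duplicated(key)
  out <- data.frame(node_a = a[keep], node_b = b[keep],
                    stringsAsFactors = FALSE)
  out$score <- as.numeric(score[paste(out$node_a, out$node_b, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Write an interaction edge list
#' @param edges Data frame `node_a`, `node_b`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning a named
#' character vector of uppercase sequences.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read aligned binding sequences (one per line)
#'
#' Plain-text reader for bacterial one-hybrid style training sets: one
#' equal-length A/C/G/T sequence per line, blank lines and `#` comments
#' ignored. This is the raw-sequence dialect exported by FlyFactorSurvey.
#'
#' @param path Path to the text file.
#' @return Character vector of uppercase sequences.
#' @export
read_aligned_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  seqs <- toupper(lines)
  if (length(seqs) == 0) {
    stop("no sequences in ", path)
  }
  check_acgt(seqs)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  seqs
}

#' Read a motif from a MEME minimal-format file
#'
#' Parses the first (or a named) motif from a MEME minimal motif file: the
#' `MOTIF` line, the `letter-probability matrix:` header with `w=` and
#' `nsites=`, and the per-position A/C/G/T probability rows. The optional
#' `Background letter frequencies` line supplies the background model
#' (uniform if absent). Probabilities are converted back to counts via
#' `nsites` so the result behaves like a PWM built with [build_pwm()] at zero
#' pseudocount.
#'
#' @param path Path to the MEME minimal file.
#' @param motif Optional motif name; default first motif in the file.
#' @return A `pwm` object (see [build_pwm()]).
#' @export
read_meme_motif <- function(path, motif = NULL) {
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (length(motif_i) == 0) {
    stop("no MOTIF record in ", path)
  }
  names_avail <- vapply(strsplit(lines[motif_i], "\\s+"), `[`, "", 2)
  pick <- if (is.null(motif)) 1L else match(motif, names_avail)
  if (is.na(pick)) {
    stop("motif '", motif, "' not found; available: ",
         paste(names_avail, collapse = ", "))
  }
  start <- motif_i[pick]
  hdr_i <- grep("^letter-probability matrix:", lines)
  hdr_i <- hdr_i[hdr_i > start][1]
  if (is.na(hdr_i)) {
    stop("no letter-probability matrix for motif ", names_avail[pick])
  }
  hdr <- lines[hdr_i]
  w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
  nsites <- if (grepl("nsites=", hdr)) {
    as.numeric(sub(".*\\bnsites=\\s*([0-9.]+).*", "\\1", hdr))
  } else {
    20
  }
  rows <- lines[(hdr_i + 1):(hdr_i + w)]
  freq <- t(vapply(strsplit(trimws(rows), "\\s+"),
                   function(x) as.numeric(x[1:4]), numeric(4)))
  colnames(freq) <- c("A", "C", "G", "T")
  pwm_from_frequencies(freq, background = bg, name = names_avail[pick],
                       n_seqs = nsites, pseudocount = 0)
}
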