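#' The 21 curated retinal determination gene network members
#'
#' The literature-curated set of molecular components of the Drosophila
#' retinal determination gene network (RDGN): the Pax6 paralogues and the
#' downstream/accessory factors and signalling molecules. Genes in this set
#' are annotated as known members and are excluded from the novel-candidate
#' screen.
#'
#' @return Character vector of 21 gene symbols.
#' @export
known_rdgn_genes <- function() {
  c("toy", "ey", "so", "eya", "dac", "tsh", "tio", "hth", "eyg", "toe",
    "Optix", "dan", "danr", "ato", "nmo", "gro", "hry", "N", "hh", "dpp",
    "wg")
}

#' Build a seed-centred interaction subnetwork
#'
#' Keeps edges at or above the confidence cutoff, takes the seed's direct
#' neighbours as the subnetwork members, and computes each gene's
#' connectivity as its degree within the subgraph induced on the seed plus
#' members (again using only qualifying edges). The seed's connectivity
#' therefore equals the member count, and every member has connectivity of at
#' least 1.
#'
#' @param edges Data frame `node_a`, `node_b`, `score` (undirected; duplicate
#'   unordered pairs collapsed keeping the maximum score).
#' @param seed Seed gene symbol.
#' @param min_score Minimum combined confidence score (STRING 0-1000 scale);
#'   default 500.
#' @return An object of class `seed_network`: list with `seed`, `members`
#'   (character), `connectivity` (named integer over seed + members) and
#'   `min_score`.
#' @examples
#' edges <- data.frame(node_a = c("a", "b", "a"), node_b = c("b", "c", "c"),
#'                     score = 900)
#' build_seed_network(edges, "a")
#' @export
build_seed_network <- function(edges, seed, min_score = 500) {
  edges <- as_edge_list(edges)
  keep <- edges$score >= min_score
  edges <- edges[keep, , drop = FALSE]
  touches_seed <- edges$node_a == seed | edges$node_b == seed
  if (!any(touches_seed)) {
    stop("seed not connected")
  }
  members <- sort(unique(c(edges$node_a[touches_seed],
                           edges$node_b[touches_seed])))
  members <- setdiff(members, seed)
  g <- igraph::graph_from_data_frame(edges[c("node_a", "node_b")],
                                     directed = FALSE)
  sub <- igraph::induced_subgraph(g, c(seed, members))
  conn <- igraph::degree(sub)
  structure(list(seed = seed,
                 members = members,
                 connectivity = setNames(as.integer(conn), names(conn)),
                 min_score = min_score),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat("Seed PPI subnetwork\n")
  cat("  seed:      ", x$seed, "\n", sep = "")
  cat("  members:   ", length(x$members),
      " (score >= ", x$min_score, ")\n", sep = "")
  nonseed <- x$connectivity[names(x$connectivity) != x$seed]
  if (length(nonseed) > 0) {
    cat("  non-seed connectivity: ", min(nonseed), "-", max(nonseed),
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarise a seed network's connectivity
#'
#' Reports the member count, the maximum connectivity among non-seed members
#' and the gene achieving it (ties broken lexicographically). Works on a
#' [build_seed_network()] result or directly on a published connectivity
#' table (data frame with `gene_symbol` and `node_conn`, the seed being its
#' first row unless named).
#'
#' @param net A `seed_network` or a connectivity-table data frame.
#' @param seed Seed gene symbol; required only for data frames whose first
#'   row is not the seed.
#' @return List with `n_members`, `max_nonseed_conn` and `argmax_gene`.
#' @export
connectivity_summary <- function(net, seed = NULL) {
  if (inherits(net, "seed_network")) {
    conn <- net$connectivity
    seed <- net$seed
  } else {
    stopifnot(is.data.frame(net),
              all(c("gene_symbol", "node_conn") %in% names(net)))
    if (is.null(seed)) seed <- net$gene_symbol[1]
    conn <- setNames(net$node_conn, net$gene_symbol)
  }
  if (!seed %in% names(conn)) {
    stop("seed '", seed, "' not present in the network")
  }
  nonseed <- conn[names(conn) != seed]
  if (length(nonseed) == 0) {
    stop("network has no non-seed members")
  }
  top <- max(nonseed)
  argmax <- sort(names(nonseed)[nonseed == top])[1]
  list(n_members = length(nonseed),
       max_nonseed_conn = as.integer(top),
       argmax_gene = argmax)
}

# Connectivity columns for the screen: accepts a seed_network or a
# connectivity table; returns data.frame(gene_symbol, conn) over non-seed
# members.
conn_table <- function(net, seed = NULL) {
  if (is.null(net)) {
    return(data.frame(gene_symbol = character(), conn = integer(),
                      stringsAsFactors = FALSE))
  }
  if (inherits(net, "seed_network")) {
    conn <- net$connectivity
    seed <- net$seed
  } else {
    stopifnot(all(c("gene_symbol", "node_conn") %in% names(net)))
    if (is.null(seed)) seed <- net$gene_symbol[1]
    conn <- setNames(as.integer(net$node_conn), net$gene_symbol)
  }
  conn <- conn[names(conn) != seed]
  data.frame(gene_symbol = names(conn), conn = as.integer(conn),
             stringsAsFactors = FALSE)
}

#' Screen for candidate network components
#'
#' The combined connectivity/expression screen: a gene passes when it has at
#' least `conn_min` node connections in the ey and/or the toy seed
#' subnetwork, is not one of the 21 curated RDGN members (seeds included),
#' has expression data, and shows a read count of at least `reads_min`
#' (inclusive) in at least one cell line — the published read-count cutoff of
#' 8 corresponds to roughly `tpm_min` = 0.15 TPM. Genes present in a network
#' but absent from the expression table are treated as unmeasured (with a
#' message), not as an error.
#'
#' @param ey_net,toy_net Seed networks ([build_seed_network()] results) or
#'   published connectivity tables ([read_network_table()]); either may be
#'   `NULL` for a single-network screen.
#' @param expr Expression data frame with `gene_symbol`, `kc_reads`,
#'   `s2_reads`, `kc_tpm`, `s2_tpm`, `measured`.
#' @param conn_min Minimum node connectivity; default 14.
#' @param reads_min Minimum read count in at least one cell line (inclusive);
#'   default 8.
#' @param tpm_min Documented TPM equivalent of `reads_min`; default 0.15.
#'   Recorded in the result, not used as an additional filter.
#' @param ey_seed,toy_seed Seed symbols used when `ey_net`/`toy_net` are
#'   plain connectivity tables; defaults `"ey"` and `"toy"`.
#' @return Data frame of class `candidate_report`, one row per non-seed gene
#'   appearing in either network, sorted by maximum connectivity (then
#'   symbol): columns `gene_symbol`, `ey_conn`, `toy_conn`, the expression
#'   columns, `measured`, `is_rdgn`, `passes_screen` and `specificity`
#'   (filled by [classify_specificity()]).
#' @export
screen_candidates <- function(ey_net, toy_net, expr,
                              conn_min = 14, reads_min = 8, tpm_min = 0.15,
                              ey_seed = "ey", toy_seed = "toy") {
  stopifnot(conn_min >= 0, reads_min >= 0)
  ey <- conn_table(ey_net, ey_seed)
  toy <- conn_table(toy_net, toy_seed)
  genes <- sort(union(ey$gene_symbol, toy$gene_symbol))
  genes <- setdiff(genes, c(ey_seed, toy_seed))
  out <- data.frame(gene_symbol = genes, stringsAsFactors = FALSE)
  out$ey_conn <- ifelse(genes %in% ey$gene_symbol,
                        ey$conn[match(genes, ey$gene_symbol)], 0L)
  out$toy_conn <- ifelse(genes %in% toy$gene_symbol,
                         toy$conn[match(genes, toy$gene_symbol)], 0L)
  m <- match(genes, expr$gene_symbol)
  absent <- is.na(m)
  if (any(absent)) {
    message(sum(absent), " network gene(s) absent from the expression ",
            "table, treated as unmeasured: ",
            paste(head(genes[absent], 5), collapse = ", "),
            if (sum(absent) > 5) ", ..." else "")
  }
  for (col in c("kc_reads", "s2_reads", "kc_tpm", "s2_tpm")) {
    out[[col]] <- ifelse(absent, NA_real_, expr[[col]][m])
  }
  out$measured <- !absent & expr$measured[m]
  out$measured[is.na(out$measured)] <- FALSE
  out$is_rdgn <- out$gene_symbol %in% known_rdgn_genes()
  reads_ok <- out$measured &
    (pmax(out$kc_reads, out$s2_reads, na.rm = TRUE) >= reads_min)
  reads_ok[is.na(reads_ok)] <- FALSE
  out$passes_screen <- (out$ey_conn >= conn_min | out$toy_conn >= conn_min) &
    !out$is_rdgn & reads_ok
  out$specificity <- NA_character_
  out <- out[order(-pmax(out$ey_conn, out$toy_conn), out$gene_symbol,
                   method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(conn_min = conn_min, reads_min = reads_min,
                                  tpm_min = tpm_min)
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Classify candidates by network specificity
#'
#' A gene is `shared` when it appears (connectivity > 0) in both seed
#' subnetworks, and `ey_specific`/`toy_specific` when it appears in only one.
#' Presence, not the screening connectivity threshold, decides specificity: a
#' gene can pass the screen through one network yet be shared because it also
#' touches the other.
#'
#' @param candidates Data frame with `ey_conn` and `toy_conn` columns, e.g.
#'   from [screen_candidates()].
#' @return The same data frame with `specificity` filled.
#' @export
classify_specificity <- function(candidates) {
  stopifnot(all(c("ey_conn", "toy_conn") %in% names(candidates)))
  if (any(candidates$ey_conn == 0 & candidates$toy_conn == 0)) {
    stop("not in either network")
  }
  spec <- ifelse(candidates$ey_conn > 0 & candidates$toy_conn > 0, "shared",
                 ifelse(candidates$ey_conn > 0, "ey_specific",
                        "toy_specific"))
  candidates$specificity <- spec
  candidates
}
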