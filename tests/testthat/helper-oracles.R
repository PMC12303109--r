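# Independent oracles used across the suite. These deliberately avoid the
# package's scanning/graph code paths: string scoring is recomputed from raw
# counts with scalar loops, and graph degrees are counted by brute-force
# adjacency enumeration.

BASES <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Log-odds score of one window, recomputed from the training set from
# scratch (counts -> pseudocounted frequencies -> log2 ratio), scalar loop.
oracle_score <- function(training, window, pseudocount = 0.25,
                         background = rep(0.25, 4)) {
  n <- length(training)
  w <- nchar(training[1])
  total <- 0
  for (i in seq_len(w)) {
    col <- substr(training, i, i)
    b <- substr(window, i, i)
    cnt <- sum(col == b)
    freq <- (cnt + pseudocount) / (n + 4 * pseudocount)
    total <- total + log2(freq / background[match(b, BASES)])
  }
  total
}

# All (start, strand, score) hits by exhaustive window enumeration.
oracle_scan <- function(training, sequence, threshold, pseudocount = 0.25,
                        both_strands = TRUE) {
  w <- nchar(training[1])
  L <- nchar(sequence)
  out <- NULL
  for (start in seq_len(L - w + 1)) {
    win <- substr(sequence, start, start + w - 1)
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      target <- if (st == "+") win else oracle_revcomp(win)
      sc <- oracle_score(training, target, pseudocount)
      if (sc >= threshold) {
        out <- rbind(out, data.frame(start = start, strand = st,
                                     score = sc,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(), strand = character(), score = numeric())
  } else {
    out
  }
}

# Brute-force within-subnetwork connectivity: filter edges by score, find the
# seed's neighbours, then count adjacency inside seed + neighbours by direct
# pair enumeration.
oracle_seed_connectivity <- function(edges, seed, min_score = 500) {
  keep <- edges[edges$score >= min_score, , drop = FALSE]
  nb <- unique(c(keep$node_b[keep$node_a == seed],
                 keep$node_a[keep$node_b == seed]))
  nodes <- union(seed, nb)
  conn <- setNames(integer(length(nodes)), nodes)
  for (k in seq_len(nrow(keep))) {
    a <- keep$node_a[k]; b <- keep$node_b[k]
    if (a %in% nodes && b %in% nodes) {
      conn[a] <- conn[a] + 1L
      conn[b] <- conn[b] + 1L
    }
  }
  conn
}

# All distinct permutations of a small character multiset (recursive).
distinct_perms <- function(chars) {
  if (length(chars) <= 1) {
    return(list(chars))
  }
  out <- list()
  for (b in unique(chars)) {
    rest <- chars[-match(b, chars)]
    for (p in distinct_perms(rest)) {
      out[[length(out) + 1]] <- c(b, p)
    }
  }
  out
}

# A small random edge list for property tests.
random_edges <- function(n_nodes, p, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
             score = sample(0:1000, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}
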