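#' Simulate a two-condition expression table
#'
#' Draws per-gene read counts for two conditions from a negative-binomial
#' model (mean `nb_mean`, dispersion `nb_dispersion`, so the count variance
#' is `mu + dispersion * mu^2`) and applies designated log2 fold changes to
#' the condition-A (Kc) means of planted genes. Gene lengths are drawn
#' uniformly from `gene_length_range` and TPM is computed per condition with
#' [compute_tpm()]. The returned truth labels support recovery tests of the
#' downstream threshold classification.
#'
#' @param n_genes Total number of genes (>= 2).
#' @param fold_changes Data frame with columns `class`, `log2fc`, `n`
#'   designating planted effect classes; remaining genes get log2fc = 0 and
#'   class `"null"`. Default: no planted effects.
#' @param nb_mean Baseline negative-binomial mean; default 500.
#' @param nb_dispersion Negative-binomial dispersion (1/size); default 0.1.
#' @param gene_length_range Integer range of transcript lengths in bases;
#'   default c(500, 3000).
#' @param seed Integer seed; identical inputs give identical output.
#' @return List with `table` (expression data frame in the package's column
#'   layout, all genes measured) and `truth` (data frame `gene_symbol`,
#'   `class`, `log2fc`).
#' @export
simulate_expression <- function(n_genes,
                                fold_changes = NULL,
                                nb_mean = 500,
                                nb_dispersion = 0.1,
                                gene_length_range = c(500L, 3000L),
                                seed = 1) {
  stopifnot(n_genes >= 2, nb_mean > 0)
  if (is.na(nb_dispersion) || nb_dispersion <= 0) {
    stop("nb_dispersion must be a positive real")
  }
  n_planted <- if (is.null(fold_changes)) 0L else sum(fold_changes$n)
  stopifnot(n_planted <= n_genes)
  with_seed(seed, {
    lengths <- sample(seq(gene_length_range[1], gene_length_range[2]),
                      n_genes, replace = TRUE)
    lfc <- rep(0, n_genes)
    class <- rep("null", n_genes)
    if (n_planted > 0) {
      idx <- 1L
      for (j in seq_len(nrow(fold_changes))) {
        take <- seq(idx, length.out = fold_changes$n[j])
        lfc[take] <- fold_changes$log2fc[j]
        class[take] <- fold_changes$class[j]
        idx <- idx + fold_changes$n[j]
      }
    }
    size <- 1 / nb_dispersion
    kc_reads <- rnbinom(n_genes, mu = nb_mean * 2^lfc, size = size)
    s2_reads <- rnbinom(n_genes, mu = nb_mean, size = size)
    if (sum(kc_reads) == 0 || sum(s2_reads) == 0) {
      stop("simulated library has no expressed genes; increase nb_mean")
    }
    tbl <- data.frame(
      gene_symbol = sprintf("g%04d", seq_len(n_genes)),
      gene_id = seq_len(n_genes),
      kc_reads = kc_reads,
      s2_reads = s2_reads,
      kc_tpm = compute_tpm(kc_reads, lengths),
      s2_tpm = compute_tpm(s2_reads, lengths),
      length = lengths,
      stringsAsFactors = FALSE)
    tbl$measured <- TRUE
    list(table = tbl,
         truth = data.frame(gene_symbol = tbl$gene_symbol,
                            class = class, log2fc = lfc,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an interaction graph with a planted seed cluster
#'
#' Generates an Erdos-Renyi background graph over `n_nodes` genes and plants
#' a dense cluster (edge probability `within_prob`) containing a designated
#' seed gene, mimicking the tightly interconnected sub-cluster that known
#' network members form around a seed. Planted edges receive high confidence
#' scores, background edges scores spanning the full range, so filtering at
#' the usual cutoff retains the planted cluster.
#'
#' @param n_nodes Total genes (>= cluster_size + 1).
#' @param cluster_size Number of planted cluster members besides the seed
#'   (the dense cluster spans `cluster_size + 1` nodes).
#' @param within_prob Edge probability inside the planted cluster;
#'   default 0.9.
#' @param background_edge_prob Background edge probability; default 0.02.
#' @param planted_score_range Score range for planted edges;
#'   default c(700, 1000).
#' @param background_score_range Score range for background edges;
#'   default c(150, 1000).
#' @param seed_gene Symbol of the seed; default `"seed"`.
#' @param seed Integer seed.
#' @return List with `edges` (data frame `node_a`, `node_b`, `score`),
#'   `members` (true cluster members excluding the seed) and `seed_gene`.
#' @export
simulate_ppi <- function(n_nodes = 100,
                         cluster_size = 12,
                         within_prob = 0.9,
                         background_edge_prob = 0.02,
                         planted_score_range = c(700, 1000),
                         background_score_range = c(150, 1000),
                         seed_gene = "seed",
                         seed = 1) {
  stopifnot(n_nodes >= cluster_size + 1, cluster_size >= 0,
            within_prob >= 0, within_prob <= 1,
            background_edge_prob >= 0, background_edge_prob <= 1)
  nodes <- c(seed_gene, sprintf("n%04d", seq_len(n_nodes - 1)))
  cluster <- if (cluster_size > 0) nodes[seq_len(cluster_size + 1)] else
    character()
  with_seed(seed, {
    pairs <- t(utils::combn(nodes, 2))
    in_cluster <- pairs[, 1] %in% cluster & pairs[, 2] %in% cluster
    p <- ifelse(in_cluster, within_prob, background_edge_prob)
    keep <- runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    in_cluster <- in_cluster[keep]
    lo <- ifelse(in_cluster, planted_score_range[1],
                 background_score_range[1])
    hi <- ifelse(in_cluster, planted_score_range[2],
                 background_score_range[2])
    score <- round(runif(nrow(pairs), lo, hi))
    edges <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                        score = pmin(score, 1000),
                        stringsAsFactors = FALSE)
    list(edges = edges,
         members = setdiff(cluster, seed_gene),
         seed_gene = seed_gene)
  })
}

#' Sample training sequences from a known PWM
#'
#' Draws sequences position-independently from the PWM's frequency rows,
#' emulating a bacterial one-hybrid selection against the motif. As the
#' sample grows, [build_pwm()] on the sample converges to the truth matrix.
#'
#' @param pwm_truth A [build_pwm()] object used as the generating model.
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences of the motif's width.
#' @export
sample_training_sequences <- function(pwm_truth, n, seed = 1) {
  stopifnot(n >= 1)
  freq <- pwm_truth$frequencies
  with_seed(seed, {
    mat <- vapply(seq_len(pwm_truth$width), function(i) {
      sample(DNA_BASES, n, replace = TRUE, prob = freq[i, ])
    }, character(n))
    if (n == 1) mat <- matrix(mat, nrow = 1)
    apply(mat, 1, paste, collapse = "")
  })
}

#' Generate an enhancer with planted motif instances
#'
#' Draws a background sequence i.i.d. from `base_composition` and overwrites
#' it with non-overlapping copies of the PWM consensus at uniformly sampled
#' positions, each on a uniformly chosen strand (minus-strand plants insert
#' the reverse complement). The returned ground truth supports planted-site
#' recovery tests.
#'
#' @param pwm_truth A [build_pwm()] object; its consensus is planted.
#' @param enhancer_length Total sequence length in bases.
#' @param n_sites Number of planted sites (>= 0).
#' @param base_composition Background probabilities over A,C,G,T; default
#'   uniform.
#' @param seed Integer seed.
#' @return List with `sequence` (character) and `sites` (data frame `start`,
#'   `strand` of the planted instances, sorted by start).
#' @export
plant_sites_enhancer <- function(pwm_truth, enhancer_length, n_sites,
                                 base_composition = c(0.25, 0.25, 0.25, 0.25),
                                 seed = 1) {
  w <- pwm_truth$width
  stopifnot(n_sites >= 0, length(base_composition) == 4,
            abs(sum(base_composition) - 1) < 1e-9)
  if (enhancer_length < n_sites * w) {
    stop("cannot fit ", n_sites, " non-overlapping sites of width ", w,
         " in ", enhancer_length, " bases")
  }
  with_seed(seed, {
    chars <- sample(DNA_BASES, enhancer_length, replace = TRUE,
                    prob = base_composition)
    starts <- integer(0)
    if (n_sites > 0) {
      # Sample non-overlapping starts via the gap construction: choose the
      # slack before each site, then lay the sites down left to right.
      slack <- enhancer_length - n_sites * w
      cuts <- sort(sample.int(slack + 1, n_sites, replace = TRUE) - 1L)
      starts <- cuts + (seq_len(n_sites) - 1L) * w + 1L
    }
    strands <- if (n_sites > 0) sample(c("+", "-"), n_sites, TRUE) else
      character()
    cons <- strsplit(pwm_truth$consensus, "")[[1]]
    cons_rc <- strsplit(revcomp(pwm_truth$consensus), "")[[1]]
    for (i in seq_len(n_sites)) {
      ins <- if (strands[i] == "+") cons else cons_rc
      chars[starts[i]:(starts[i] + w - 1)] <- ins
    }
    list(sequence = paste(chars, collapse = ""),
         sites = data.frame(start = starts, strand = strands,
                            stringsAsFactors = FALSE))
  })
}
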