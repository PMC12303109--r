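#!/usr/bin/env Rscript

# Expression profiles of the two Pax6 paralogues and of every gene in the
# two seed PPI networks: fold differences, pseudocounted log2 Kc/S2 ratios,
# |log2| > 2 threshold classification, and within-class ranks.

suppressPackageStartupMessages(library(rdgnscreen))
dir.create("results", showWarnings = FALSE)

pax6 <- read_expression_table(rdgn_fixture("pax6_expression.tsv"))
cat("Pax6 paralogue profile (Kc vs S2):\n")
for (i in seq_len(nrow(pax6))) {
  hi <- max(pax6$kc_reads[i], pax6$s2_reads[i])
  lo <- min(pax6$kc_reads[i], pax6$s2_reads[i])
  cat(sprintf("  %-3s reads %4g/%-4g  fold %7.2f  log2(Kc/S2) %6.2f\n",
              pax6$gene_symbol[i], pax6$kc_reads[i], pax6$s2_reads[i],
              fold_difference(hi, lo),
              round(log2_tpm_ratio(pax6$kc_tpm[i], pax6$s2_tpm[i], 1e-12),
                    2)))
}

# Classify every gene appearing in either seed network, using the published
# log2 ratios carried by the tables, then rank the up/down classes.
ey_tbl <- read_network_table(rdgn_fixture("ey_network.tsv"))
toy_tbl <- read_network_table(rdgn_fixture("toy_network.tsv"))
expr <- rdgnscreen:::merge_network_expression(ey_tbl, toy_tbl)
calls <- rank_within_class(classify_differential(expr))
cat("\nThreshold classification over", nrow(calls), "network genes:\n")
print(table(calls$direction))
top_up <- calls[calls$direction == "up" & calls$rank_in_class <= 3, ]
cat("highest-ranked Kc-up genes:",
    paste(top_up$gene_symbol[order(top_up$rank_in_class)], collapse = ", "),
    "\n")

out <- merge(expr[c("gene_symbol", "gene_id", "kc_reads", "s2_reads",
                    "kc_tpm", "s2_tpm")],
             calls, by = "gene_symbol", sort = TRUE)
write.table(out, "results/expression_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
cat("wrote results/expression_classes.tsv\n")
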