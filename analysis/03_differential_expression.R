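#!/usr/bin/env Rscript
# Call fight-responsive genes for B-vs-D20 and B-vs-D60 under both
# threshold profiles, partition the two stringent DEG lists (Venn), and
# test the overlap by the upper-tail hypergeometric test.

library(pibs)

counts <- read_counts("results/data/counts.tsv")
design <- read.csv("results/data/design.csv", stringsAsFactors = FALSE)
kept <- filter_low_expression(counts)
lx <- log_transform(tmm_values(kept))
b <- design$sample_id[design$group == "B"]

de <- lapply(c(D20 = "D20", D60 = "D60"), function(g)
  de_test(lx, kept, b, design$sample_id[design$group == g]))
for (g in names(de))
  write.table(de[[g]], sprintf("results/de_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)

char <- lapply(de, select_degs, profile = "characterization")
sync <- lapply(de, select_degs, profile = "sync_input")
cat(sprintf("DEGs (FDR <= 0.05, |logFC| > 2): D20 %d, D60 %d\n",
            length(char$D20), length(char$D60)))
cat(sprintf("up-regulated sync input (FDR <= 0.05, logFC > 0): D20 %d, D60 %d\n",
            length(sync$D20), length(sync$D60)))
for (g in names(sync))
  writeLines(sync[[g]], sprintf("results/degs_sync_input_%s.txt", g))

v <- venn_partition(char$D20, char$D60)
h <- if (v$both > 0)
  overlap_hypergeometric(length(char$D20), length(char$D60), v$both,
                         nrow(kept)) else list(p = 1, log10_p = 0)
cat(sprintf("Venn: %d D20-only, %d D60-only, %d shared (union %d)\n",
            v$a_only, v$b_only, v$both, v$union))
cat(sprintf("overlap hypergeometric: log10 p = %.2f\n", h$log10_p))

pc <- projection_categories(de$D20, de$D60)
cat(sprintf("projection: %d significant in both, %d sign-discordant\n",
            sum(pc$table$category == "both"), pc$n_discordant))

jsonlite::write_json(list(venn = v, overlap_log10_p = h$log10_p,
                          categories = as.list(table(pc$table$category))),
                     "results/venn_overlap.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/de_*.tsv, results/degs_sync_input_*.txt, results/venn_overlap.json\n")
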