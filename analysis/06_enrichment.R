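#!/usr/bin/env Rscript
# Over-representation of the D60 synchronized gene set against a synthetic
# annotation. Half the terms are seeded with synchronized genes (so the
# analysis has something to find); the rest are random draws from the
# expressed universe.

library(pibs)

counts <- read_counts("results/data/counts.tsv")
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)
universe <- rownames(filter_low_expression(counts))

sync_tab <- read.delim("results/sync_genes_D60.tsv", stringsAsFactors = FALSE)
sync_set <- sync_tab$gene_id[sync_tab$is_synchronized]
cat(sprintf("test set: %d synchronized D60 genes; universe %d genes\n",
            length(sync_set), length(universe)))

set.seed(30)
true_sync <- intersect(truth$gene_id[truth$is_synchronized], universe)
terms <- c(
  lapply(1:10, function(i)            # synchrony-enriched terms
    unique(c(sample(true_sync, min(15, length(true_sync))),
             sample(universe, 10)))),
  lapply(1:10, function(i) sample(universe, 40))
)
names(terms) <- c(sprintf("SYNC%02d", 1:10), sprintf("RAND%02d", 1:10))

res <- ora(sync_set, terms, universe, min_overlap = 2, alpha = 0.05)
cat(sprintf("%d terms tested, %d significant (p < 0.05)\n",
            nrow(res), sum(res$significant)))
print(res[1:5, c("term_id", "overlap", "term_size", "p", "fdr")], digits = 3)
sig <- res$term_id[res$significant]
cat(sprintf("significant terms that were seeded with synchronized genes: %d/%d\n",
            sum(grepl("^SYNC", sig)), length(sig)))
write.table(res, "results/enrichment_D60.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/enrichment_D60.tsv\n")
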