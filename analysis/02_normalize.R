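#!/usr/bin/env Rscript
# Filter low-expression genes (CPM >= 1 in >= 1 sample) and compute
# TMM-normalized expression ("TMM values") plus their log2 transform.

library(pibs)

counts <- read_counts("results/data/counts.tsv")
kept <- filter_low_expression(counts, min_cpm = 1, min_samples = 1)
cat(sprintf("expression filter: %d of %d genes kept\n",
            nrow(kept), nrow(counts)))

factors <- tmm_factors(kept)
cat("TMM factors:\n")
print(data.frame(sample = factors$sample_id,
                 factor = round(factors$factor, 4))[1:5, ])
cat(sprintf("geometric mean of factors: %.9f\n",
            exp(mean(log(factors$factor)))))

expr <- tmm_values(kept, factors)
write.table(data.frame(gene_id = rownames(expr), round(expr, 4),
                       check.names = FALSE),
            "results/tmm_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.csv(factors, "results/tmm_factors.csv", row.names = FALSE)
cat("wrote results/tmm_values.tsv and results/tmm_factors.csv\n")
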