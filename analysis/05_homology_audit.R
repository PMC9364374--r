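#!/usr/bin/env Rscript
# Structural homology audit of the two split strategies: for each fold,
# the mean over test records of the tree edit distance to the structurally
# nearest training record. Intra-family (k-fold) splits leak near-identical
# structures (distances near zero); family-fold splits do not.

suppressPackageStartupMessages({
  library(shadowfold)
})

SEED <- 5L
dir.create("results", showWarnings = FALSE)

# moderate lengths keep all-vs-all tree edit distance affordable
specs <- default_corpus_specs(12L)
corpus <- generate_corpus(specs, seed = 11L)
corpus <- corpus[vapply(corpus, seq_length, 1L) <= 120L]
cat(sprintf("auditing %d records (lengths <= 120 nt)\n", length(corpus)))

ka <- audit_splits(kfold_split(corpus, k = 5L, seed = SEED), corpus,
                   max_test = 10L, max_train = 30L, seed = SEED)
fa <- audit_splits(familyfold_split(corpus), corpus,
                   max_test = 10L, max_train = 30L, seed = SEED)
ka$split <- "kfold"; fa$split <- "familyfold"
out <- rbind(ka, fa)
write.csv(out, "results/homology_audit.csv", row.names = FALSE)
print(as.data.frame(out), digits = 3)
cat(sprintf(paste0(
  "\nFindings: mean minimum tree edit distance is %.1f under k-fold splits\n",
  "but %.1f under family-fold splits - intra-family evaluation hands the\n",
  "model near-identical test structures at training time.\n"),
  mean(ka$mean_min_ted), mean(fa$mean_min_ted)))
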