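#!/usr/bin/env Rscript
# Step 5 — what the typical study in this literature could detect.
#
# With the literature's median cell size (n = 30 per group), a one-tailed
# test has power ~0.31 against the larger admissible bias-corrected estimate
# (d = 0.30) and ~0.61 even against an optimistic d = 0.50; conventional 0.80
# power would require an implausible d = 0.65.

suppressPackageStartupMessages(library(primingmeta))
dir.create("results", showWarnings = FALSE)

n <- 30
grid <- data.frame(d = c(0.30, 0.50, 0.65))
grid$power_one_tailed <- vapply(grid$d, power_two_group, numeric(1),
                                n_per_group = n, alpha = 0.05,
                                sidedness = "one")
d80 <- required_d(0.80, n_per_group = n, alpha = 0.05, sidedness = "one")

write.table(format(grid, digits = 3), "results/power.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(grid, row.names = FALSE)
cat(sprintf("d required for 0.80 one-tailed power at n = %d/group: %.2f\n",
            n, d80))
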