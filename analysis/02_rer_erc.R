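#!/usr/bin/env Rscript
# Stage 2: branch-length tables -> RER matrices -> integrated FtERC.
#
# Reads the stage-1 trees and tables from disk (exercising the same I/O a
# real study would use), normalizes each clade to relative evolutionary
# rates against its genome-wide branch profile, correlates RER profiles
# per clade, Fisher-transforms with the branch-count adjustment, and sums
# across clades into the integrated FtERC matrix.
suppressPackageStartupMessages(library(ratecov))

data_dir <- "results/data"
out <- "results"
clades <- sub("\\.nwk$", "", list.files(data_dir, pattern = "\\.nwk$"))

rers <- lapply(clades, function(cl) {
  tree <- read_clade_tree(file.path(data_dir, paste0(cl, ".nwk")), cl)
  tb <- read_branch_table(file.path(data_dir, paste0(cl, ".tsv")), tree)
  compute_rer(tb, master_profile(tb))
})
erc <- build_erc_matrix(rers, n_min = 5)

write_pair_table(pair_records(erc), file.path(out, "erc_pairs.tsv"))
thr <- significance_threshold(erc)
jsonlite::write_json(c(erc$summary, list(threshold = thr)),
                     file.path(out, "erc_summary.json"),
                     auto_unbox = TRUE, digits = NA)

print(erc)
cat("mean + 2 SD significance threshold:", round(thr, 3), "\n")
cat("pairs above threshold:",
    sum(erc$score[upper.tri(erc$score)] >= thr, na.rm = TRUE), "\n")
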