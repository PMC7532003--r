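#!/usr/bin/env Rscript

# Stage 5: conservation of poly(A) positions between conditions.
#
# Per gene, the major-isoform positions of two conditions are treated as
# draws from the eligible (non-A) positions of a window, and the upper-tail
# hypergeometric probability of observing at least the shared count is
# computed under two windows: the cross-condition combined major end zone
# and the full 3'UTR window.

suppressPackageStartupMessages({
  library(polyAshift)
  library(data.table)
})

res <- "results"
bundle <- read_genome_bundle(file.path(res, "genome", "genome.fa"),
                             file.path(res, "genome", "genes.gff3"))
scaled <- fread(file.path(res, "scaled_profiles.tsv"))

pairs <- list(c("slow1", "ref"), c("fast1", "ref"), c("slow1", "slow2"))
rows <- list()
for (pr in pairs) {
  for (win in c("combined", "full")) {
    ov <- genewise_overlap_summary(scaled, bundle, pr[1], pr[2],
                                   window = win)
    tab <- ov$table[, `:=`(cond_a = pr[1], cond_b = pr[2], window = win)]
    rows[[paste(pr[1], pr[2], win)]] <- tab
    cat(sprintf("%s vs %s [%s]: %d genes, median P = %.3g\n",
                pr[1], pr[2], win, nrow(tab), ov$median_p))
  }
}
fwrite(rbindlist(rows), file.path(res, "overlap_probabilities.tsv"),
       sep = "\t")

cz <- combined_major_end_zone(scaled, bundle)
fwrite(cz, file.path(res, "combined_major_end_zones.tsv"), sep = "\t")
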