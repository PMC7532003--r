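#!/usr/bin/env Rscript

# Stage 4: the shift model.
#
# For each strain vs the reference: per-gene raw percentile shifts
# (test - reference; negative = upstream), replicate-calibrated percentile
# errors, the empirical error model (non-zero frequencies halved, floor
# 1/G), net shifts k, P(g) = min(1, 5 * prod of tail probabilities), and
# direction calls requiring concordant signs and P(g) < 0.01.  Strain
# calls are then combined into Upstream / Downstream / Neutral / Other,
# and per-gene weighted-average net shifts are computed for the slow
# strains.

suppressPackageStartupMessages({
  library(polyAshift)
  library(data.table)
})

res <- "results"
pcoords <- fread(file.path(res, "percentile_coordinates.tsv"))
counts <- fread(file.path(res, "normalized_counts.tsv"))
genes_kept <- readLines(file.path(res, "genes_kept.txt"))

strains <- c("slow1", "slow2", "fast1", "fast2")
assessments <- list()
for (s in strains) {
  a <- assess_shifts(pcoords, test = s, ref = "ref")
  assessments[[s]] <- a$assessment[, strain := s]
}
assess <- rbindlist(assessments)
fwrite(assess, file.path(res, "shift_assessments.tsv"), sep = "\t")
print(assess[, .(n = .N), by = .(strain, call)])

combined <- classify_combined(assess[, .(gene, strain, call)],
                              slow = c("slow1", "slow2"),
                              fast = c("fast1", "fast2"))
fwrite(combined, file.path(res, "combined_classes.tsv"), sep = "\t")
print(combined[, .(n = .N), by = class])

# weighted-average net shift per gene, slow1 vs ref
wa <- counts[gene %in% genes_kept & condition %in% c("slow1", "ref"),
             .(wavg = sum(offset * count) / sum(count)),
             by = .(gene, condition, replicate)]
w <- dcast(wa, gene ~ condition + replicate, value.var = "wavg")
w <- w[complete.cases(w)]
w[, wa_net_shift := weighted_average_net_shift(slow1_1, slow1_2,
                                               ref_1, ref_2)]
fwrite(w, file.path(res, "weighted_average_shifts_slow1.tsv"), sep = "\t")
cat("median weighted-average net shift (slow1 vs ref):",
    median(w$wa_net_shift), "nt\n")
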