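#!/usr/bin/env Rscript

# Stage 6: sequence context and occupancy.
#
# Nucleotide composition (RNA alphabet) +/-10 nt around the max-isoform
# endpoint, tallied separately for the combined shift classes; and a
# synthetic promoter/ORF occupancy table with an injected log-linear
# dependence on the net overall end zone shift, summarized by the Pearson
# correlation between the processivity ratio and the shift.

suppressPackageStartupMessages({
  library(polyAshift)
  library(data.table)
})

res <- "results"
bundle <- read_genome_bundle(file.path(res, "genome", "genome.fa"),
                             file.path(res, "genome", "genes.gff3"))
landmarks <- fread(file.path(res, "endzone_landmarks.tsv"))
combined <- fread(file.path(res, "combined_classes.tsv"))
assess <- fread(file.path(res, "shift_assessments.tsv"))

cats <- split(combined$gene, combined$class)
cats <- cats[vapply(cats, length, integer(1)) > 0]
comp <- composition_around_max(landmarks[condition == "ref"], bundle, cats)
fwrite(comp, file.path(res, "composition_around_max.tsv"), sep = "\t")
print(dcast(comp[position %in% c(-2, -1, 1)],
            category + position ~ base, value.var = "pct"))

shifts <- assess[strain == "slow1", .(gene, net_overall)]
occ <- simulate_occupancy(shifts, slope = 0.05, noise_sd = 0.2,
                          seed = 20260101)
fwrite(occ, file.path(res, "occupancy.tsv"), sep = "\t")
sv <- shift_vs_processivity(occ[, .(gene, ratio)], shifts)
fwrite(sv$table, file.path(res, "shift_vs_processivity.tsv"), sep = "\t")
cat("Pearson R (processivity ratio vs net overall shift):",
    round(sv$r, 3), "\n")
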