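#!/usr/bin/env Rscript

# Stage 3: end-zone profiling.
#
# Genes with >= 1000 combined-replicate reads in every condition are kept;
# per gene and condition the isoform profile is scaled to the max isoform
# (100%), major isoforms (>= 5%) delimit the major end zone, and the
# weighted-average endpoint and 10/25/50/75/90% percentile coordinates are
# computed.  Landmark medians are compared across conditions and replicate
# agreement is summarized at the total, isoform and profile levels.

suppressPackageStartupMessages({
  library(polyAshift)
  library(data.table)
})

res <- "results"
counts <- fread(file.path(res, "normalized_counts.tsv"))

genes_kept <- filter_genes(counts, min_combined = 1000)
cat("genes passing the depth filter:", length(genes_kept), "\n")
writeLines(genes_kept, file.path(res, "genes_kept.txt"))

prof <- build_profiles(counts, gene_set = genes_kept)
fwrite(prof$landmarks, file.path(res, "endzone_landmarks.tsv"), sep = "\t")
fwrite(prof$scaled, file.path(res, "scaled_profiles.tsv"), sep = "\t")

pcoords <- percentile_table(counts, gene_set = genes_kept)
fwrite(pcoords, file.path(res, "percentile_coordinates.tsv"), sep = "\t")

cmp <- list(c("slow1", "ref"), c("slow2", "ref"),
            c("fast1", "ref"), c("fast2", "ref"))
smry <- landmark_summary(prof, comparisons = cmp)
fwrite(smry$medians, file.path(res, "landmark_medians.tsv"), sep = "\t")
fwrite(smry$tests, file.path(res, "landmark_tests.tsv"), sep = "\t")
fwrite(smry$metagene, file.path(res, "metagene_profile.tsv"), sep = "\t")
print(smry$medians)

reps <- rbindlist(lapply(unique(counts$condition), function(cn) {
  rc <- replicate_correlations(counts[condition == cn],
                               gene_set = genes_kept)
  data.table(condition = cn, total_r = rc$total_r,
             isoform_r = rc$isoform_r, n_isoforms = rc$n_isoforms,
             median_profile_r = median(rc$profile_r$r, na.rm = TRUE))
}))
fwrite(reps, file.path(res, "replicate_correlations.tsv"), sep = "\t")
print(reps)
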