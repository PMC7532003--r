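#!/usr/bin/env Rscript

# Stage 1: simulate a ground-truth dataset.
#
# One synthetic chromosome of 3'UTR windows with known poly(A) sites; five
# conditions (a reference plus two "slow" and two "fast" strains, i.e.
# positive and negative proximal tilts tau); two replicates each; raw
# 3'-end reads written as FASTQ, with a small decoy fraction for the
# internal-priming filter to remove.

suppressPackageStartupMessages({
  library(polyAshift)
  library(data.table)
})

res <- "results"
dir.create(file.path(res, "genome"), showWarnings = FALSE, recursive = TRUE)
dir.create(file.path(res, "reads"), showWarnings = FALSE)

spec <- synthetic_spec(
  n_genes = 200,
  sites_per_gene = 4:8,
  depth_per_replicate = 700,
  n_replicates = 2,
  conditions = c(ref = 0, slow1 = 1, slow2 = 0.8,
                 fast1 = -0.8, fast2 = -0.6),
  sensitive_fraction = 0.3,
  decoy_fraction = 0.05,
  seed = 20260101)
print(spec)

bundle <- build_genome(spec)
write_genome_bundle(bundle,
                    fasta = file.path(res, "genome", "genome.fa"),
                    gff3 = file.path(res, "genome", "genes.gff3"))

truth <- assign_site_weights(spec, bundle)
print(truth)
fwrite(truth$sites, file.path(res, "truth_sites.tsv"), sep = "\t")
fwrite(truth$weights, file.path(res, "truth_weights.tsv"), sep = "\t")
fwrite(truth$genes, file.path(res, "truth_genes.tsv"), sep = "\t")
fwrite(truth$wavg, file.path(res, "truth_wavg.tsv"), sep = "\t")

counts <- sample_counts(truth, spec)
fwrite(counts, file.path(res, "sampled_counts.tsv"), sep = "\t")

manifest <- emit_reads(counts, bundle, spec, file.path(res, "reads"))
fwrite(manifest, file.path(res, "read_manifest.tsv"), sep = "\t")
cat("samples:", nrow(manifest), " reads:", sum(manifest$n_reads),
    " decoys:", sum(manifest$n_decoys), "\n")
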