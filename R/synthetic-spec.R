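#' Specification for a synthetic 3'-end sequencing experiment
#'
#' Bundles every tunable of the simulator: genome layout, poly(A)-site
#' architecture, condition-dependent usage tilts, sequencing depth and the
#' read dialect.  All simulator outputs are pure functions of the spec
#' (including its seed): the same spec yields byte-identical genomes, truth
#' ledgers, count tables and reads.
#'
#' @param n_genes number of genes to simulate.
#' @param utr_len length (nt) of each gene's 3'UTR window; endpoints are
#'   tabulated at offsets 1..`utr_len` after the stop codon.
#' @param sites_per_gene integer vector; the number of poly(A) sites per gene
#'   is drawn uniformly from this set (e.g. `4:8`).
#' @param depth_per_replicate reads sampled per gene per replicate.
#' @param n_replicates number of biological replicates per condition.
#' @param conditions named numeric vector of per-condition tilt parameters
#'   \eqn{\tau} (unitless, signed).  \eqn{\tau > 0} re-weights usage toward
#'   ORF-proximal sites, \eqn{\tau < 0} toward distal sites; \eqn{\tau = 0}
#'   leaves baseline usage untouched.  Only "sensitive" genes respond to the
#'   tilt; all other genes behave as if \eqn{\tau = 0} in every condition.
#' @param sensitive_fraction fraction of genes (in `[0,1]`) whose site usage
#'   responds to the condition tilt.
#' @param weight_concentration Dirichlet concentration for baseline site
#'   weights (1 = flat Dirichlet).
#' @param purine_enrichment optional positive exponent biasing site placement
#'   in sensitive genes toward offsets whose +/-10 nt context is purine rich;
#'   `NULL` disables the bias.
#' @param replicate_concentration optional Dirichlet concentration for
#'   per-replicate jitter of site weights; `NULL` (default) means replicates
#'   differ only by multinomial sampling noise.
#' @param t_run_range integer range for the simulated leading-T (poly(A) tail)
#'   run length of each read.
#' @param decoy_fraction fraction of extra internal-priming decoy reads
#'   (reads ending just upstream of genomic A-runs at least as long as their
#'   leading-T run) emitted alongside genuine reads.
#' @param min_site_offset smallest 3'UTR offset at which a poly(A) site may be
#'   placed; the default keeps the 17-nt mapping core of every read inside
#'   the simulated 3'UTR.
#' @param orf_len length of the stub ORF simulated upstream of each UTR.
#' @param spacer_len intergenic spacer length between simulated genes.
#' @param seed integer RNG seed; drives every stage of the simulator.
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_genes,
                           utr_len = 400L,
                           sites_per_gene = 4:8,
                           depth_per_replicate = 2000L,
                           n_replicates = 2L,
                           conditions = c(ref = 0, test = 1),
                           sensitive_fraction = 0.2,
                           weight_concentration = 1,
                           purine_enrichment = NULL,
                           replicate_concentration = NULL,
                           t_run_range = c(4L, 12L),
                           decoy_fraction = 0,
                           min_site_offset = 20L,
                           orf_len = 60L,
                           spacer_len = 50L,
                           seed = 1L) {
  stopifnot(
    n_genes >= 1, utr_len >= 1,
    all(sites_per_gene >= 1),
    depth_per_replicate > 0,
    n_replicates >= 1,
    length(conditions) >= 1, !is.null(names(conditions)), all(nzchar(names(conditions))),
    sensitive_fraction >= 0, sensitive_fraction <= 1,
    weight_concentration > 0,
    is.null(purine_enrichment) || purine_enrichment >= 0,
    is.null(replicate_concentration) || replicate_concentration > 0,
    length(t_run_range) == 2, t_run_range[1] >= 1, t_run_range[2] >= t_run_range[1],
    decoy_fraction >= 0, decoy_fraction < 1,
    min_site_offset >= 1, orf_len >= 20, spacer_len >= 20
  )
  if (max(sites_per_gene) > utr_len) {
    stop("utr_len (", utr_len, ") is too small to host ", max(sites_per_gene),
         " poly(A) sites per gene")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    utr_len = as.integer(utr_len),
    sites_per_gene = as.integer(sites_per_gene),
    depth_per_replicate = as.integer(depth_per_replicate),
    n_replicates = as.integer(n_replicates),
    conditions = conditions,
    sensitive_fraction = sensitive_fraction,
    weight_concentration = weight_concentration,
    purine_enrichment = purine_enrichment,
    replicate_concentration = replicate_concentration,
    t_run_range = as.integer(t_run_range),
    decoy_fraction = decoy_fraction,
    min_site_offset = as.integer(min_site_offset),
    orf_len = as.integer(orf_len),
    spacer_len = as.integer(spacer_len),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$n_genes, "genes,", x$utr_len, "nt UTRs,",
      length(x$conditions), "condition(s) x", x$n_replicates, "replicate(s),",
      "depth", x$depth_per_replicate, "/gene/replicate, seed", x$seed, "\n")
  cat("  tilts:", paste(names(x$conditions), x$conditions, sep = "=", collapse = ", "),
      "| sensitive fraction", x$sensitive_fraction, "\n")
  invisible(x)
}
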