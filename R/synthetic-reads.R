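#' Emit raw 3'-end reads (FASTQ) for sampled endpoint counts
#'
#' Writes one FASTQ per sample.  Each genuine read is a leading-T run (length
#' drawn uniformly from `spec$t_run_range`, standing in for the poly(A) tail)
#' followed by the reverse complement of the 17 genomic nt ending at the
#' sampled endpoint on the sense strand — the minimal structure the
#' read-processing filters act on.  Optionally a fraction of internal-priming
#' decoy reads is added: reads ending immediately upstream of genomic A-runs
#' at least as long as their leading-T run, which the priming filter must
#' remove.  Endpoints closer than 17 nt to the window start are skipped with
#' a warning.  All qualities are fixed at 'I'.
#'
#' @param counts a [sample_counts()] table.
#' @param bundle the matching `genome_bundle`.
#' @param spec the matching [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return a `data.table` with columns sample, path, n_reads, n_skipped,
#'   n_decoys.
#' @export
emit_reads <- function(counts, bundle, spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(bundle, "genome_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  min_t <- spec$t_run_range[1]; max_t <- spec$t_run_range[2]

  # candidate decoy endpoints: positions just 5' of forward-strand A-runs
  decoy_sites <- NULL
  if (spec$decoy_fraction > 0) {
    runs <- gregexpr(paste0("A{", min_t, ",}"), bundle$seqs[[1]])[[1]]
    if (runs[1] != -1L) {
      len <- attr(runs, "match.length")
      keep <- runs >= 18L
      decoy_sites <- data.table::data.table(pos = as.integer(runs[keep]) - 1L,
                                            run = len[keep])
    }
    if (is.null(decoy_sites) || nrow(decoy_sites) == 0L) {
      warning("no genomic A-runs of length >= ", min_t,
              "; decoy reads not emitted")
      decoy_sites <- NULL
    }
  }

  withr::with_seed(stage_seed(spec$seed, 4L), {
    out <- lapply(split(counts, counts$sample), function(sc) {
      smp <- sc$sample[1]
      skip <- sc$offset < 17L
      n_skipped <- sum(sc$count[skip])
      if (n_skipped > 0) {
        warning(sum(skip), " endpoint position(s) (", n_skipped,
                " reads) in sample ", smp,
                " lie < 17 nt into the 3'UTR window; reads skipped")
      }
      sc <- sc[!skip]
      cores <- revcomp(sense_core_at(bundle, sc$gene, sc$offset))
      idx <- rep(seq_len(nrow(sc)), sc$count)
      k <- sample(min_t:max_t, length(idx), replace = TRUE)
      reads <- paste0(strrep("T", k), cores[idx])
      ids <- sprintf("r%07d", seq_along(reads))

      n_decoys <- 0L
      if (!is.null(decoy_sites)) {
        n_decoys <- round(spec$decoy_fraction * length(reads))
        if (n_decoys > 0) {
          di <- sample(nrow(decoy_sites), n_decoys, replace = TRUE)
          dpos <- decoy_sites$pos[di]
          drun <- decoy_sites$run[di]
          dk <- min_t + floor(stats::runif(n_decoys) * (pmin(drun, max_t) - min_t + 1))
          dcore <- revcomp(substring(bundle$seqs[[1]], dpos - 16L, dpos))
          reads <- c(reads, paste0(strrep("T", dk), dcore))
          ids <- c(ids, sprintf("d%07d", seq_len(n_decoys)))
        }
      }
      ord <- sample(length(reads))
      dss <- Biostrings::DNAStringSet(reads[ord])
      names(dss) <- ids[ord]
      path <- file.path(dir, paste0(smp, ".fastq"))
      Biostrings::writeXStringSet(
        dss, path, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(dss))))
      data.table::data.table(sample = smp, path = path,
                             n_reads = length(reads),
                             n_skipped = n_skipped, n_decoys = n_decoys)
    })
    data.table::rbindlist(out)[]
  })
}
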