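#' Generate a synthetic mini-genome with strand-aware 3'UTR windows
#'
#' Lays out `n_genes` non-overlapping genes (alternating strands) on a single
#' random chromosome, each a stub ORF followed, in transcript orientation, by
#' a `utr_len`-nt 3'UTR endpoint window.  The genome is a pure function of
#' the spec and its seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a `genome_bundle`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (max(spec$sites_per_gene) > spec$utr_len - spec$min_site_offset + 1) {
    stop("utr_len too small to host ", max(spec$sites_per_gene),
         " sites at offsets >= ", spec$min_site_offset)
  }
  withr::with_seed(stage_seed(spec$seed, 1L), {
    glen <- spec$orf_len + spec$utr_len
    step <- glen + spec$spacer_len
    total <- spec$n_genes * step + spec$spacer_len
    chrom <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                   collapse = "")
    start <- spec$spacer_len + (seq_len(spec$n_genes) - 1L) * step + 1L
    end <- start + glen - 1L
    strand <- rep_len(c("+", "-"), spec$n_genes)
    genes <- data.table::data.table(
      gene_id = sprintf("g%04d", seq_len(spec$n_genes)),
      chrom = "chrS",
      strand = strand,
      # transcript orientation: ORF occupies the 5' part of the locus
      orf_start = ifelse(strand == "+", start, start + spec$utr_len),
      orf_end = ifelse(strand == "+", start + spec$orf_len - 1L, end),
      utr_start = ifelse(strand == "+", start + spec$orf_len, start),
      utr_end = ifelse(strand == "+", end, start + spec$utr_len - 1L),
      utr_len = spec$utr_len)
    new_genome_bundle(c(chrS = chrom), genes,
                      params = list(orf_len = spec$orf_len,
                                    spacer_len = spec$spacer_len,
                                    min_site_offset = spec$min_site_offset))
  })
}

# Count every forward-strand 17-mer of the genome; a 17-mer placed uniquely
# means count(kmer) + count(revcomp(kmer)) == 1 across both strands
# (odd-length k-mers cannot be their own reverse complement).
kmer_counts <- function(bundle, k = 17L) {
  tabs <- lapply(bundle$seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  kmers <- unlist(tabs, use.names = FALSE)
  dt <- data.table::data.table(kmer = kmers)
  dt[, list(n = .N), by = "kmer"]
}

# Sense-strand 17-mer ending at offset p of a gene (may reach into the ORF).
sense_core_at <- function(bundle, gene_id, offset, k = 17L) {
  .idx <- base::match(gene_id, bundle$genes$gene_id)
  g <- bundle$genes[.idx]
  chrom <- unname(bundle$seqs[g$chrom])
  plus <- g$strand == "+"
  pos <- ifelse(plus, g$orf_end + offset, g$orf_start - offset)
  fwd <- ifelse(plus,
                substr(chrom, pos - k + 1L, pos),
                substr(chrom, pos, pos + k - 1L))
  out <- fwd
  if (any(!plus)) out[!plus] <- revcomp(fwd[!plus])
  out
}

# Sense-strand A-run length immediately downstream (3') of an endpoint,
# capped at `cap` nt.
downstream_a_run <- function(bundle, gene_id, offset, cap = 50L) {
  .idx <- base::match(gene_id, bundle$genes$gene_id)
  g <- bundle$genes[.idx]
  chrom <- unname(bundle$seqs[g$chrom])
  plus <- g$strand == "+"
  pos <- ifelse(plus, g$orf_end + offset, g$orf_start - offset)
  down <- ifelse(plus,
                 substr(chrom, pos + 1L, pos + cap),
                 substr(chrom, pmax(pos - cap, 1L), pos - 1L))
  out <- integer(length(down))
  out[plus] <- leading_run(down[plus], "A")
  if (any(!plus)) {
    # minus-strand downstream reads leftward; A on the sense strand is T on
    # the forward strand, so count the trailing T-run of the forward slice
    rev_chunks <- vapply(strsplit(down[!plus], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
    out[!plus] <- leading_run(rev_chunks, "T")
  }
  out
}
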