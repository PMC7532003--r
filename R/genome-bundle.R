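# GenomeBundle: reference sequences plus strand-aware per-gene 3'UTR windows.
#
# Offsets are 1-based relative to the first nt after the stop codon, in
# transcript orientation; offset p of a plus-strand gene with ORF end E is
# genomic position E + p, and of a minus-strand gene with ORF start S is
# genomic position S - p (base = complement of the forward strand).

new_genome_bundle <- function(seqs, genes, params = list()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            data.table::is.data.table(genes))
  genes <- data.table::copy(genes)
  data.table::setkey(genes, gene_id)
  b <- structure(list(seqs = seqs, genes = genes, params = params),
                 class = "genome_bundle")
  b$utr_seq <- utr_sense_seqs(b)
  b
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", length(x$seqs), "sequence(s) (",
      sum(nchar(x$seqs)), "nt ),", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

# Sense-strand 3'UTR sequence for every gene (named character vector).
utr_sense_seqs <- function(bundle) {
  g <- bundle$genes
  fwd <- substr(unname(bundle$seqs[g$chrom]), g$utr_start, g$utr_end)
  out <- ifelse(g$strand == "+", fwd, revcomp(fwd))
  names(out) <- g$gene_id
  out
}

#' Map 3'UTR offsets to genomic coordinates
#'
#' @param bundle a `genome_bundle`.
#' @param gene_id gene identifier(s), recycled against `offset`.
#' @param offset 1-based offsets after the stop codon.
#' @return integer genomic positions on the gene's chromosome.
#' @export
offset_to_genomic <- function(bundle, gene_id, offset) {
  .idx <- base::match(gene_id, bundle$genes$gene_id)
  g <- bundle$genes[.idx]
  ifelse(g$strand == "+", g$orf_end + offset, g$orf_start - offset)
}

#' Sense-strand base at given 3'UTR offsets
#'
#' Offsets may lie outside the annotated window (negative offsets reach into
#' the ORF, offsets beyond `utr_len` reach downstream); bases are read from
#' the genome, and positions off the chromosome ends return `NA`.
#'
#' @inheritParams offset_to_genomic
#' @return character vector of bases (DNA alphabet) or `NA`.
#' @export
sense_base_at <- function(bundle, gene_id, offset) {
  .idx <- base::match(gene_id, bundle$genes$gene_id)
  g <- bundle$genes[.idx]
  pos <- ifelse(g$strand == "+", g$orf_end + offset, g$orf_start - offset)
  len <- nchar(bundle$seqs)[match(g$chrom, names(bundle$seqs))]
  ok <- pos >= 1 & pos <= len
  base <- rep(NA_character_, length(pos))
  if (any(ok)) {
    fwd <- substr(unname(bundle$seqs[g$chrom[ok]]), pos[ok], pos[ok])
    base[ok] <- ifelse(g$strand[ok] == "+", fwd,
                       chartr("ACGT", "TGCA", fwd))
  }
  base
}

#' Count non-A sense-strand positions in a 3'UTR window
#'
#' Endpoints are only tabulated at offsets whose sense-strand genomic base is
#' not A; this counts the eligible positions of a window, the universe size N
#' of the positional-overlap hypergeometric test.
#'
#' @param bundle a `genome_bundle`.
#' @param gene_id a single gene id.
#' @param from,to offset window (inclusive); defaults to the full UTR.
#' @return integer count of non-A positions.
#' @export
count_non_a <- function(bundle, gene_id, from = 1L, to = NULL) {
  s <- bundle$utr_seq[[gene_id]]
  if (is.null(to)) to <- nchar(s)
  stopifnot(from >= 1, to <= nchar(s), from <= to)
  win <- strsplit(substr(s, from, to), "")[[1]]
  sum(win != "A")
}

#' Serialize a genome bundle to FASTA + GFF3
#'
#' Writes the sequences as FASTA and the gene models as GFF3 (1-based
#' inclusive coordinates, strand column respected) with a `gene` feature per
#' locus and a `three_prime_UTR` feature for the 400-nt endpoint window.
#'
#' @param bundle a `genome_bundle`.
#' @param fasta,gff3 output file paths.
#' @return invisibly, the two paths.
#' @export
write_genome_bundle <- function(bundle, fasta, gff3) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$seqs), fasta)
  g <- bundle$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$orf_start, end = g$orf_end),
    strand = g$strand, type = "gene", ID = g$gene_id)
  gr_utr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$utr_start, end = g$utr_end),
    strand = g$strand, type = "three_prime_UTR",
    ID = paste0(g$gene_id, ".utr"), Parent = g$gene_id)
  rtracklayer::export(c(gr_gene, gr_utr), gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Load a genome bundle from FASTA + GFF3
#'
#' Reconstructs the strand-aware per-gene 3'UTR windows from `gene` and
#' `three_prime_UTR` features (matched by `Parent`/`ID`).
#'
#' @param fasta,gff3 input file paths.
#' @return a `genome_bundle`.
#' @export
read_genome_bundle <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  seqs_chr <- as.character(seqs)
  names(seqs_chr) <- sub("\\s.*$", "", names(seqs_chr))
  gr <- rtracklayer::import(gff3, format = "gff3")
  is_gene <- gr$type == "gene"
  is_utr <- gr$type == "three_prime_UTR"
  gene_ids <- gr$ID[is_gene]
  parent <- vapply(gr$Parent[is_utr], function(p) p[[1]], character(1))
  utr_idx <- match(gene_ids, parent)
  stopifnot(!anyNA(utr_idx))
  utr <- gr[is_utr][utr_idx]
  gn <- gr[is_gene]
  genes <- data.table::data.table(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gn)),
    strand = as.character(GenomicRanges::strand(gn)),
    orf_start = GenomicRanges::start(gn),
    orf_end = GenomicRanges::end(gn),
    utr_start = GenomicRanges::start(utr),
    utr_end = GenomicRanges::end(utr),
    utr_len = GenomicRanges::width(utr))
  new_genome_bundle(seqs_chr, genes)
}
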