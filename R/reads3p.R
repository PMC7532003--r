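# Read-level processing of 3'-end sequencing reads: leading-T parsing,
# unique exact 17-mer placement, internal-priming filtering, gene assignment
# and depth normalization.

#' Parse raw 3'-end reads: leading-T run and 17-nt mapping core
#'
#' Rejects reads containing non-ACGT symbols or not starting with T; for the
#' rest, strips the maximal leading-T run (the reverse-complemented poly(A)
#' tail), records its length, and takes the first 17 nt of the remainder as
#' the mapping core.  Reads whose remainder is shorter than 17 nt are
#' rejected.
#'
#' @param reads character vector of upper-case read sequences.
#' @return a `data.table` with columns seq, status (`"ok"`, `"ambiguous"`,
#'   `"no_leading_t"`, `"too_short"`), t_count, core17 (`NA` unless ok).
#' @export
parse_reads <- function(reads) {
  status <- rep("ok", length(reads))
  status[grepl("[^ACGT]", reads)] <- "ambiguous"
  status[status == "ok" & !startsWith(reads, "T")] <- "no_leading_t"
  t_count <- rep(NA_integer_, length(reads))
  core17 <- rep(NA_character_, length(reads))
  ok <- status == "ok"
  if (any(ok)) {
    tc <- leading_run(reads[ok], "T")
    rem <- substr(reads[ok], tc + 1L, nchar(reads[ok]))
    short <- nchar(rem) < 17L
    status[ok][short] <- "too_short"
    keep <- ok
    keep[ok] <- !short
    t_count[keep] <- tc[!short]
    core17[keep] <- substr(rem[!short], 1L, 17L)
  }
  data.table::data.table(seq = reads, status = status,
                         t_count = t_count, core17 = core17)
}

#' Place 17-nt cores on the genome by unique exact match
#'
#' Searches each core and its reverse complement over all sequences with no
#' mismatches.  A core matching exactly once (over both strands combined) is
#' placed; zero or multiple matches are rejected.  The inferred mRNA
#' endpoint is the sense-strand position adjacent to the read's leading-T
#' run: for a match of the core's reverse complement on the forward strand
#' at `[s, e]` the endpoint is `(+, e)`; for a forward match of the core
#' itself it is `(-, s)`.
#'
#' @param cores character vector of distinct 17-nt cores.
#' @param bundle a `genome_bundle`.
#' @return a `data.table` with columns core17, status (`"unique"`,
#'   `"unmapped"`, `"multi"`), chrom, strand, pos.
#' @export
place_cores <- function(cores, bundle) {
  stopifnot(!anyDuplicated(cores), all(nchar(cores) == 17L))
  n <- length(cores)
  dict_rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(cores))
  dict_fw <- Biostrings::DNAStringSet(cores)
  hits <- data.table::data.table(idx = integer(0), chrom = character(0),
                                 strand = character(0), pos = integer(0))
  acc <- list()
  for (chr in names(bundle$seqs)) {
    subj <- Biostrings::DNAString(bundle$seqs[[chr]])
    # match of revcomp(core) on forward strand -> plus-strand endpoint at end
    m_plus <- Biostrings::matchPDict(Biostrings::PDict(dict_rc), subj)
    # match of the core itself on forward strand -> minus-strand endpoint at start
    m_minus <- Biostrings::matchPDict(Biostrings::PDict(dict_fw), subj)
    np <- S4Vectors::elementNROWS(m_plus)
    nm <- S4Vectors::elementNROWS(m_minus)
    if (any(np > 0)) {
      acc[[paste0(chr, "+")]] <- data.table::data.table(
        idx = rep(seq_len(n), np), chrom = chr, strand = "+",
        pos = unlist(lapply(seq_len(n), function(i)
          BiocGenerics::end(m_plus[[i]])), use.names = FALSE))
    }
    if (any(nm > 0)) {
      acc[[paste0(chr, "-")]] <- data.table::data.table(
        idx = rep(seq_len(n), nm), chrom = chr, strand = "-",
        pos = unlist(lapply(seq_len(n), function(i)
          BiocGenerics::start(m_minus[[i]])), use.names = FALSE))
    }
  }
  hits <- if (length(acc)) data.table::rbindlist(acc) else hits
  nhit <- integer(n)
  if (nrow(hits)) {
    tab <- hits[, list(nh = .N), by = "idx"]
    nhit[tab$idx] <- tab$nh
  }
  out <- data.table::data.table(core17 = cores,
                                status = ifelse(nhit == 0L, "unmapped",
                                                ifelse(nhit > 1L, "multi", "unique")),
                                chrom = NA_character_, strand = NA_character_,
                                pos = NA_integer_)
  if (nrow(hits)) {
    uni <- hits[hits$idx %in% which(nhit == 1L)]
    out$chrom[uni$idx] <- uni$chrom
    out$strand[uni$idx] <- uni$strand
    out$pos[uni$idx] <- uni$pos
  }
  out
}

# Sense-strand A-run immediately downstream of genomic endpoints.
genomic_a_run <- function(bundle, chrom, strand, pos, cap = 50L) {
  chr_seq <- unname(bundle$seqs[chrom])
  chr_len <- nchar(bundle$seqs)[match(chrom, names(bundle$seqs))]
  plus <- strand == "+"
  down <- ifelse(plus,
                 substr(chr_seq, pos + 1L, pmin(pos + cap, chr_len)),
                 substr(chr_seq, pmax(pos - cap, 1L), pos - 1L))
  out <- integer(length(down))
  out[plus] <- leading_run(down[plus], "A")
  if (any(!plus)) {
    rev_chunks <- vapply(strsplit(down[!plus], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
    out[!plus] <- leading_run(rev_chunks, "T")
  }
  out
}

#' Internal-priming filter
#'
#' A read is kept only if its leading-T count strictly exceeds the length of
#' the consecutive-A run on the sense strand immediately downstream of its
#' inferred endpoint; otherwise the "tail" could be genomically templated
#' (oligo-dT priming on an internal A-run) rather than a poly(A) tail.
#'
#' @param t_count integer vector of leading-T counts.
#' @param a_run integer vector of downstream genomic A-run lengths.
#' @return logical keep/drop vector.
#' @export
internal_priming_keep <- function(t_count, a_run) {
  t_count > a_run
}

#' Tabulate endpoints into per-gene 3'UTR offset counts
#'
#' Each endpoint is counted for every gene whose strand matches and whose
#' 3'UTR window contains it (endpoints inside two overlapping windows are
#' counted for both genes).  Endpoints outside all windows are returned as
#' an unassigned total.  The tabulator asserts the placement-convention
#' invariant that no endpoint falls on a sense-strand A.
#'
#' @param endpoints a `data.table` with columns chrom, strand, pos, weight
#'   (reads per endpoint).
#' @param bundle a `genome_bundle`.
#' @return a list with `counts` (gene, offset, count) and `unassigned`
#'   (total weight outside all windows).
#' @export
tabulate_endpoints <- function(endpoints, bundle) {
  g <- bundle$genes
  ep <- data.table::as.data.table(endpoints)
  if (!"weight" %in% names(ep)) ep[, weight := 1]
  ep[, pos2 := pos]
  hits <- g[ep,
            on = c("chrom", "strand", "utr_start<=pos", "utr_end>=pos2"),
            nomatch = NULL,
            list(gene_id = x.gene_id, chrom = x.chrom, strand = x.strand,
                 orf_start = x.orf_start, orf_end = x.orf_end,
                 pos = i.pos, weight = i.weight)]
  counts <- data.table::data.table(gene = character(0), offset = integer(0),
                                   count = numeric(0))
  if (nrow(hits)) {
    hits[, offset := ifelse(strand == "+", pos - orf_end, orf_start - pos)]
    bases <- sense_base_at(bundle, hits$gene_id, hits$offset)
    stopifnot("endpoint tabulated at a sense-strand A position" =
                all(bases != "A", na.rm = TRUE))
    counts <- hits[, list(count = sum(weight)), by = c("gene_id", "offset")]
    data.table::setnames(counts, "gene_id", "gene")
    data.table::setorder(counts, gene, offset)
  }
  assigned <- if (nrow(hits)) {
    # an endpoint may hit several genes; count its weight once for assignment
    uniq <- unique(ep[, c("chrom", "strand", "pos", "weight"), with = FALSE])
    hit_keys <- unique(hits[, c("chrom", "strand", "pos"), with = FALSE])
    sum(uniq$weight[paste(uniq$chrom, uniq$strand, uniq$pos) %in%
                      paste(hit_keys$chrom, hit_keys$strand, hit_keys$pos)])
  } else 0
  list(counts = counts[], unassigned = sum(ep$weight) - assigned)
}

#' Scale an endpoint table to a target total depth
#'
#' Multiplies every count by `target / total` so the sample's scaled total
#' equals the target (25 million by default); scaled counts may be
#' fractional and are never re-rounded, preserving all relative proportions.
#'
#' @param counts a `data.table` with a `count` column (a single sample; if a
#'   `sample` column is present each sample is scaled independently).
#' @param target target total read count.
#' @return the table with scaled counts.
#' @export
normalize_depth <- function(counts, target = 25e6) {
  dt <- data.table::copy(data.table::as.data.table(counts))
  if (nrow(dt) == 0L || sum(dt$count) <= 0) {
    stop("cannot normalize an empty endpoint table")
  }
  if ("sample" %in% names(dt)) {
    dt[, count := count * target / sum(count), by = "sample"]
  } else {
    dt[, count := count * target / sum(count)]
  }
  dt[]
}

#' Process one FASTQ sample into an endpoint count table
#'
#' Full read-level pipeline: parse (leading-T / ambiguity rules), place the
#' 17-nt cores by unique exact match, apply the internal-priming filter,
#' assign endpoints to gene 3'UTR windows, and optionally scale to a target
#' depth.
#'
#' @param fastq path to the FASTQ file.
#' @param bundle a `genome_bundle`.
#' @param sample,condition,replicate labels attached to the output rows.
#' @param target_depth if non-`NULL`, scale the sample to this total.
#' @return a list with `counts` (sample, condition, replicate, gene, offset,
#'   count) and `stats` (reads in each rejection class).
#' @export
process_sample_fastq <- function(fastq, bundle, sample,
                                 condition = sample, replicate = 1L,
                                 target_depth = NULL) {
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  parsed <- parse_reads(unname(reads))
  ok <- parsed[parsed$status == "ok"]
  placed <- place_cores(unique(ok$core17), bundle)
  ok <- merge(ok, placed, by = "core17", sort = FALSE)
  n_unmapped <- sum(ok$status.y == "unmapped")
  n_multi <- sum(ok$status.y == "multi")
  ok <- ok[ok$status.y == "unique"]
  kept <- logical(0)
  if (nrow(ok)) {
    aruns <- genomic_a_run(bundle, ok$chrom, ok$strand, ok$pos)
    kept <- internal_priming_keep(ok$t_count, aruns)
  }
  n_primed <- sum(!kept)
  ok <- ok[kept]
  ep <- ok[, list(weight = as.numeric(.N)),
           by = c("chrom", "strand", "pos")]
  tab <- tabulate_endpoints(ep, bundle)
  counts <- tab$counts
  counts[, sample := sample]
  counts[, condition := condition]
  counts[, replicate := as.integer(replicate)]
  data.table::setcolorder(counts,
    c("sample", "condition", "replicate", "gene", "offset", "count"))
  if (!is.null(target_depth)) counts <- normalize_depth(counts, target_depth)
  stats <- data.table::data.table(
    sample = sample,
    n_total = length(reads),
    n_ambiguous = sum(parsed$status == "ambiguous"),
    n_no_leading_t = sum(parsed$status == "no_leading_t"),
    n_too_short = sum(parsed$status == "too_short"),
    n_unmapped = n_unmapped, n_multi = n_multi,
    n_internal_priming = n_primed,
    n_unassigned = tab$unassigned,
    n_tabulated = sum(counts$count > 0))
  list(counts = counts[], stats = stats)
}
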