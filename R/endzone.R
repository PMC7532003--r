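# End-zone profiling: per-gene landmarks from 3'-isoform endpoint counts,
# percentile coordinates, meta-gene summaries and replicate correlations.

#' Filter genes by combined replicate read count
#'
#' Keeps genes whose replicate-combined total is at least `min_combined`
#' (inclusive) in EVERY condition present in the table.  With the default
#' threshold of 1000 normalized reads this reproduces the analyzed-gene-set
#' rule used throughout the pipeline.
#'
#' @param counts endpoint table (columns condition, gene, count, ...).
#' @param min_combined inclusive threshold on the per-condition combined
#'   replicate total.
#' @return character vector of retained gene ids, sorted.
#' @export
filter_genes <- function(counts, min_combined = 1000) {
  dt <- data.table::as.data.table(counts)
  tot <- dt[, list(total = sum(count)), by = c("gene", "condition")]
  n_cond <- length(unique(dt$condition))
  keep <- tot[, list(ok = .N == n_cond && all(total >= min_combined)),
              by = "gene"]
  sort(keep$gene[keep$ok])
}

#' Build an end-zone profile for one gene in one condition
#'
#' Scales isoform counts so the maximally expressed isoform (max isoform) is
#' 100%, and derives the landmarks: max position (ties broken toward the
#' most ORF-proximal offset), major isoforms (scaled expression >= 5%), the
#' major end zone (region between the 5'-most and 3'-most major isoforms)
#' and its span, and the read-weighted average endpoint.
#'
#' @param offsets integer vector of 3'UTR offsets with non-zero counts.
#' @param counts numeric vector of counts (replicates already summed).
#' @return a list with elements `scaled` (named percentage vector),
#'   `max_pos`, `major` (offsets), `mez` (c(5' boundary, 3' boundary)),
#'   `span`, `wavg`, `total`; or `NULL` if the total is zero.
#' @export
build_profile <- function(offsets, counts) {
  stopifnot(length(offsets) == length(counts), all(counts >= 0))
  o <- order(offsets)
  offsets <- offsets[o]; counts <- counts[o]
  total <- sum(counts)
  if (total <= 0) return(NULL)
  mx <- max(counts)
  scaled <- 100 * counts / mx
  names(scaled) <- offsets
  max_pos <- offsets[which(counts == mx)[1]]
  major <- offsets[scaled >= 5 - 1e-9]
  mez <- range(major)
  list(scaled = scaled, max_pos = max_pos, major = major,
       mez = mez, span = diff(mez),
       wavg = sum(offsets * counts) / total, total = total)
}

#' End-zone landmarks for all genes and conditions
#'
#' Sums replicates within each condition, then computes every gene's
#' landmarks (see [build_profile()]).
#'
#' @param counts endpoint table.
#' @param gene_set optional character vector restricting the genes profiled.
#' @return a list with `landmarks` (gene, condition, total, max_pos, mez5,
#'   mez3, span, wavg, n_major) and `scaled` (gene, condition, offset,
#'   count, pct, major).
#' @export
build_profiles <- function(counts, gene_set = NULL) {
  dt <- data.table::as.data.table(counts)
  if (!is.null(gene_set)) dt <- dt[dt$gene %in% gene_set]
  pooled <- dt[, list(count = sum(count)), by = c("gene", "condition", "offset")]
  data.table::setorder(pooled, gene, condition, offset)
  pooled[, pct := 100 * count / max(count), by = c("gene", "condition")]
  pooled[, major := pct >= 5 - 1e-9]
  landmarks <- pooled[, {
    mx <- max(count)
    list(total = sum(count),
         max_pos = offset[which(count == mx)[1]],
         mez5 = min(offset[major]),
         mez3 = max(offset[major]),
         wavg = sum(offset * count) / sum(count),
         n_major = sum(major))
  }, by = c("gene", "condition")]
  landmarks[, span := mez3 - mez5]
  data.table::setcolorder(landmarks, c("gene", "condition", "total", "max_pos",
                                       "mez5", "mez3", "span", "wavg", "n_major"))
  list(landmarks = landmarks[], scaled = pooled[])
}

#' Percentile coordinates of a single endpoint distribution
#'
#' The q-percentile coordinate is the smallest offset at which the
#' cumulative read count (upstream of and including that offset) reaches q%
#' of the gene's total.
#'
#' @param offsets integer offsets with non-zero counts.
#' @param counts numeric counts.
#' @param qs percentiles, in percent.
#' @return named integer vector of coordinates (names = percentiles).
#' @export
percentile_coords <- function(offsets, counts, qs = c(10, 25, 50, 75, 90)) {
  o <- order(offsets)
  offsets <- offsets[o]; counts <- counts[o]
  total <- sum(counts)
  stopifnot(total > 0)
  cs <- cumsum(counts)
  out <- vapply(qs, function(q) {
    offsets[which(cs >= q * total / 100 - 1e-9)[1]]
  }, numeric(1))
  names(out) <- qs
  out
}

#' Percentile coordinates per gene, condition and replicate
#'
#' @param counts endpoint table.
#' @param qs percentiles, in percent.
#' @param gene_set optional restriction of the genes used.
#' @return a `data.table` (gene, condition, replicate, q, coord).
#' @export
percentile_table <- function(counts, qs = c(10, 25, 50, 75, 90),
                             gene_set = NULL) {
  dt <- data.table::as.data.table(counts)
  if (!is.null(gene_set)) dt <- dt[dt$gene %in% gene_set]
  data.table::setorder(dt, gene, condition, replicate, offset)
  dt[, {
    cs <- cumsum(count)
    tot <- cs[length(cs)]
    list(q = qs,
         coord = vapply(qs, function(qq)
           offset[which(cs >= qq * tot / 100 - 1e-9)[1]], numeric(1)))
  }, by = c("gene", "condition", "replicate")]
}

#' Genome-wide landmark medians and meta-gene profiles
#'
#' Per condition, the medians across genes of each landmark (max position,
#' weighted average, major end zone boundaries, span) and the mean
#' scaled-percentage meta-gene profile over offsets 1..`utr_len`.  For each
#' requested comparison, a paired two-sided Wilcoxon signed-rank test across
#' genes per landmark, flagged at `alpha`.
#'
#' @param profiles a [build_profiles()] result.
#' @param comparisons list of `c(test, ref)` condition pairs (may be empty).
#' @param utr_len window length for the meta-gene profile.
#' @param alpha significance threshold for flagging.
#' @return a list with `medians` (condition x landmark), `tests`
#'   (comparison, landmark, p, flagged) and `metagene` (condition, offset,
#'   mean_pct).
#' @export
landmark_summary <- function(profiles, comparisons = list(),
                             utr_len = 400L, alpha = 0.01) {
  lm <- profiles$landmarks
  vars <- c("max_pos", "wavg", "mez5", "mez3", "span")
  med <- lm[, lapply(.SD, stats::median), by = "condition", .SDcols = vars]

  n_genes <- length(unique(lm$gene))
  sc <- profiles$scaled
  meta <- sc[, list(mean_pct = sum(pct) / n_genes),
             by = c("condition", "offset")]
  full <- data.table::CJ(condition = unique(lm$condition),
                         offset = seq_len(utr_len))
  meta <- meta[full, on = c("condition", "offset")]
  meta[is.na(mean_pct), mean_pct := 0]

  tests <- data.table::data.table(comparison = character(0),
                                  landmark = character(0),
                                  p = numeric(0), flagged = logical(0))
  if (length(comparisons)) {
    rows <- list()
    for (cmp in comparisons) {
      a <- lm[lm$condition == cmp[1]]
      b <- lm[lm$condition == cmp[2]]
      common <- intersect(a$gene, b$gene)
      if (length(common) < 2) next
      a <- a[match(common, a$gene)]; b <- b[match(common, b$gene)]
      for (v in vars) {
        d <- a[[v]] - b[[v]]
        p <- if (all(d == 0)) 1 else
          suppressWarnings(stats::wilcox.test(a[[v]], b[[v]],
                                              paired = TRUE)$p.value)
        rows[[paste(cmp[1], cmp[2], v)]] <- data.table::data.table(
          comparison = paste(cmp[1], "vs", cmp[2]), landmark = v,
          p = p, flagged = p < alpha)
      }
    }
    if (length(rows)) tests <- data.table::rbindlist(rows)
  }
  list(medians = med[], tests = tests[], metagene = meta[])
}

#' Percent coordinate usage across the 3'UTR
#'
#' For each offset, 100 x (number of genes with non-zero reads at that
#' offset) / (number of genes whose sense-strand base at that offset is not
#' A).  Offsets where no gene has a non-A base are reported as `NA`.
#'
#' @param counts endpoint table (samples pooled).
#' @param bundle a `genome_bundle`.
#' @param gene_set genes to include.
#' @param utr_len window length.
#' @return a `data.table` (offset, n_non_a, n_covered, pct_usage).
#' @export
percent_coordinate_usage <- function(counts, bundle, gene_set,
                                     utr_len = 400L) {
  dt <- data.table::as.data.table(counts)
  dt <- dt[dt$gene %in% gene_set]
  seqs <- bundle$utr_seq[gene_set]
  mat <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    length(b) <- utr_len
    b != "A" & !is.na(b)
  }, logical(utr_len))
  n_non_a <- rowSums(mat)
  cov <- dt[dt$count > 0, list(n = data.table::uniqueN(gene)), by = "offset"]
  n_cov <- integer(utr_len)
  n_cov[cov$offset] <- cov$n
  data.table::data.table(
    offset = seq_len(utr_len), n_non_a = n_non_a, n_covered = n_cov,
    pct_usage = ifelse(n_non_a > 0, 100 * n_cov / n_non_a, NA_real_))
}

#' Replicate reproducibility at three levels
#'
#' For one condition with exactly two replicates: (i) Pearson correlation of
#' per-gene totals; (ii) Pearson correlation of individual isoform counts
#' genome-wide, omitting isoforms with fewer than `min_isoform_reads` reads
#' in both replicates; (iii) per-gene Pearson correlation of max-scaled
#' profiles over the full `utr_len`-offset vector.
#'
#' @param counts endpoint table for a single condition, two replicates.
#' @param gene_set genes used for the per-gene profile correlations.
#' @param min_isoform_reads isoform-level inclusion threshold.
#' @param utr_len profile vector length.
#' @return a list with `total_r`, `isoform_r`, `n_isoforms`, and
#'   `profile_r` (data.table gene, r).
#' @export
replicate_correlations <- function(counts, gene_set = NULL,
                                   min_isoform_reads = 10, utr_len = 400L) {
  dt <- data.table::as.data.table(counts)
  reps <- sort(unique(dt$replicate))
  stopifnot("exactly two replicates required" = length(reps) == 2)

  tot <- data.table::dcast(dt[, list(n = sum(count)), by = c("gene", "replicate")],
                           gene ~ replicate, value.var = "n", fill = 0)
  total_r <- stats::cor(tot[[2]], tot[[3]])

  iso <- data.table::dcast(dt, gene + offset ~ replicate,
                           value.var = "count", fill = 0,
                           fun.aggregate = sum)
  keep <- pmax(iso[[3]], iso[[4]]) >= min_isoform_reads
  iso <- iso[keep]
  isoform_r <- if (nrow(iso) >= 2) stats::cor(iso[[3]], iso[[4]]) else NA_real_

  if (is.null(gene_set)) gene_set <- unique(dt$gene)
  pr <- dt[dt$gene %in% gene_set]
  profile_r <- pr[, {
    v1 <- numeric(utr_len); v2 <- numeric(utr_len)
    s1 <- replicate == reps[1]
    v1[offset[s1]] <- count[s1]
    v2[offset[!s1]] <- count[!s1]
    if (max(v1) > 0) v1 <- 100 * v1 / max(v1)
    if (max(v2) > 0) v2 <- 100 * v2 / max(v2)
    r <- if (stats::sd(v1) > 0 && stats::sd(v2) > 0)
      stats::cor(v1, v2) else NA_real_
    list(r = r)
  }, by = "gene"]
  list(total_r = total_r, isoform_r = isoform_r, n_isoforms = nrow(iso),
       profile_r = profile_r[])
}
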