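# Sequence context around cleavage/polyadenylation sites and Pol II
# occupancy (processivity) summaries.

#' Nucleotide composition around max-isoform endpoints
#'
#' For each gene category, tallies the sense-strand base at signed positions
#' around the max-isoform cleavage site.  Position -1 is the last
#' genomically encoded nucleotide (the endpoint base itself, immediately
#' upstream of the poly(A) tail); position 0 does not exist; positive
#' positions are genomic sequence downstream of the cleavage site, not part
#' of the mRNA.  Percentages are over the genes of the category with a
#' defined base at the position; genes whose window runs off the sequence
#' end are skipped there and counted in the exclusion log.
#'
#' @param landmarks the `landmarks` table of [build_profiles()] for one
#'   condition (uses `max_pos`).
#' @param bundle a `genome_bundle`.
#' @param categories named list of gene-id vectors.
#' @param w half-window width in nt.
#' @param alphabet `"RNA"` (report U for T, mirroring the transcript) or
#'   `"DNA"`.
#' @return a `data.table` (category, position, base, pct, n_genes) plus an
#'   `exclusions` attribute (category, position, n_skipped).
#' @export
composition_around_max <- function(landmarks, bundle, categories,
                                   w = 10L, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  lm <- data.table::as.data.table(landmarks)
  positions <- c(-(w:1), 1:w)
  out <- list(); excl <- list()
  for (cat in names(categories)) {
    gset <- intersect(categories[[cat]], lm$gene)
    mp <- lm$max_pos[match(gset, lm$gene)]
    for (j in positions) {
      # -1 is the endpoint base itself; -2 the base before it; +1 the first
      # base past the cleavage site
      off <- if (j < 0) mp + j + 1L else mp + j
      bases <- sense_base_at(bundle, gset, off)
      def <- !is.na(bases)
      n <- sum(def)
      if (alphabet == "RNA") bases <- chartr("T", "U", bases)
      abc <- if (alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
      tab <- table(factor(bases[def], levels = abc))
      out[[paste(cat, j)]] <- data.table::data.table(
        category = cat, position = j, base = abc,
        pct = if (n > 0) 100 * as.numeric(tab) / n else NA_real_,
        n_genes = n)
      if (n < length(gset)) {
        excl[[paste(cat, j)]] <- data.table::data.table(
          category = cat, position = j, n_skipped = length(gset) - n)
      }
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "exclusions",
                      if (length(excl)) data.table::rbindlist(excl)
                      else data.table::data.table())
  res[]
}

#' Pol II processivity ratio
#'
#' The promoter/ORF occupancy ratio of the test condition divided by the
#' same ratio in the reference condition.  Values above 1 indicate
#' disproportionate promoter accumulation (reduced processivity) in the
#' test condition.  All occupancies must be positive.
#'
#' @param prom_ref,orf_ref background-subtracted promoter and ORF occupancy
#'   in the reference condition (arbitrary units).
#' @param prom_test,orf_test occupancies in the test condition.
#' @return numeric ratio(s).
#' @export
#' @examples
#' processivity_ratio(2, 1, 8, 1)  # 4
processivity_ratio <- function(prom_ref, orf_ref, prom_test, orf_test) {
  if (any(c(prom_ref, orf_ref, prom_test, orf_test) <= 0)) {
    stop("occupancies must be positive for ratio computation")
  }
  (prom_test / orf_test) / (prom_ref / orf_ref)
}

#' Correlation of processivity ratio with end zone shift
#'
#' Pearson correlation, across genes, of the processivity ratio with the
#' net overall end zone shift; requires at least three genes with both
#' quantities, and returns `NA` when either variable is constant.
#'
#' @param ratios a `data.table` (gene, ratio).
#' @param shifts a `data.table` (gene, net_overall).
#' @return a list with `r`, `n` and the merged `table`.
#' @export
shift_vs_processivity <- function(ratios, shifts) {
  dt <- merge(data.table::as.data.table(ratios),
              data.table::as.data.table(shifts), by = "gene")
  dt <- dt[stats::complete.cases(dt)]
  if (nrow(dt) < 3) stop("need at least 3 genes with both quantities")
  r <- if (stats::sd(dt$ratio) > 0 && stats::sd(dt$net_overall) > 0)
    stats::cor(dt$ratio, dt$net_overall) else NA_real_
  list(r = r, n = nrow(dt), table = dt[])
}

#' Simulate ChIP occupancy records with a shift-linked processivity ratio
#'
#' Synthetic stand-in for promoter/ORF Pol II occupancy measurements: the
#' log processivity ratio is a linear function of the gene's (negative) net
#' overall end zone shift plus Gaussian noise, and the four occupancies are
#' positive draws consistent with that ratio.
#'
#' @param shifts a `data.table` (gene, net_overall).
#' @param slope change in log-ratio per nt of upstream shift.
#' @param noise_sd standard deviation of the log-ratio noise.
#' @param seed RNG seed.
#' @return a `data.table` (gene, prom_ref, orf_ref, prom_test, orf_test,
#'   ratio).
#' @export
simulate_occupancy <- function(shifts, slope = 0.05, noise_sd = 0.2,
                               seed = 1L) {
  dt <- data.table::as.data.table(shifts)
  withr::with_seed(stage_seed(seed, 6L), {
    lr <- slope * (-dt$net_overall) + stats::rnorm(nrow(dt), 0, noise_sd)
    orf_ref <- stats::runif(nrow(dt), 0.5, 2)
    prom_ref <- orf_ref * stats::runif(nrow(dt), 0.8, 1.6)
    orf_test <- stats::runif(nrow(dt), 0.5, 2)
    prom_test <- orf_test * (prom_ref / orf_ref) * exp(lr)
    data.table::data.table(gene = dt$gene, prom_ref = prom_ref,
                           orf_ref = orf_ref, prom_test = prom_test,
                           orf_test = orf_test,
                           ratio = (prom_test / orf_test) / (prom_ref / orf_ref))
  })
}
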