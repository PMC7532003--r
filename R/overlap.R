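# Conservation of poly(A) endpoints: combined major end zones and the
# hypergeometric probability that positional overlap of major isoforms
# between two conditions arises by chance.

#' Upper-tail hypergeometric probability of positional overlap
#'
#' Probability that two sets of `a` and `b` positions drawn independently
#' and uniformly from `n` eligible positions share at least `c` positions:
#' \deqn{P(q) = \sum_{i=c}^{\min(\alpha,\beta)}
#'   \binom{\beta}{i}\binom{N-\beta}{\alpha-i} / \binom{N}{\alpha}.}
#' Binomial coefficients are evaluated in log space, so universes of
#' thousands of positions (or genes — the same survival function applies to
#' gene-set overlap) pose no overflow problem.
#'
#' @param n universe size N (e.g. non-A positions of the combined major end
#'   zone, or genes analyzed).
#' @param a,b sizes of the two sets.
#' @param c_shared observed overlap.
#' @return P(q), the probability of an overlap at least as large by chance.
#' @export
#' @examples
#' overlap_probability(10, 3, 3, 3)  # 1/choose(10,3)
overlap_probability <- function(n, a, b, c_shared) {
  stopifnot(length(n) == 1, a >= 0, b >= 0, c_shared >= 0,
            a <= n, b <= n, c_shared <= min(a, b))
  if (a + b - c_shared > n) {
    stop("impossible configuration: a + b - c exceeds the universe size")
  }
  if (c_shared == 0) return(1)
  i <- c_shared:min(a, b)
  sum(exp(lchoose(b, i) + lchoose(n - b, a - i) - lchoose(n, a)))
}

#' Combined major end zone across conditions
#'
#' Per gene, the union of the major end zones over every condition: the 5'
#' boundary is the most ORF-proximal major isoform seen in any condition and
#' the 3' boundary the most distal.  The number of eligible non-A positions
#' inside the window is the universe size for the positional-overlap test.
#'
#' @param scaled the `scaled` table of [build_profiles()] covering all
#'   conditions.
#' @param bundle a `genome_bundle`.
#' @return a `data.table` (gene, cmz5, cmz3, n_non_a); genes with no major
#'   isoform anywhere are excluded.
#' @export
combined_major_end_zone <- function(scaled, bundle) {
  sc <- data.table::as.data.table(scaled)
  mj <- sc[sc$major == TRUE]
  cz <- mj[, list(cmz5 = min(offset), cmz3 = max(offset)), by = "gene"]
  cz[, n_non_a := mapply(function(g, lo, hi)
    count_non_a(bundle, g, lo, hi), gene, cmz5, cmz3)]
  cz[]
}

#' Per-gene positional-overlap probabilities between two conditions
#'
#' For each gene: alpha = number of major isoforms in condition A, beta = in
#' condition B, c = shared major isoform positions, N = non-A positions in
#' the combined major end zone (across ALL conditions in `scaled`) or, for
#' the permissive variant, in the gene's full 3'UTR.  Genes require at least
#' one major isoform in both conditions.
#'
#' @param scaled the `scaled` table of [build_profiles()].
#' @param bundle a `genome_bundle`.
#' @param cond_a,cond_b the two conditions compared.
#' @param window `"combined"` (combined major end zone) or `"full"` (whole
#'   3'UTR).
#' @return a list with `table` (gene, n, alpha, beta, c_shared, p) and
#'   `median_p`.
#' @export
genewise_overlap_summary <- function(scaled, bundle, cond_a, cond_b,
                                     window = c("combined", "full")) {
  window <- match.arg(window)
  sc <- data.table::as.data.table(scaled)
  mj <- sc[sc$major == TRUE]
  ma <- mj[mj$condition == cond_a, list(gene, offset)]
  mb <- mj[mj$condition == cond_b, list(gene, offset)]
  genes <- intersect(unique(ma$gene), unique(mb$gene))
  if (window == "combined") {
    cz <- combined_major_end_zone(sc, bundle)
    nsize <- cz$n_non_a[match(genes, cz$gene)]
  } else {
    nsize <- vapply(genes, function(g) count_non_a(bundle, g), integer(1))
  }
  tab <- data.table::rbindlist(lapply(seq_along(genes), function(i) {
    g <- genes[i]
    oa <- ma$offset[ma$gene == g]
    ob <- mb$offset[mb$gene == g]
    cs <- length(intersect(oa, ob))
    data.table::data.table(gene = g, n = nsize[i],
                           alpha = length(oa), beta = length(ob),
                           c_shared = cs,
                           p = overlap_probability(nsize[i], length(oa),
                                                   length(ob), cs))
  }))
  list(table = tab[], median_p = stats::median(tab$p))
}
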