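# Replicate-calibrated percentile-shift statistics: raw shifts, empirical
# error model, net shifts, per-gene probabilities and direction calls.

#' Raw percentile shift between two conditions
#'
#' The average over replicate pairs of the test-minus-reference percentile
#' coordinate difference, rounded half-away-from-zero to the nearest nt.
#' With the test-minus-reference sign convention a negative shift is
#' upstream (shorter 3'UTR isoforms in the test condition).
#'
#' @param t1,t2 test-condition percentile coordinates, replicates 1 and 2.
#' @param r1,r2 reference-condition coordinates, replicates 1 and 2.
#' @return signed integer shift(s) in nt.
#' @export
raw_shift <- function(t1, t2, r1, r2) {
  round_half_away(((t1 - r1) + (t2 - r2)) / 2)
}

#' Replicate-derived percentile error
#'
#' The within-condition replicate coordinate differences of the test and
#' reference conditions are averaged, and the rounded absolute value is the
#' percentile error: the reproducibility-scale against which raw shifts are
#' judged.
#'
#' @inheritParams raw_shift
#' @return non-negative integer error(s) in nt.
#' @export
percentile_error <- function(t1, t2, r1, r2) {
  round_half_away(abs(((t1 - t2) + (r1 - r2)) / 2))
}

#' Build the empirical percentile-error model
#'
#' Tabulates the magnitude-frequency distribution f(i) of the percentile
#' errors over the analyzed gene set, halving the frequencies of all
#' non-zero magnitudes to account for the error being equally likely
#' positive or negative.  Tail probabilities follow
#' \deqn{P(x) = \sum_{i=x}^{Max} f(i) / G}
#' with G the number of genes; magnitudes beyond the largest observed error
#' are assigned the floor probability 1/G.
#'
#' @param errors integer vector of percentile errors, one per gene.
#' @return an object of class `error_model`: list with `f` (frequencies over
#'   magnitudes 0..max), `G`, `max_mag`, `floor`, `Px` (tail probabilities
#'   for x = 0..max).
#' @export
build_error_model <- function(errors) {
  stopifnot(length(errors) > 0, all(errors >= 0), all(errors == round(errors)))
  G <- length(errors)
  max_mag <- max(errors)
  f <- numeric(max_mag + 1)
  tab <- table(errors)
  f[as.integer(names(tab)) + 1L] <- as.numeric(tab)
  f[-1L] <- f[-1L] / 2
  Px <- rev(cumsum(rev(f))) / G
  structure(list(f = f, G = G, max_mag = max_mag, floor = 1 / G, Px = Px),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("error_model over", x$G, "genes; max magnitude", x$max_mag,
      "; floor", signif(x$floor, 3), "\n")
  invisible(x)
}

#' Tail probability of an error magnitude
#'
#' P(|k|) that a net shift of magnitude |k| arises from replicate noise
#' alone; magnitudes beyond the model's largest observed error receive the
#' floor probability 1/G.
#'
#' @param model an [build_error_model()] object.
#' @param x non-negative integer magnitude(s).
#' @return numeric probabilities.
#' @export
error_tail_prob <- function(model, x) {
  stopifnot(all(x >= 0))
  ifelse(x > model$max_mag, model$floor, model$Px[x + 1L])
}

#' Net percentile shift
#'
#' The raw shift diminished by the percentile error: |k| = |raw| - error
#' with the raw shift's sign, set to zero whenever the error equals or
#' exceeds the raw magnitude.
#'
#' @param raw signed raw shift(s).
#' @param error non-negative error(s).
#' @return signed integer net shift(s) k.
#' @export
net_shift <- function(raw, error) {
  sign(raw) * pmax(0, abs(raw) - error)
}

#' Per-gene shift probability P(g)
#'
#' Multiplies the five per-percentile tail probabilities P(|k|) and the
#' multiple-testing factor 5, capped at 1.
#'
#' @param k numeric vector of the five net shifts (or their magnitudes).
#' @param models list of five `error_model`s, one per percentile, in the
#'   same order as `k`.
#' @return P(g) in (0, 1].
#' @export
gene_probability <- function(k, models) {
  stopifnot(length(k) == length(models))
  p <- mapply(function(ki, m) error_tail_prob(m, abs(ki)), k, models)
  min(1, 5 * prod(p))
}

#' Direction call for one strain comparison
#'
#' A gene is upshifted iff its cumulative net shift and net number of
#' positions shifted are both negative and P(g) < alpha; downshifted iff
#' both are positive and P(g) < alpha; otherwise "other".
#'
#' @param sum_k cumulative net shift(s).
#' @param net_pos net number of positions shifted.
#' @param p_g per-gene probability.
#' @param alpha significance threshold.
#' @return character vector of calls.
#' @export
classify_strain <- function(sum_k, net_pos, p_g, alpha = 0.01) {
  ifelse(sum_k < 0 & net_pos < 0 & p_g < alpha, "upshifted",
         ifelse(sum_k > 0 & net_pos > 0 & p_g < alpha, "downshifted",
                "other"))
}

#' Assess percentile shifts of all genes between two conditions
#'
#' End-to-end shift statistic for one comparison: per gene and percentile
#' the raw shift and replicate error, the per-percentile empirical error
#' models over the supplied gene set, net shifts, the cumulative net shift,
#' the net number of positions shifted, P(g) and the direction call.
#'
#' @param pcoords a [percentile_table()] result covering both conditions
#'   with two replicates each.
#' @param test,ref condition labels (shift sign is test minus reference, so
#'   negative = upstream).
#' @param alpha significance threshold for the direction call.
#' @return a list with `assessment` (one row per gene: net shifts k per
#'   percentile, sum_k, net_pos, p_g, call) and `models` (per-percentile
#'   error models).
#' @export
assess_shifts <- function(pcoords, test, ref, alpha = 0.01) {
  pc <- data.table::as.data.table(pcoords)
  pc <- pc[pc$condition %in% c(test, ref)]
  wide <- data.table::dcast(pc, gene + q ~ condition + replicate,
                            value.var = "coord")
  tcols <- paste(test, 1:2, sep = "_")
  rcols <- paste(ref, 1:2, sep = "_")
  stopifnot(all(c(tcols, rcols) %in% names(wide)))
  wide <- wide[stats::complete.cases(wide[, c(tcols, rcols), with = FALSE])]
  # only genes with all five percentiles in all four samples
  nq <- length(unique(wide$q))
  full <- wide[, list(n = .N), by = "gene"]
  wide <- wide[wide$gene %in% full$gene[full$n == nq]]

  wide[, raw := raw_shift(get(tcols[1]), get(tcols[2]),
                          get(rcols[1]), get(rcols[2]))]
  wide[, err := percentile_error(get(tcols[1]), get(tcols[2]),
                                 get(rcols[1]), get(rcols[2]))]
  qs <- sort(unique(wide$q))
  models <- lapply(qs, function(qq) build_error_model(wide$err[wide$q == qq]))
  names(models) <- qs
  wide[, k := net_shift(raw, err)]
  wide[, p_k := error_tail_prob(models[[as.character(q)]], abs(k)), by = "q"]

  assess <- wide[, list(sum_k = sum(k), net_pos = sum(sign(k)),
                        p_g = min(1, 5 * prod(p_k))), by = "gene"]
  kw <- data.table::dcast(wide, gene ~ q, value.var = "k")
  data.table::setnames(kw, as.character(qs), paste0("k", qs))
  assess <- merge(kw, assess, by = "gene")
  assess[, call := classify_strain(sum_k, net_pos, p_g, alpha)]
  assess[, net_overall := sum_k / length(qs)]
  list(assessment = assess[], models = models,
       test = test, ref = ref, alpha = alpha)
}

#' Combined multi-strain classification
#'
#' Combines per-strain direction calls into the four-way classification:
#' Upstream = upshifted in both slow strains (fast behavior ignored);
#' Downstream = downshifted in both fast strains (slow behavior ignored);
#' Neutral = "other" in all four strains; Other = remainder.  Genes in both
#' the Upstream and Downstream criteria sets carry `both = TRUE` (the
#' speed-sensitive "Both" sub-category) and are labelled Upstream in the
#' single `class` column; the logical columns `upstream` and `downstream`
#' give the overlapping sets themselves.
#'
#' @param calls a `data.table` (gene, strain, call) with calls for all four
#'   strains; genes missing any strain are excluded.
#' @param slow,fast character vectors of the two slow and two fast strain
#'   labels.
#' @return a `data.table` (gene, upstream, downstream, both, class).
#' @export
classify_combined <- function(calls, slow, fast) {
  stopifnot(length(slow) == 2, length(fast) == 2)
  dt <- data.table::as.data.table(calls)
  wide <- data.table::dcast(dt, gene ~ strain, value.var = "call")
  need <- c(slow, fast)
  stopifnot(all(need %in% names(wide)))
  wide <- wide[stats::complete.cases(wide[, need, with = FALSE])]
  up <- wide[[slow[1]]] == "upshifted" & wide[[slow[2]]] == "upshifted"
  down <- wide[[fast[1]]] == "downshifted" & wide[[fast[2]]] == "downshifted"
  neutral <- Reduce(`&`, lapply(need, function(s) wide[[s]] == "other"))
  data.table::data.table(
    gene = wide$gene, upstream = up, downstream = down, both = up & down,
    class = ifelse(up, "Upstream",
                   ifelse(down, "Downstream",
                          ifelse(neutral, "Neutral", "Other"))))
}

#' Net shift in weighted-average endpoint position
#'
#' The average test-minus-reference difference of per-replicate weighted
#' average endpoints, diminished by the absolute value of the averaged
#' within-condition replicate differences; set to zero when the
#' between-condition shift is smaller in magnitude than the replicate
#' scale.
#'
#' @inheritParams raw_shift
#' @return signed real net shift(s) in nt.
#' @export
weighted_average_net_shift <- function(t1, t2, r1, r2) {
  s <- ((t1 - r1) + (t2 - r2)) / 2
  e <- abs(((t1 - t2) + (r1 - r2)) / 2)
  sign(s) * pmax(0, abs(s) - e)
}

#' Net overall end zone shift
#'
#' The mean of the five percentile net shifts (sum_k / 5), in nt; when two
#' same-speed strains are combined, average their two values.
#'
#' @param sum_k cumulative net shift(s) over the five percentiles.
#' @param n_percentiles number of percentile categories.
#' @return real net overall shift(s) in nt.
#' @export
net_overall_shift <- function(sum_k, n_percentiles = 5L) {
  sum_k / n_percentiles
}
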