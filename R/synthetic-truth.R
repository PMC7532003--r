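#' Assign poly(A)-site architectures and condition-dependent usage weights
#'
#' Draws, for every gene, a set of poly(A)-site offsets at eligible non-A
#' sense-strand positions and Dirichlet baseline usage weights, then derives
#' per-condition effective weights by the exponential tilt
#' \deqn{w'_i \propto w_i \exp(-\tau p_i / 100)}
#' (renormalized), where \eqn{p_i} is the site offset.  A positive tilt
#' re-weights usage toward ORF-proximal sites without creating new ones;
#' genes outside the sensitive fraction use \eqn{\tau = 0} in all conditions.
#'
#' Eligible offsets satisfy: sense-strand base is not A; the downstream
#' genomic A-run is shorter than the minimum simulated leading-T run (so no
#' genuine read is lost to the internal-priming filter); and the 17-mer
#' ending at the site occurs exactly once in the genome (so placement is
#' unique and count recovery is exact).
#'
#' @param spec a [synthetic_spec()].
#' @param bundle the matching [build_genome()] output.
#' @return an object of class `synthetic_truth`: a list with `sites`
#'   (gene_id, offset, base_weight), `weights` (gene_id, offset, condition,
#'   weight), `genes` (gene_id, sensitive, n_sites) and `wavg` (gene_id,
#'   condition, true_wavg — the analytic weighted-mean endpoint).
#' @export
assign_site_weights <- function(spec, bundle) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(bundle, "genome_bundle"))
  kc <- kmer_counts(bundle)
  withr::with_seed(stage_seed(spec$seed, 2L), {
    gene_ids <- bundle$genes$gene_id
    n_sens <- round(spec$sensitive_fraction * spec$n_genes)
    sensitive_ids <- sample(gene_ids, n_sens)
    conds <- spec$conditions
    min_t <- spec$t_run_range[1]

    site_list <- vector("list", length(gene_ids))
    for (i in seq_along(gene_ids)) {
      gid <- gene_ids[i]
      offs <- spec$min_site_offset:spec$utr_len
      bases <- strsplit(bundle$utr_seq[[gid]], "")[[1]][offs]
      cand <- offs[bases != "A"]
      if (length(cand)) {
        runs <- downstream_a_run(bundle, rep(gid, length(cand)), cand)
        cand <- cand[runs < min_t]
      }
      if (length(cand)) {
        cores <- sense_core_at(bundle, rep(gid, length(cand)), cand)
        cnt <- function(x) {
          n <- kc$n[match(x, kc$kmer)]
          n[is.na(n)] <- 0L
          n
        }
        n_occ <- cnt(cores) + cnt(revcomp(cores))
        cand <- cand[n_occ == 1L]
      }
      n_sites <- if (length(spec$sites_per_gene) == 1L) spec$sites_per_gene
                 else sample(spec$sites_per_gene, 1L)
      if (length(cand) < n_sites) {
        stop("gene ", gid, " has only ", length(cand),
             " eligible poly(A)-site positions; cannot place ", n_sites,
             " sites (utr_len too small or too repetitive)")
      }
      prob <- NULL
      if (!is.null(spec$purine_enrichment) && gid %in% sensitive_ids) {
        pur <- vapply(cand, function(p) {
          win <- strsplit(bundle$utr_seq[[gid]], "")[[1]]
          idx <- max(1L, p - 10L):min(spec$utr_len, p + 10L)
          mean(win[idx] %in% c("A", "G"))
        }, numeric(1))
        prob <- pur^spec$purine_enrichment
      }
      sites <- sort(sample(cand, n_sites, prob = prob))
      w <- stats::rgamma(n_sites, shape = spec$weight_concentration)
      if (sum(w) <= 0) w <- rep(1, n_sites)
      site_list[[i]] <- data.table::data.table(
        gene_id = gid, offset = sites, base_weight = w / sum(w))
    }
    sites <- data.table::rbindlist(site_list)

    ns <- sites[, list(n_sites = .N), by = "gene_id"]
    genes <- data.table::data.table(
      gene_id = gene_ids,
      sensitive = gene_ids %in% sensitive_ids,
      n_sites = ns$n_sites[match(gene_ids, ns$gene_id)])

    weights <- data.table::rbindlist(lapply(names(conds), function(cn) {
      tau <- conds[[cn]]
      w <- data.table::copy(sites)
      w[, condition := cn]
      w[, tau_eff := ifelse(gene_id %in% sensitive_ids, tau, 0)]
      w[, weight := base_weight * exp(-tau_eff * offset / 100)]
      w[, weight := weight / sum(weight), by = "gene_id"]
      w[, c("gene_id", "offset", "condition", "weight"), with = FALSE]
    }))
    wavg <- weights[, list(true_wavg = sum(offset * weight)),
                    by = c("gene_id", "condition")]
    structure(list(sites = sites, weights = weights, genes = genes,
                   wavg = wavg, conditions = conds),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$genes), "genes,",
      sum(x$genes$sensitive), "sensitive,",
      nrow(x$sites), "poly(A) sites,",
      length(x$conditions), "condition(s)\n")
  invisible(x)
}

#' Sample multinomial endpoint counts per condition and replicate
#'
#' For every gene, condition and replicate, draws read counts over the
#' gene's poly(A)-site offsets from a multinomial with the condition's
#' effective weights at the configured depth.  By default replicates differ
#' only by multinomial sampling noise; if `spec$replicate_concentration` is
#' set, per-replicate weights are jittered by a Dirichlet draw centred on
#' the condition weights.
#'
#' @param truth an [assign_site_weights()] result.
#' @param spec the matching [synthetic_spec()].
#' @return a `data.table` with columns sample, condition, replicate, gene,
#'   offset, count (one row per non-zero cell).
#' @export
sample_counts <- function(truth, spec) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(spec, "synthetic_spec"))
  withr::with_seed(stage_seed(spec$seed, 3L), {
    w <- truth$weights
    data.table::setkey(w, condition, gene_id, offset)
    out <- list()
    for (cn in names(truth$conditions)) {
      wc <- w[w$condition == cn]
      gsplit <- split(wc, wc$gene_id)
      for (r in seq_len(spec$n_replicates)) {
        rows <- lapply(gsplit, function(g) {
          p <- g$weight
          if (!is.null(spec$replicate_concentration)) {
            a <- stats::rgamma(length(p), shape = p * spec$replicate_concentration)
            p <- if (sum(a) > 0) a / sum(a) else p
          }
          n <- as.integer(stats::rmultinom(1L, spec$depth_per_replicate, p))
          data.table::data.table(gene = g$gene_id, offset = g$offset, count = n)
        })
        dt <- data.table::rbindlist(rows)
        dt <- dt[dt$count > 0L]
        dt[, condition := cn]
        dt[, replicate := r]
        dt[, sample := paste0(cn, "_rep", r)]
        out[[paste0(cn, "_", r)]] <- dt
      }
    }
    counts <- data.table::rbindlist(out)
    data.table::setcolorder(counts,
      c("sample", "condition", "replicate", "gene", "offset", "count"))
    counts[]
  })
}
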