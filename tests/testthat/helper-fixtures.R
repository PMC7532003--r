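library(data.table)

# small deterministic simulated dataset shared across tests
small_spec <- function(n_genes = 30, depth = 1000, seed = 42,
                       conditions = c(ref = 0, slow = 1), ...) {
  synthetic_spec(n_genes = n_genes, depth_per_replicate = depth,
                 conditions = conditions, seed = seed, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- small_spec()
      bundle <- build_genome(spec)
      truth <- assign_site_weights(spec, bundle)
      counts <- sample_counts(truth, spec)
      cache <<- list(spec = spec, bundle = bundle, truth = truth,
                     counts = counts)
    }
    cache
  }
})

# endpoint table from a named list gene -> c(offset = count)
toy_counts <- function(gene_list, sample = "s1", condition = "c1",
                       replicate = 1L) {
  data.table::rbindlist(lapply(names(gene_list), function(g) {
    v <- gene_list[[g]]
    data.table::data.table(sample = sample, condition = condition,
                           replicate = replicate, gene = g,
                           offset = as.integer(names(v)),
                           count = as.numeric(v))
  }))
}

# brute-force overlap oracle: fix set A = 1..a, enumerate all B subsets of
# size b, count the fraction sharing at least c positions with A
enumerate_overlap <- function(n, a, b, c_shared) {
  stopifnot(n <= 20)
  subsets <- utils::combn(n, b)
  hits <- colSums(subsets <= a) >= c_shared
  mean(hits)
}
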