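# small in-code fixtures shared across test files

make_counts <- function(m, otu_ids = NULL, sample_ids = NULL) {
  if (is.null(otu_ids)) otu_ids <- paste0("O", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(otu_ids, sample_ids)
  as_otu_table(m)
}

# minimal metadata: one compartment, 4 zones x n sites x n samples
make_metadata <- function(n_sites = 1, n_samples = 1,
                          compartment = "rhizosphere") {
  grid <- expand.grid(zone = zone_levels, site = seq_len(n_sites),
                      rep = seq_len(n_samples), comp = compartment,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste(grid$zone, grid$site, grid$comp, grid$rep, sep = "_"),
    compartment = grid$comp,
    zone = grid$zone,
    site_id = paste0(grid$zone, grid$site)
  )
}

# a lineage tibble from named vectors otu -> lineage string
make_taxonomy <- function(...) {
  x <- c(...)
  parse_lineage(names(x), unname(x))
}

# one default synthetic dataset reused by several files (generated once)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_gradient_community(seed = 7L)
    cache
  }
})

# textbook Pearson correlation + t-test p, written directly from the formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))
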