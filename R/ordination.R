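#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, computed between sample columns.
#' Works on counts or relative abundances; on proportions it is invariant to a
#' common rescaling of counts.
#'
#' @param counts OTU table (no zero-total samples).
#' @return A `dist` object over samples with entries in \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  m <- otu_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Zero-total sample(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS with monotone regression and random restarts; the
#' lowest-stress solution over the restarts is returned. Deterministic for a
#' fixed `seed`.
#'
#' @param d A `dist` object (e.g. from [bray_curtis]).
#' @param k Embedding dimension (default 2; must be < number of samples).
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed.
#' @return Object of class `nmds_ord` with elements `points` (tibble
#'   `sample_id`, `NMDS1`, ...), `stress`, `converged`, `k`, `n_restarts`,
#'   `seed`. See [tidy.nmds_ord()], [glance.nmds_ord()], [autoplot.nmds_ord()].
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (k >= n) abort("nmds: k must be smaller than the number of samples.")
  fit <- withr::with_seed(seed, suppressWarnings(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   trace = 0, autotransform = FALSE, wascores = FALSE)
  ))
  if (!isTRUE(fit$converged)) {
    warn("nmds: no convergent solution within the restart cap; returning best so far.")
  }
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(ncol(pts)))
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(
    list(points = bind_cols(tibble(sample_id = ids),
                            as_tibble(pts, .name_repair = "minimal")),
         stress = fit$stress, converged = isTRUE(fit$converged),
         k = k, n_restarts = n_restarts, seed = seed, engine = fit),
    class = "nmds_ord"
  )
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat("NMDS ordination: k =", x$k, ", stress =", signif(x$stress, 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

# within-group sum of squared distances for a label vector
permanova_ss_within <- function(D2, g) {
  ss <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    ss <- ss + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix: pseudo-F from among/within sums of
#' squared distances, with a permutation p-value
#' `p = (#{F* >= F} + 1) / (n_permutations + 1)` under free shuffling of
#' sample labels. `exact = TRUE` enumerates every label permutation (feasible
#' for small n) and reports the exact proportion `#{F* >= F} / n!`.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations Number of random permutations (default 5000).
#' @param seed Integer seed for the permutation draw.
#' @param exact Enumerate all permutations instead of sampling (n <= 9).
#' @return Object of class `permanova_test` with `pseudo_F`, `p_value`,
#'   `df_among`, `df_within`, `n_permutations`, `exact`.
#' @export
permanova <- function(d, groups, n_permutations = 5000, seed = 1L,
                      exact = FALSE) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  g <- as.character(groups)
  if (length(g) != n) abort("groups must have one label per sample.")
  sizes <- table(g)
  if (length(sizes) < 2) abort("permanova needs >= 2 groups.")
  if (any(sizes < 2)) {
    abort(paste0("Group(s) with < 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  D2 <- as.matrix(d)^2
  a <- length(sizes)
  ss_total <- sum(D2) / (2 * n)
  f_of <- function(lab) {
    ssw <- permanova_ss_within(D2, lab)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(g)
  if (exact) {
    if (n > 9) abort("exact enumeration is limited to n <= 9 samples.")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1L, function(ix) f_of(g[ix]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_permutations <- nrow(perms)
  } else {
    f_perm <- withr::with_seed(seed, vapply(
      seq_len(n_permutations),
      function(i) f_of(sample(g)), numeric(1)))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_permutations + 1)
  }
  structure(
    list(pseudo_F = f_obs, p_value = p, df_among = a - 1, df_within = n - a,
         n_permutations = n_permutations, exact = exact,
         method = "one-way PERMANOVA"),
    class = "permanova_test"
  )
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for n <= 9
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' @export
print.permanova_test <- function(x, ...) {
  cat(x$method, ": pseudo-F =", signif(x$pseudo_F, 5),
      ", p =", signif(x$p_value, 4),
      sprintf("(%s%d permutations)\n", if (x$exact) "all " else "",
              x$n_permutations))
  invisible(x)
}
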