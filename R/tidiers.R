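#' Tidy an ANOVA result
#'
#' @param x An `anova_test` from [anova_oneway].
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `df_residual`, `p_value`.
#' @export
tidy.anova_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df[1], df_residual = x$df[2],
         p_value = x$p_value)
}

#' @rdname tidy.anova_test
#' @export
glance.anova_test <- function(x, ...) tidy.anova_test(x)

#' Tidy Tukey HSD pairwise comparisons
#'
#' @param x A `tukey_test` from [tukey_hsd].
#' @param ... Unused.
#' @return Tibble of pairwise contrasts with adjusted p-values.
#' @export
tidy.tukey_test <- function(x, ...) x$pairwise

#' @rdname tidy.tukey_test
#' @export
glance.tukey_test <- function(x, ...) {
  tibble(n_groups = length(x$groups),
         n_contrasts = nrow(x$pairwise),
         min_adj_p_value = suppressWarnings(min(x$pairwise$adj_p_value)))
}

#' Tidy an NMDS ordination
#'
#' @param x An `nmds_ord` from [nmds].
#' @param ... Unused.
#' @return Tibble of sample coordinates (`sample_id`, `NMDS1`, ...).
#' @export
tidy.nmds_ord <- function(x, ...) x$points

#' @rdname tidy.nmds_ord
#' @export
glance.nmds_ord <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, converged = x$converged,
         n_restarts = x$n_restarts)
}

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova_test` from [permanova].
#' @param ... Unused.
#' @return One-row tibble with the pseudo-F, p-value and permutation count.
#' @export
tidy.permanova_test <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, df_among = x$df_among,
         df_within = x$df_within, p_value = x$p_value,
         n_permutations = x$n_permutations, exact = x$exact)
}

#' @rdname tidy.permanova_test
#' @export
glance.permanova_test <- function(x, ...) tidy.permanova_test(x)

#' Tidy a co-occurrence network
#'
#' @param x A `co_network` from [build_network].
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `method`, `r`, `p`, `q`, `sign`).
#' @export
tidy.co_network <- function(x, ...) x$edges

#' Network-level summary
#'
#' @param x A `co_network`.
#' @param ... Unused.
#' @return One-row tibble: node/edge counts and the positive-edge fraction.
#' @export
glance.co_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_otu_nodes = sum(x$nodes$class != "soil_parameter"),
         n_edges = nrow(x$edges),
         prop_positive = if (nrow(x$edges)) mean(x$edges$sign == "+") else NA_real_)
}
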