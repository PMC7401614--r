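#' Rarefy an OTU table to even depth
#'
#' Samples whose total count falls below `depth` are dropped (reported via a
#' message); the remaining samples are subsampled without replacement to
#' exactly `depth` reads. Reproducible for a fixed `seed`.
#'
#' @param counts OTU table of integer counts.
#' @param depth Target reads per sample (default 1000).
#' @param seed Integer seed for the subsampling draw.
#' @param quiet Suppress the dropped-sample message.
#' @return Rarefied OTU table; every retained sample sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 1000, seed = 1L, quiet = FALSE) {
  stopifnot(depth >= 1)
  counts <- validate_otu_table(counts)
  m <- otu_matrix(counts)
  totals <- colSums(m)
  keep <- totals >= depth
  if (!any(keep)) abort(paste0("All samples have fewer than ", depth, " reads."))
  if (!quiet && any(!keep)) {
    inform(paste0("rarefy_counts: dropped ", sum(!keep),
                  " sample(s) below depth ", depth, ": ",
                  paste(colnames(m)[!keep], collapse = ", ")))
  }
  m <- m[, keep, drop = FALSE]
  # vegan::rrarefy warns when every count exceeds the target depth; harmless
  rar <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(t(m), depth)))
  as_otu_table(t(rar))
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (base-2 by default, i.e. bits), the Simpson diversity index
#' `1 - sum(p^2)` (optionally the dominance form `sum(p^2)`), and observed OTU
#' richness. Intended to be run on a rarefied table so samples are comparable.
#'
#' @param counts OTU table (counts or proportions; each sample must have a
#'   positive total).
#' @param shannon_base Logarithm base for Shannon (2 or `exp(1)`).
#' @param simpson `"diversity"` for `1 - sum(p^2)` (default) or `"dominance"`
#'   for `sum(p^2)`.
#' @return Tibble with columns `sample_id`, `observed_otus`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(counts, shannon_base = 2,
                            simpson = c("diversity", "dominance")) {
  simpson <- match.arg(simpson)
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  m <- otu_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Zero-total sample(s): ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  x <- t(m)  # vegan convention: samples in rows
  sh <- vegan::diversity(x, index = "shannon", base = shannon_base)
  si <- vegan::diversity(x, index = "simpson")   # 1 - sum p^2
  if (simpson == "dominance") si <- 1 - si
  tibble(
    sample_id = colnames(m),
    observed_otus = unname(colSums(m > 0)),
    shannon = unname(sh),
    simpson = unname(si)
  )
}

#' One-way ANOVA on a per-sample metric
#'
#' Classical one-way fixed-effects F test. The degenerate case where every
#' value is identical is reported as F = 0, p = 1.
#'
#' @param data Data frame of per-sample values.
#' @param value,group Columns (tidy-eval) holding the metric and group labels.
#' @return An object of class `anova_test`; see [tidy.anova_test()] and
#'   [glance.anova_test()].
#' @export
anova_oneway <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) abort("anova_oneway needs at least 2 groups.")
  if (!any(table(g) >= 2)) abort("At least one group needs >= 2 values.")
  if (var(v) == 0) {  # identical values: no variance to partition
    return(structure(
      list(statistic = 0, p_value = 1,
           df = c(nlevels(droplevels(g)) - 1L,
                  length(v) - nlevels(droplevels(g))),
           groups = levels(droplevels(g)), method = "one-way ANOVA"),
      class = "anova_test"))
  }
  fit <- aov(v ~ g)
  an <- anova(fit)
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  if (!is.finite(f)) {  # zero residual and zero between variance
    if (isTRUE(all.equal(var(v), 0)) || an$`Sum Sq`[1] < 1e-12) {
      f <- 0; p <- 1
    }
  }
  structure(
    list(statistic = f, p_value = p,
         df = unname(an$Df), groups = levels(droplevels(g)),
         method = "one-way ANOVA"),
    class = "anova_test"
  )
}

#' Tukey HSD pairwise comparisons
#'
#' Pairwise adjusted p-values from the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes). Groups with fewer than two values
#' are excluded with a warning; fewer than two eligible groups is an error.
#' When all values are identical constants every pairwise p is 1.
#'
#' @inheritParams anova_oneway
#' @return An object of class `tukey_test` with a tibble of pairwise
#'   contrasts; see [tidy.tukey_test()].
#' @export
tukey_hsd <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("tukey_hsd: excluding group(s) with < 2 values: ",
                paste(small, collapse = ", ")))
    keep <- !(as.character(g) %in% small)
    v <- v[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) abort("tukey_hsd needs >= 2 groups with >= 2 values each.")
  if (var(v) == 0) {  # identical constants: every contrast is exactly null
    cmb <- utils::combn(levels(g), 2)
    pr <- tibble(contrast = paste(cmb[2, ], cmb[1, ], sep = "-"),
                 estimate = 0, conf_low = 0, conf_high = 0, adj_p_value = 1)
    return(structure(list(pairwise = pr, groups = levels(g),
                          method = "Tukey HSD"),
                     class = "tukey_test"))
  }
  fit <- aov(v ~ g)
  tk <- TukeyHSD(fit)$g
  pr <- tibble(
    contrast = rownames(tk),
    estimate = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]),
    adj_p_value = unname(tk[, "p adj"])
  )
  structure(
    list(pairwise = pr, groups = levels(g), method = "Tukey HSD"),
    class = "tukey_test"
  )
}

#' Dominant OTUs by pooled relative abundance
#'
#' An OTU is dominant when its pooled proportion over the chosen samples
#' (total reads of the OTU / total reads of those samples) strictly exceeds
#' `threshold` — the conventional "> 1\% of all sequences" cut.
#'
#' @param counts OTU table (counts or proportions).
#' @param samples Character vector of sample columns to pool; `NULL` = all.
#' @param threshold Strict lower bound on pooled proportion (default 0.01).
#' @return Tibble `otu_id`, `pooled_abundance`, sorted descending.
#' @export
dominant_otus <- function(counts, samples = NULL, threshold = 0.01) {
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  all_samp <- setdiff(names(counts), "otu_id")
  if (is.null(samples)) samples <- all_samp
  miss <- setdiff(samples, all_samp)
  if (length(miss)) abort(paste0("Unknown sample(s): ", paste(miss, collapse = ", ")))
  if (length(samples) == 0L) abort("Empty sample subset.")
  m <- otu_matrix(counts)[, samples, drop = FALSE]
  pooled <- rowSums(m) / sum(m)
  tibble(otu_id = rownames(m), pooled_abundance = unname(pooled)) |>
    filter(.data$pooled_abundance > threshold) |>
    arrange(desc(.data$pooled_abundance))
}

#' Zone-membership (Venn) partition of OTUs
#'
#' Within one compartment, an OTU is present in a zone when it has a positive
#' count in at least one sample of that zone (computed on filtered,
#' pre-rarefaction counts). The core set is the intersection across all zones;
#' zone-specific OTUs occur in exactly one zone.
#'
#' @param counts OTU table.
#' @param metadata Sample metadata (see [validate_sample_metadata]).
#' @param compartment `"rhizosphere"` or `"endosphere"`.
#' @return Tibble of class `venn_partition`: `otu_id`, one logical column per
#'   zone, `pattern` (e.g. `"1011"` ordered by zone rank), `n_zones`,
#'   `category` (`"core"`, a zone name for zone-specific OTUs, `"partial"`
#'   otherwise). OTUs absent from every sample of the compartment are omitted.
#' @export
venn_partition <- function(counts, metadata,
                           compartment = c("rhizosphere", "endosphere")) {
  compartment <- match.arg(compartment)
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  md <- validate_sample_metadata(metadata)
  md <- filter(md, .data$compartment == !!compartment,
               .data$sample_id %in% setdiff(names(counts), "otu_id"))
  zones <- intersect(zone_levels, unique(md$zone))
  if (length(zones) < 2) {
    abort("venn_partition needs >= 2 zones present in the compartment.")
  }
  m <- otu_matrix(counts)
  pres <- vapply(zones, function(z) {
    s <- md$sample_id[md$zone == z]
    rowSums(m[, s, drop = FALSE] > 0) > 0
  }, logical(nrow(m)))
  observed <- rowSums(pres) > 0
  pres <- pres[observed, , drop = FALSE]
  nz <- rowSums(pres)
  category <- unname(ifelse(nz == length(zones), "core",
                            ifelse(nz == 1L,
                                   zones[apply(pres, 1L, which.max)],
                                   "partial")))
  out <- bind_cols(
    tibble(otu_id = rownames(pres)),
    as_tibble(pres),
    tibble(pattern = apply(pres, 1L, function(x) paste0(as.integer(x), collapse = "")),
           n_zones = as.integer(nz),
           category = category)
  )
  class(out) <- c("venn_partition", class(out))
  attr(out, "zones") <- zones
  attr(out, "compartment") <- compartment
  out
}
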