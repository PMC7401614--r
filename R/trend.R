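#' Zone-level mean abundance profiles
#'
#' For each OTU, the arithmetic mean of its per-sample proportions within each
#' bioclimatic zone of one compartment, ordered by aridity rank.
#'
#' @param rel Relative abundance table.
#' @param metadata Sample metadata.
#' @param compartment `"rhizosphere"` or `"endosphere"`.
#' @return Tibble `otu_id` plus one column per zone (`humid`, `semi_arid`,
#'   `upper_arid`, `lower_arid`).
#' @export
zone_profiles <- function(rel, metadata,
                          compartment = c("rhizosphere", "endosphere")) {
  compartment <- match.arg(compartment)
  rel <- validate_otu_table(rel, integer_counts = FALSE)
  md <- validate_sample_metadata(metadata)
  md <- filter(md, .data$compartment == !!compartment,
               .data$sample_id %in% setdiff(names(rel), "otu_id"))
  missing_zones <- setdiff(zone_levels, unique(md$zone))
  if (length(missing_zones)) {
    abort(paste0("Zone(s) absent from compartment '", compartment, "': ",
                 paste(missing_zones, collapse = ", ")))
  }
  m <- otu_matrix(rel)
  prof <- vapply(zone_levels, function(z) {
    s <- md$sample_id[md$zone == z]
    rowMeans(m[, s, drop = FALSE])
  }, numeric(nrow(m)))
  bind_cols(tibble(otu_id = rownames(m)), as_tibble(prof))
}

# correlation that maps a zero-variance profile to 0 rather than NA
trend_cor <- function(x, y, method) {
  if (sd(y) == 0 || sd(x) == 0) return(0)
  suppressWarnings(cor(x, y, method = method))
}

#' Classify OTU trends along the aridity gradient
#'
#' Each sufficiently abundant OTU is labelled `increased`, `decreased` or
#' `neutral` by correlating its abundance profile with the zone aridity rank
#' (0 = humid ... 3 = lower-arid): `r > r_threshold` is increased,
#' `r < -r_threshold` decreased (strict inequalities), anything else neutral.
#' OTUs whose pooled compartment abundance is at or below
#' `min_pooled_abundance` are labelled `excluded_low_abundance`.
#'
#' The correlation can be computed across site-mean profiles (default, one
#' point per site), across the four zone means, or across raw per-sample
#' proportions. With only four zone-level points the null distribution of
#' Pearson's r is uniform on \[-1, 1\], so |r| > 0.9 fires on 10\% of pure
#' noise profiles; site-level profiles avoid that degeneracy while still
#' averaging out most count noise (see the package vignette).
#'
#' Zone means relative to the humid zone are reported alongside (`ratio_*`
#' columns); when the humid mean is zero a pseudo-abundance of half the
#' smallest nonzero proportion in the compartment is used for the ratio only.
#'
#' @param rel Relative abundance table.
#' @param metadata Sample metadata.
#' @param compartment `"rhizosphere"` or `"endosphere"`.
#' @param r_threshold Strict correlation threshold (default 0.9).
#' @param min_pooled_abundance Eligibility cut on pooled compartment
#'   abundance (default 0.001, i.e. 0.1\% of sequences).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param level Profile granularity: `"site"` (default), `"zone"`, `"sample"`.
#' @return Tibble of class `trend_classification`: `otu_id`, `compartment`,
#'   `label`, `r`, `pooled_abundance`, zone-mean columns (`mean_humid`, ...)
#'   and humid-reference ratios (`ratio_semi_arid`, ...).
#' @export
classify_trends <- function(rel, metadata,
                            compartment = c("rhizosphere", "endosphere"),
                            r_threshold = 0.9, min_pooled_abundance = 0.001,
                            method = c("pearson", "spearman"),
                            level = c("site", "zone", "sample")) {
  compartment <- match.arg(compartment)
  method <- match.arg(method)
  level <- match.arg(level)
  stopifnot(r_threshold > 0, r_threshold <= 1)
  rel <- validate_otu_table(rel, integer_counts = FALSE)
  md <- validate_sample_metadata(metadata)
  md <- filter(md, .data$compartment == !!compartment,
               .data$sample_id %in% setdiff(names(rel), "otu_id"))
  prof <- zone_profiles(rel, metadata, compartment)  # also checks all 4 zones
  m <- otu_matrix(rel)[, md$sample_id, drop = FALSE]
  pooled <- rowMeans(m)

  if (level == "zone") {
    x <- 0:3
    y_mat <- as.matrix(prof[, zone_levels])
  } else if (level == "site") {
    sites <- distinct(md, .data$site_id, .data$zone_rank)
    y_mat <- vapply(sites$site_id, function(sid) {
      s <- md$sample_id[md$site_id == sid]
      rowMeans(m[, s, drop = FALSE])
    }, numeric(nrow(m)))
    x <- sites$zone_rank
  } else {
    x <- md$zone_rank
    y_mat <- m
  }
  r <- vapply(seq_len(nrow(m)), function(i) trend_cor(x, y_mat[i, ], method),
              numeric(1))

  label <- dplyr::case_when(
    pooled <= min_pooled_abundance ~ "excluded_low_abundance",
    r > r_threshold ~ "increased",
    r < -r_threshold ~ "decreased",
    TRUE ~ "neutral"
  )

  zm <- as.matrix(prof[, zone_levels])
  nonzero <- m[m > 0]
  eps <- if (length(nonzero)) min(nonzero) / 2 else .Machine$double.eps
  humid_ref <- ifelse(zm[, "humid"] > 0, zm[, "humid"], eps)
  ratios <- zm / humid_ref

  out <- bind_cols(
    tibble(otu_id = rownames(m), compartment = compartment,
           label = label, r = r, pooled_abundance = unname(pooled)),
    as_tibble(zm) |> rlang::set_names(paste0("mean_", zone_levels)),
    as_tibble(ratios) |> rlang::set_names(paste0("ratio_", zone_levels))
  )
  class(out) <- c("trend_classification", class(out))
  attr(out, "params") <- list(r_threshold = r_threshold,
                              min_pooled_abundance = min_pooled_abundance,
                              method = method, level = level)
  out
}

#' OTUs sharing a trend across compartments
#'
#' @param rhizo,endo `trend_classification` tibbles for the two compartments.
#' @param label Trend to intersect: `"increased"` (default) or `"decreased"`.
#' @return Sorted character vector of OTU ids carrying `label` in both.
#' @export
shared_trend_otus <- function(rhizo, endo, label = c("increased", "decreased")) {
  label <- match.arg(label)
  sort(intersect(rhizo$otu_id[rhizo$label == label],
                 endo$otu_id[endo$label == label]))
}
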