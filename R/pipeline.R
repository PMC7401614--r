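#' Pipeline configuration
#'
#' Collects the inputs and every tunable threshold of the full analysis. The
#' defaults are the study settings: rarefaction to 1000 reads, dominance above
#' 1\%, trend eligibility above 0.1\% with |r| > 0.9, network edges at
#' |r| >= 0.9 with BH-adjusted q <= 0.05, 5000 permutations.
#'
#' @param counts,metadata,taxonomy,soil Inputs: each either an in-memory
#'   tibble or a TSV/BIOM path.
#' @param out_dir Output directory for [run_pipeline].
#' @param rarefaction_depth Reads per sample for alpha diversity.
#' @param dominance_threshold Strict pooled-abundance cut for dominant OTUs.
#' @param trend_r_threshold,trend_min_abundance,trend_method,trend_level
#'   Passed to [classify_trends].
#' @param network_r_min,network_alpha,network_p_mode,network_combine Passed to
#'   [build_network].
#' @param hub_min_degree,hub_top_k Passed to [rank_hubs].
#' @param n_permutations PERMANOVA permutations.
#' @param nmds_restarts NMDS random restarts.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata, taxonomy, soil = NULL,
                            out_dir = tempfile("aridnet_run_"),
                            rarefaction_depth = 1000,
                            dominance_threshold = 0.01,
                            trend_r_threshold = 0.9,
                            trend_min_abundance = 0.001,
                            trend_method = "pearson",
                            trend_level = "site",
                            network_r_min = 0.9, network_alpha = 0.05,
                            network_p_mode = "bh", network_combine = "or",
                            hub_min_degree = 56, hub_top_k = 22,
                            n_permutations = 5000, nmds_restarts = 20,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_input <- function(x, reader, what) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(paste0("Missing ", what, " input: ", x))
    return(reader(x))
  }
  abort(paste0("Input '", what, "' must be a data frame or a file path."))
}

# config echo for the manifest: inputs replaced by a shape/path summary
config_echo <- function(cfg, shapes) {
  c(shapes,
    cfg[setdiff(names(cfg), c("counts", "metadata", "taxonomy", "soil",
                              "out_dir"))])
}

#' Run the full aridity-gradient analysis
#'
#' Executes organelle filtering, relative abundance, phylum-level
#' aggregation, rarefaction, alpha diversity with group tests, Bray-Curtis /
#' NMDS / PERMANOVA, zone Venn partitioning, dominant-OTU selection, trend
#' classification, co-occurrence network construction, subnetwork splitting,
#' hub ranking and Cytoscape exports, writing fixed-name TSV/GraphML/SIF
#' artifacts plus a `manifest.json` under `cfg$out_dir`. Runs are
#' deterministic for a fixed config and seed.
#'
#' @param cfg A [pipeline_config].
#' @return The manifest (named list: files written, config echo, seed record,
#'   stage log of dropped-item counts and headline statistics), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  counts <- load_input(cfg$counts, read_otu_table, "otu")
  metadata <- load_input(cfg$metadata, read_sample_metadata, "metadata")
  taxonomy <- load_input(cfg$taxonomy, read_taxonomy, "taxonomy")
  soil <- load_input(cfg$soil, read_soil_profiles, "soil")
  if (is.null(counts) || is.null(metadata) || is.null(taxonomy)) {
    abort("run_pipeline needs counts, metadata and taxonomy inputs.")
  }
  counts <- validate_otu_table(counts)
  metadata <- validate_sample_metadata(metadata)
  if (!all(setdiff(names(counts), "otu_id") %in% metadata$sample_id)) {
    abort("Sample ids in the OTU table are missing from the metadata.")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log <- list()

  filtered <- filter_organelles(counts, taxonomy, quiet = TRUE)
  log$organelle_otus_removed <- nrow(counts) - nrow(filtered)
  rel <- relative_abundance(filtered)

  phylum <- aggregate_taxa(rel, taxonomy, level = "phylum",
                           split_proteobacteria = TRUE)
  readr::write_tsv(phylum, out("phylum.tsv"), progress = FALSE)

  rar <- suppressMessages(
    rarefy_counts(filtered, depth = cfg$rarefaction_depth,
                  seed = cfg$seed + 101L, quiet = TRUE))
  log$samples_below_depth <-
    length(setdiff(names(filtered), names(rar)))
  alpha <- alpha_diversity(rar) |>
    left_join(metadata, by = "sample_id")
  readr::write_tsv(alpha, out("alpha.tsv"), progress = FALSE)

  gt <- list(); tk <- list()
  for (metric in c("shannon", "simpson", "observed_otus")) {
    a <- anova_oneway(alpha, metric, "compartment")
    gt[[length(gt) + 1L]] <- tibble(metric = metric, factor = "compartment",
                                    compartment = "both",
                                    statistic = a$statistic,
                                    p_value = a$p_value)
    for (comp in intersect(compartment_levels, unique(alpha$compartment))) {
      sub <- filter(alpha, .data$compartment == comp)
      if (length(unique(sub$zone)) < 2) next
      a <- anova_oneway(sub, metric, "zone")
      gt[[length(gt) + 1L]] <- tibble(metric = metric, factor = "zone",
                                      compartment = comp,
                                      statistic = a$statistic,
                                      p_value = a$p_value)
      t <- tryCatch(
        suppressWarnings(tukey_hsd(sub, metric, "zone")),
        error = function(e) NULL)
      if (!is.null(t)) {
        tk[[length(tk) + 1L]] <- mutate(t$pairwise, metric = metric,
                                        compartment = comp)
      }
    }
  }
  readr::write_tsv(bind_rows(gt), out("group_tests.tsv"), progress = FALSE)
  readr::write_tsv(bind_rows(tk), out("tukey.tsv"), progress = FALSE)

  d <- bray_curtis(rel)
  dm <- as.matrix(d)
  readr::write_tsv(bind_cols(tibble(sample_id = rownames(dm)), as_tibble(dm)),
                   out("bray_curtis.tsv"), progress = FALSE)
  ord <- nmds(d, k = 2, n_restarts = cfg$nmds_restarts, seed = cfg$seed + 202L)
  readr::write_tsv(left_join(ord$points, metadata, by = "sample_id"),
                   out("nmds.tsv"), progress = FALSE)

  md_d <- metadata[match(rownames(dm), metadata$sample_id), ]
  pm <- list(permanova_row(d, md_d$compartment, "compartment", "both", cfg))
  for (comp in intersect(compartment_levels, unique(md_d$compartment))) {
    idx <- which(md_d$compartment == comp)
    if (length(unique(md_d$zone[idx])) < 2) next
    dsub <- stats::as.dist(dm[idx, idx])
    pm[[length(pm) + 1L]] <- permanova_row(dsub, md_d$zone[idx], "zone", comp, cfg)
  }
  pm <- bind_rows(pm)
  readr::write_tsv(pm, out("permanova.tsv"), progress = FALSE)

  venns <- list(); doms <- list(); trends <- list()
  for (comp in intersect(compartment_levels, unique(metadata$compartment))) {
    vp <- venn_partition(filtered, metadata, comp)
    venns[[comp]] <- mutate(as_tibble(vp), compartment = comp)
    cs <- metadata$sample_id[metadata$compartment == comp]
    doms[[comp]] <- dominant_otus(filtered, intersect(cs, names(filtered)),
                                  cfg$dominance_threshold) |>
      mutate(compartment = comp)
    trends[[comp]] <- classify_trends(
      rel, metadata, comp, r_threshold = cfg$trend_r_threshold,
      min_pooled_abundance = cfg$trend_min_abundance,
      method = cfg$trend_method, level = cfg$trend_level)
  }
  readr::write_tsv(bind_rows(venns), out("venn.tsv"), progress = FALSE)
  readr::write_tsv(bind_rows(doms), out("dominant.tsv"), progress = FALSE)
  readr::write_tsv(bind_rows(trends), out("trends.tsv"), progress = FALSE)

  features <- build_feature_vectors(rel, metadata, trends, soil)
  cors <- correlate_pairs(features, quiet = TRUE)
  net <- build_network(cors, features, r_min = cfg$network_r_min,
                       alpha = cfg$network_alpha, p_mode = cfg$network_p_mode,
                       combine = cfg$network_combine)
  readr::write_tsv(net$edges, out("edges.tsv"), progress = FALSE)
  write_network_sif(net, out("network.sif"), out("nodes.tsv"))
  write_network_graphml(net, out("network.graphml"))
  hubs <- rank_hubs(net, cfg$hub_min_degree, cfg$hub_top_k)
  readr::write_tsv(hubs, out("hubs.tsv"), progress = FALSE)
  sub <- split_subnetworks(net)

  log$excluded_low_abundance_otus <-
    sum(bind_rows(trends)$label == "excluded_low_abundance")
  log$trend_increased <- sum(bind_rows(trends)$label == "increased")
  log$trend_decreased <- sum(bind_rows(trends)$label == "decreased")
  log$network_nodes <- nrow(net$nodes)
  log$network_edges <- nrow(net$edges)
  log$between_class_edges <- nrow(sub$between_edges)
  log$hubs <- nrow(hubs)
  log$nmds_stress <- ord$stress

  files <- c("phylum.tsv", "alpha.tsv", "group_tests.tsv", "tukey.tsv",
             "bray_curtis.tsv", "nmds.tsv", "permanova.tsv", "venn.tsv",
             "dominant.tsv", "trends.tsv", "edges.tsv", "nodes.tsv",
             "network.sif", "network.graphml", "hubs.tsv")
  shapes <- list(
    input_otus = nrow(counts),
    input_samples = length(setdiff(names(counts), "otu_id")),
    soil_sites = if (is.null(soil)) 0L else nrow(soil))
  manifest <- list(files = files,
                   config = config_echo(cfg, shapes),
                   seed = cfg$seed,
                   log = log)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

permanova_row <- function(d, groups, factor, compartment, cfg) {
  pt <- permanova(d, groups, n_permutations = cfg$n_permutations,
                  seed = cfg$seed + 303L)
  tibble(factor = factor, compartment = compartment,
         pseudo_F = pt$pseudo_F, p_value = pt$p_value,
         n_permutations = pt$n_permutations)
}
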