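feature_classes <- c("rhizo_increased", "rhizo_decreased",
                     "endo_increased", "endo_decreased", "soil_parameter")

compartment_prefix <- c(rhizosphere = "rhizo", endosphere = "endo")

#' Assemble site-aligned feature vectors for network inference
#'
#' Features are (i) OTUs labelled increased or decreased in either compartment
#' — their per-site value is the mean proportion across that site's samples in
#' the relevant compartment — and (ii) the soil parameters, one value per
#' site. All vectors share the site axis; sites lacking a value carry `NA`
#' and are dropped pairwise during correlation.
#'
#' @param rel Relative abundance table.
#' @param metadata Sample metadata.
#' @param trends A `trend_classification` tibble or a list of them (typically
#'   one per compartment).
#' @param soil Soil profile tibble (`site_id` + the nine soil variables), or
#'   `NULL` to build an OTU-only feature set.
#' @return Object of class `feature_vectors`: tibble `feature_id`, `class`,
#'   `otu_id`, `compartment`, then one numeric column per site.
#' @export
build_feature_vectors <- function(rel, metadata, trends, soil = NULL) {
  rel <- validate_otu_table(rel, integer_counts = FALSE)
  md <- validate_sample_metadata(metadata)
  if (inherits(trends, "trend_classification")) trends <- list(trends)
  trends <- bind_rows(trends)
  keep <- filter(trends, .data$label %in% c("increased", "decreased"))
  m <- otu_matrix(rel)
  sites <- sort(unique(md$site_id))

  rows <- purrr::pmap(
    list(keep$otu_id, keep$compartment, keep$label),
    function(otu, comp, lab) {
      cmd <- md[md$compartment == comp & md$sample_id %in% colnames(m), ]
      vals <- vapply(sites, function(sid) {
        s <- cmd$sample_id[cmd$site_id == sid]
        if (length(s) == 0L) return(NA_real_)
        mean(m[otu, s])
      }, numeric(1))
      c(list(feature_id = paste0(compartment_prefix[[comp]], ":", otu),
             class = paste0(compartment_prefix[[comp]], "_", lab),
             otu_id = otu, compartment = comp),
        as.list(vals))
    })
  otu_part <- bind_rows(rows)

  soil_part <- NULL
  if (!is.null(soil)) {
    soil <- validate_soil_profiles(soil)
    soil_rows <- purrr::map(soil_variables, function(v) {
      vals <- soil[[v]][match(sites, soil$site_id)]
      c(list(feature_id = paste0("soil:", v), class = "soil_parameter",
             otu_id = NA_character_, compartment = NA_character_),
        setNames(as.list(vals), sites))
    })
    soil_part <- bind_rows(soil_rows)
  }
  out <- bind_rows(otu_part, soil_part)
  if (nrow(out) == 0L) {
    out <- tibble(feature_id = character(), class = character(),
                  otu_id = character(), compartment = character())
  }
  class(out) <- c("feature_vectors", class(out))
  attr(out, "sites") <- sites
  out
}

#' All-pairs correlations among features
#'
#' Every unordered feature pair is tested with each requested method;
#' p-values come from the classical correlation null (`stats::cor.test`).
#' Pairs with fewer than three complete site observations, and pairs
#' involving a zero-variance vector, are skipped with a message.
#'
#' @param features A `feature_vectors` object.
#' @param methods Correlation methods (default both Pearson and Spearman).
#' @param quiet Suppress the skipped-pair message.
#' @return Tibble of class `pair_correlations`: `feature1`, `feature2`,
#'   `method`, `n`, `r`, `p`; carries the feature table as an attribute.
#' @export
correlate_pairs <- function(features, methods = c("pearson", "spearman"),
                            quiet = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  site_cols <- attr(features, "sites")
  if (is.null(site_cols)) site_cols <- setdiff(
    names(features), c("feature_id", "class", "otu_id", "compartment"))
  x <- as.matrix(features[, site_cols, drop = FALSE])
  rownames(x) <- features$feature_id
  nf <- nrow(x)
  res <- list(); skipped <- 0L
  if (nf >= 2) {
    for (i in seq_len(nf - 1L)) for (j in seq.int(i + 1L, nf)) {
      ok <- stats::complete.cases(cbind(x[i, ], x[j, ]))
      if (sum(ok) < 3 || sd(x[i, ok]) == 0 || sd(x[j, ok]) == 0) {
        skipped <- skipped + 1L
        next
      }
      for (meth in methods) {
        ct <- suppressWarnings(
          cor.test(x[i, ok], x[j, ok], method = meth, exact = FALSE))
        res[[length(res) + 1L]] <- tibble(
          feature1 = rownames(x)[i], feature2 = rownames(x)[j],
          method = meth, n = sum(ok),
          r = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  if (!quiet && skipped > 0L) {
    inform(paste0("correlate_pairs: skipped ", skipped,
                  " pair(s) with < 3 aligned sites or zero variance."))
  }
  out <- if (length(res)) bind_rows(res) else
    tibble(feature1 = character(), feature2 = character(),
           method = character(), n = integer(), r = double(), p = double())
  class(out) <- c("pair_correlations", class(out))
  attr(out, "features") <- features
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q[i] = min over j with p[j] >= p[i] of m * p[j] / rank(p[j])`, returned in
#' input order. A thin, input-validating wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric.")
  if (length(p) && (min(p, na.rm = TRUE) < 0 || max(p, na.rm = TRUE) > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Build the thresholded co-occurrence network
#'
#' An edge joins two features when at least one correlation method (OR rule;
#' `combine = "and"` requires every method) reaches `|r| >= r_min` together
#' with its significance criterion: BH-adjusted `q <= alpha` (default) or raw
#' `p <= alpha`. BH adjustment is applied within each method's family of all
#' tested pairs. The qualifying method with the larger `|r|` annotates the
#' edge; the edge sign is the sign of that r (positive = co-presence,
#' negative = mutual exclusion).
#'
#' @param correlations A `pair_correlations` tibble from [correlate_pairs].
#' @param features Feature table for node classes; defaults to the one
#'   attached to `correlations`.
#' @param r_min Inclusive absolute-correlation threshold (default 0.9).
#' @param alpha Significance level (default 0.05).
#' @param p_mode `"bh"` (BH-adjusted, default) or `"raw"`.
#' @param combine `"or"` (default): any method may qualify an edge; `"and"`:
#'   all methods must.
#' @return Object of class `co_network`: list with `nodes` (tibble `id`,
#'   `class`, `otu_id`, `compartment`), `edges` (tibble `from`, `to`,
#'   `method`, `r`, `p`, `q`, `sign`) and `params`.
#' @export
build_network <- function(correlations, features = attr(correlations, "features"),
                          r_min = 0.9, alpha = 0.05,
                          p_mode = c("bh", "raw"), combine = c("or", "and")) {
  p_mode <- match.arg(p_mode)
  combine <- match.arg(combine)
  stopifnot(r_min >= 0, r_min <= 1, alpha > 0, alpha <= 1)
  if (is.null(features)) abort("build_network needs the feature table.")
  cors <- as_tibble(correlations)
  n_methods <- length(unique(cors$method))
  if (nrow(cors)) {
    cors <- cors |>
      group_by(.data$method) |>
      mutate(q = bh_fdr(.data$p)) |>
      ungroup() |>
      mutate(crit = if (p_mode == "bh") .data$q else .data$p,
             qualifies = abs(.data$r) >= r_min & .data$crit <= alpha)
    edges <- cors |>
      group_by(.data$feature1, .data$feature2) |>
      dplyr::group_modify(function(x, key) {
        qual <- x[x$qualifies, , drop = FALSE]
        ok <- if (combine == "or") nrow(qual) >= 1L else
          nrow(qual) == n_methods
        if (!ok) return(qual[0, , drop = FALSE])
        qual[which.max(abs(qual$r)), , drop = FALSE]  # larger |r| annotates
      }) |>
      ungroup() |>
      mutate(sign = ifelse(.data$r >= 0, "+", "-")) |>
      select(from = "feature1", to = "feature2",
             "method", "r", "p", "q", "sign") |>
      arrange(.data$from, .data$to)
  } else {
    edges <- tibble(from = character(), to = character(), method = character(),
                    r = double(), p = double(), q = double(), sign = character())
  }
  nodes <- features |>
    as_tibble() |>
    select("feature_id", "class", "otu_id", "compartment") |>
    rename(id = "feature_id")
  structure(
    list(nodes = nodes, edges = edges,
         params = list(r_min = r_min, alpha = alpha, p_mode = p_mode,
                       combine = combine)),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat("co-occurrence network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges",
      sprintf("(|r| >= %g, %s <= %g)\n", x$params$r_min,
              if (x$params$p_mode == "bh") "q" else "p", x$params$alpha))
  invisible(x)
}

node_class <- function(net, ids) {
  net$nodes$class[match(ids, net$nodes$id)]
}

#' Split a network into increased / decreased subnetworks
#'
#' The increased subnetwork is the subgraph on increased-trend OTU nodes plus
#' every soil parameter with at least one edge to that class, keeping
#' OTU-OTU edges within the class and their OTU-soil edges; symmetrically for
#' decreased. Cross-class OTU edges are returned as the between-subnetwork
#' edge list, and soil-soil edges separately, so the four edge sets partition
#' the full edge set.
#'
#' @param net A `co_network`.
#' @return List with `increased` and `decreased` (`co_network` objects),
#'   `between_edges` (cross-class OTU edges) and `soil_edges` (soil-soil
#'   edges).
#' @export
split_subnetworks <- function(net) {
  stopifnot(inherits(net, "co_network"))
  cls_from <- node_class(net, net$edges$from)
  cls_to <- node_class(net, net$edges$to)
  grp <- function(cls) dplyr::case_when(
    cls %in% c("rhizo_increased", "endo_increased") ~ "inc",
    cls %in% c("rhizo_decreased", "endo_decreased") ~ "dec",
    TRUE ~ "soil")
  gf <- grp(cls_from); gt <- grp(cls_to)
  bucket <- dplyr::case_when(
    gf == "inc" & gt == "inc" ~ "increased",
    gf == "dec" & gt == "dec" ~ "decreased",
    (gf == "inc" & gt == "soil") | (gf == "soil" & gt == "inc") ~ "increased",
    (gf == "dec" & gt == "soil") | (gf == "soil" & gt == "dec") ~ "decreased",
    gf == "soil" & gt == "soil" ~ "soil",
    TRUE ~ "between"
  )
  subnet <- function(side) {
    e <- net$edges[bucket == side, , drop = FALSE]
    otu_cls <- if (side == "increased") {
      c("rhizo_increased", "endo_increased")
    } else c("rhizo_decreased", "endo_decreased")
    soil_ids <- unique(c(e$from, e$to))
    soil_ids <- soil_ids[node_class(net, soil_ids) == "soil_parameter"]
    nodes <- filter(net$nodes, .data$class %in% otu_cls | .data$id %in% soil_ids)
    structure(list(nodes = nodes, edges = e, params = net$params),
              class = "co_network")
  }
  list(increased = subnet("increased"),
       decreased = subnet("decreased"),
       between_edges = net$edges[bucket == "between", , drop = FALSE],
       soil_edges = net$edges[bucket == "soil", , drop = FALSE])
}

#' Node degrees of a network
#'
#' @param net A `co_network`.
#' @return Tibble `id`, `degree` (incident edge count), `class`.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "co_network"))
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$id))
  net$nodes |>
    mutate(degree = as.integer(deg[.data$id])) |>
    select("id", "degree", "class", "otu_id", "compartment")
}

#' Rank hub nodes by connectivity
#'
#' Degrees are counted on the full network. Nodes at or above `min_degree`
#' are ranked by degree (descending; ties broken by id) and truncated to the
#' top `top_k`.
#'
#' @param net A `co_network`.
#' @param min_degree Minimum degree to qualify as a hub (default 56).
#' @param top_k Maximum rows returned (default 22).
#' @param otus_only Restrict to OTU nodes (default `TRUE`, since hubs are
#'   interpreted as keystone taxa).
#' @return Tibble `id`, `degree`, `class`, `otu_id`, `compartment`.
#' @export
rank_hubs <- function(net, min_degree = 56, top_k = 22, otus_only = TRUE) {
  deg <- network_degrees(net)
  if (otus_only) deg <- filter(deg, .data$class != "soil_parameter")
  deg |>
    filter(.data$degree >= min_degree) |>
    arrange(desc(.data$degree), .data$id) |>
    head(top_k)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param net A `co_network`.
#' @return An undirected `igraph` graph with node attribute `class` and edge
#'   attributes `method`, `r`, `p`, `q`, `sign`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  nodes <- as.data.frame(net$nodes)
  nodes$otu_id[is.na(nodes$otu_id)] <- ""
  nodes$compartment[is.na(nodes$compartment)] <- ""
  igraph::graph_from_data_frame(as.data.frame(net$edges),
                                directed = FALSE, vertices = nodes)
}

#' Export a network as SIF plus node attributes
#'
#' Writes a Cytoscape-compatible SIF edge list (`source  pos|neg  target`,
#' tab-separated; isolated nodes appear as bare single-column lines) and,
#' optionally, a node-attribute TSV.
#'
#' @param net A `co_network`.
#' @param path Output SIF path.
#' @param node_attributes_path Optional TSV path for node attributes.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path, node_attributes_path = NULL) {
  stopifnot(inherits(net, "co_network"))
  inter <- ifelse(net$edges$sign == "+", "pos", "neg")
  lines <- paste(net$edges$from, inter, net$edges$to, sep = "\t")
  isolated <- setdiff(net$nodes$id, unique(c(net$edges$from, net$edges$to)))
  writeLines(c(lines, isolated), path)
  if (!is.null(node_attributes_path)) {
    readr::write_tsv(net$nodes, node_attributes_path, progress = FALSE)
  }
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node `class` and edge `method`, `r`, `p`, `q`, `sign` travel as GraphML
#' attributes; [read_network_graphml] round-trips the node and edge sets.
#'
#' @param net A `co_network`.
#' @param path Output GraphML path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back into a `co_network`
#'
#' @param path GraphML path written by [write_network_graphml].
#' @return A `co_network` (edge `from`/`to` ordered lexicographically).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(g)
  nodes <- tibble(
    id = vat$name,
    class = vat$class,
    otu_id = ifelse(vat$otu_id == "", NA_character_, vat$otu_id),
    compartment = ifelse(vat$compartment == "", NA_character_, vat$compartment)
  )
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    eat <- igraph::edge_attr(g)
    edges <- tibble(
      from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
      method = eat$method, r = eat$r, p = eat$p, q = eat$q, sign = eat$sign
    ) |> arrange(.data$from, .data$to)
  } else {
    edges <- tibble(from = character(), to = character(), method = character(),
                    r = double(), p = double(), q = double(), sign = character())
  }
  structure(list(nodes = nodes, edges = edges, params = list()),
            class = "co_network")
}
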