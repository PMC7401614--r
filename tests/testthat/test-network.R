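# hand-made feature table: rows = features, columns = sites
make_features <- function(m, classes = NULL) {
  if (is.null(classes)) classes <- rep("rhizo_increased", nrow(m))
  ids <- rownames(m)
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = ids, class = classes,
                   otu_id = ifelse(classes == "soil_parameter", NA, ids),
                   compartment = ifelse(classes == "soil_parameter", NA,
                                        "rhizosphere")),
    tibble::as_tibble(m))
  class(out) <- c("feature_vectors", class(out))
  attr(out, "sites") <- colnames(m)
  out
}

test_that("feature vectors use trend labels and site means, plus soil", {
  sim <- default_sim()
  rel <- relative_abundance(sim$counts)
  trends <- lapply(c("rhizosphere", "endosphere"), function(cc)
    classify_trends(rel, sim$metadata, cc))
  fv <- build_feature_vectors(rel, sim$metadata, trends, sim$soil)
  n_lab <- sum(sapply(trends, function(t)
    sum(t$label %in% c("increased", "decreased"))))
  expect_equal(nrow(fv), n_lab + 9)   # labelled OTUs + soil parameters
  expect_false(any(grepl("neutral", fv$class)))
  # spot-check one site value = mean over that site's samples
  t1 <- trends[[1]]
  otu <- t1$otu_id[t1$label == "increased"][1]
  site <- sim$metadata$site_id[1]
  samp <- sim$metadata$sample_id[sim$metadata$site_id == site &
                                   sim$metadata$compartment == "rhizosphere"]
  expect_equal(
    fv[[site]][fv$feature_id == paste0("rhizo:", otu)],
    mean(otu_matrix(rel)[otu, samp]))
  # soil joined by site
  expect_equal(fv[[site]][fv$feature_id == "soil:pH"],
               sim$soil$pH[sim$soil$site_id == site])
})

test_that("pairwise correlations match the textbook formulas", {
  set.seed(23)
  x <- rnorm(10)
  m <- rbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(10), e = rnorm(10))
  colnames(m) <- paste0("S", 1:10)
  cors <- correlate_pairs(make_features(m), quiet = TRUE)
  get <- function(f1, f2, meth) cors[cors$feature1 == f1 & cors$feature2 == f2 &
                                       cors$method == meth, ]
  expect_equal(get("a", "b", "pearson")$r, 1)        # affine
  expect_equal(get("a", "c", "pearson")$r, -1)
  expect_lt(get("a", "c", "pearson")$p, 1e-12)
  for (pair in list(c("a", "d"), c("d", "e"))) {
    o <- oracle_pearson(m[pair[1], ], m[pair[2], ])
    row <- get(pair[1], pair[2], "pearson")
    expect_equal(row$r, o$r, tolerance = 1e-10)
    expect_equal(row$p, o$p, tolerance = 1e-10)
    os <- oracle_spearman(m[pair[1], ], m[pair[2], ])
    rs <- get(pair[1], pair[2], "spearman")
    expect_equal(rs$r, os$r, tolerance = 1e-10)
  }
})

test_that("degenerate feature vectors are skipped, not propagated", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  colnames(m) <- paste0("S", 1:4)
  expect_message(cors <- correlate_pairs(make_features(m)), "skipped")
  expect_false("b" %in% c(cors$feature1, cors$feature2))
  # < 3 aligned sites
  m2 <- rbind(a = c(1, 2, NA, NA), b = c(2, 1, 3, 4))
  colnames(m2) <- paste0("S", 1:4)
  cors2 <- correlate_pairs(make_features(m2), quiet = TRUE)
  expect_equal(nrow(cors2), 0)
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1 identity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))        # monotone in sorted order
    # independent step-up: q(i) = min_{j>=i} m p(j)/j in sorted order
    o <- order(p)
    ref <- rev(cummin(rev(50 * p[o] / seq_len(50))))
    expect_equal(q[o], pmin(ref, 1), tolerance = 1e-12)
  }
})

test_that("edges require both the correlation and the significance criterion", {
  mk_cors <- function(r, p) {
    out <- tibble::tibble(feature1 = "a", feature2 = "b",
                          method = "pearson", n = 10, r = r, p = p)
    class(out) <- c("pair_correlations", class(out))
    out
  }
  feats <- make_features(matrix(0, 2, 3,
                                dimnames = list(c("a", "b"), paste0("S", 1:3))))
  expect_equal(nrow(build_network(mk_cors(0.95, 0.01), feats)$edges), 1)
  expect_equal(build_network(mk_cors(0.95, 0.01), feats)$edges$sign, "+")
  expect_equal(nrow(build_network(mk_cors(0.95, 0.2), feats)$edges), 0)
  expect_equal(nrow(build_network(mk_cors(0.5, 0.001), feats)$edges), 0)
  expect_equal(build_network(mk_cors(-0.93, 0.01), feats)$edges$sign, "-")
})

test_that("network equals a brute-force all-pairs filter on small instances", {
  set.seed(37)
  for (rep in 1:3) {
    nf <- sample(10:30, 1)
    m <- matrix(rnorm(nf * 8), nf, 8,
                dimnames = list(paste0("f", seq_len(nf)), paste0("S", 1:8)))
    # plant a correlated block so some edges exist at a modest threshold
    m[1:4, ] <- rep(m[1, ], each = 4) + rnorm(32, 0, 0.1)
    feats <- make_features(m)
    cors <- correlate_pairs(feats, quiet = TRUE)
    r_min <- 0.8; alpha <- 0.1
    for (p_mode in c("bh", "raw")) {
      net <- build_network(cors, feats, r_min = r_min, alpha = alpha,
                           p_mode = p_mode)
      got <- sort(paste(net$edges$from, net$edges$to))
      # straightforward independent filter
      want <- character()
      for (meth in c("pearson", "spearman")) {
        sub <- cors[cors$method == meth, ]
        crit <- if (p_mode == "bh") p.adjust(sub$p, "BH") else sub$p
        hit <- abs(sub$r) >= r_min & crit <= alpha
        want <- union(want, paste(sub$feature1[hit], sub$feature2[hit]))
      }
      expect_identical(got, sort(want))
    }
  }
})

test_that("edge sets shrink as thresholds tighten", {
  set.seed(43)
  m <- matrix(rnorm(15 * 10), 15, 10,
              dimnames = list(paste0("f", 1:15), paste0("S", 1:10)))
  m[1:5, ] <- rep(m[1, ], each = 5) + rnorm(50, 0, 0.3)
  cors <- correlate_pairs(make_features(m), quiet = TRUE)
  key <- function(net) paste(net$edges$from, net$edges$to)
  for (p_mode in c("raw", "bh")) {
    e1 <- key(build_network(cors, r_min = 0.5, alpha = 0.2, p_mode = p_mode))
    e2 <- key(build_network(cors, r_min = 0.7, alpha = 0.2, p_mode = p_mode))
    e3 <- key(build_network(cors, r_min = 0.5, alpha = 0.05, p_mode = p_mode))
    expect_true(all(e2 %in% e1))
    expect_true(all(e3 %in% e1))
  }
  # the AND combination rule is never more permissive than OR
  e_or <- key(build_network(cors, r_min = 0.5, alpha = 0.2, combine = "or"))
  e_and <- key(build_network(cors, r_min = 0.5, alpha = 0.2, combine = "and"))
  expect_true(all(e_and %in% e_or))
})

test_that("subnetwork split partitions edges and duplicates shared soil nodes", {
  # two increased, two decreased OTUs and one soil variable tied to both
  z <- c(1, 2, 4, 8, 16, 32)
  m <- rbind(i1 = z, i2 = z * 2, d1 = rev(z), d2 = rev(z) * 3,
             soilvar = z + 0.01)
  colnames(m) <- paste0("S", 1:6)
  feats <- make_features(m, classes = c("rhizo_increased", "endo_increased",
                                        "rhizo_decreased", "endo_decreased",
                                        "soil_parameter"))
  cors <- correlate_pairs(feats, quiet = TRUE)
  net <- build_network(cors, feats, r_min = 0.8, alpha = 0.05, p_mode = "raw")
  sub <- split_subnetworks(net)
  n_parts <- nrow(sub$increased$edges) + nrow(sub$decreased$edges) +
    nrow(sub$between_edges) + nrow(sub$soil_edges)
  expect_equal(n_parts, nrow(net$edges))
  expect_true("soilvar" %in% sub$increased$nodes$id)
  expect_true("soilvar" %in% sub$decreased$nodes$id)   # linked to both classes
  expect_true(all(sub$between_edges$sign == "-"))
  # a network with no decreased OTUs yields an OTU-free decreased subnetwork
  feats_i <- make_features(m[1:2, ], classes = rep("rhizo_increased", 2))
  net_i <- build_network(correlate_pairs(feats_i, quiet = TRUE), feats_i,
                         r_min = 0.8, alpha = 0.05, p_mode = "raw")
  sub_i <- split_subnetworks(net_i)
  expect_equal(nrow(sub_i$decreased$nodes), 0)
})

test_that("hub ranking follows degree with deterministic tie-breaks", {
  # star graph: center connected to 5 leaves
  edges <- tibble::tibble(from = "hub", to = paste0("leaf", 1:5),
                          method = "pearson", r = 0.99, p = 1e-5, q = 1e-4,
                          sign = "+")
  nodes <- tibble::tibble(id = c("hub", paste0("leaf", 1:5)),
                          class = "rhizo_increased",
                          otu_id = c("hub", paste0("leaf", 1:5)),
                          compartment = "rhizosphere")
  net <- structure(list(nodes = nodes, edges = edges, params = list()),
                   class = "co_network")
  hubs <- rank_hubs(net, min_degree = 5, top_k = 1)
  expect_equal(hubs$id, "hub")
  expect_equal(hubs$degree, 5L)
  expect_equal(nrow(rank_hubs(net, min_degree = 6)), 0)
  # degrees match a brute-force incidence count on a random graph
  set.seed(47)
  ids <- paste0("n", 1:12)
  e <- t(combn(ids, 2))[sample(66, 20), ]
  net2 <- structure(list(
    nodes = tibble::tibble(id = ids, class = "rhizo_increased",
                           otu_id = ids, compartment = "rhizosphere"),
    edges = tibble::tibble(from = e[, 1], to = e[, 2], method = "pearson",
                           r = 0.95, p = 1e-4, q = 1e-3, sign = "+"),
    params = list()), class = "co_network")
  deg <- network_degrees(net2)
  brute <- vapply(ids, function(i) sum(e == i), integer(1))
  expect_equal(deg$degree, unname(brute[deg$id]))
  h <- rank_hubs(net2, min_degree = 0, top_k = 12)
  expect_true(all(diff(h$degree) <= 0))
})

test_that("SIF and GraphML exports round-trip the graph", {
  z <- c(1, 2, 4, 8, 16)
  m <- rbind(a = z, b = z * 3, lone = c(5, 1, 4, 2, 3))
  colnames(m) <- paste0("S", 1:5)
  feats <- make_features(m)
  net <- build_network(correlate_pairs(feats, quiet = TRUE), feats,
                       r_min = 0.9, alpha = 0.05, p_mode = "raw")
  expect_equal(nrow(net$edges), 1)   # only a-b correlates

  sif <- tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(lines[1], "a\tpos\tb")
  expect_true("lone" %in% lines)     # isolated node retained

  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- read_network_graphml(gml)
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$edges[, c("from", "to", "sign")],
               net$edges[, c("from", "to", "sign")])
  expect_equal(back$edges$r, net$edges$r, tolerance = 1e-12)

  # empty network writes valid, re-readable files
  feats0 <- make_features(m[c(1, 3), ])
  net0 <- build_network(correlate_pairs(feats0, quiet = TRUE), feats0,
                        r_min = 0.999, alpha = 1e-6, p_mode = "raw")
  expect_equal(nrow(net0$edges), 0)
  write_network_sif(net0, sif)
  expect_equal(sort(readLines(sif)), sort(net0$nodes$id))
  write_network_graphml(net0, gml)
  back0 <- read_network_graphml(gml)
  expect_setequal(back0$nodes$id, net0$nodes$id)
  expect_equal(nrow(back0$edges), 0)
})
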