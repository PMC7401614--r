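test_that("rarefaction drops shallow samples and hits the target depth", {
  counts <- make_counts(matrix(c(999L, 0L, 600L, 400L, 900L, 100L), 2, 3),
                        sample_ids = c("shallow", "exact", "deep"))
  counts$deep <- c(1500L, 700L)
  expect_message(rar <- rarefy_counts(counts, depth = 1000, seed = 3),
                 "shallow")
  m <- otu_matrix(rar)
  expect_identical(colnames(m), c("exact", "deep"))
  expect_true(all(colSums(m) == 1000))
  expect_error(rarefy_counts(counts, depth = 10000), "fewer than")
  # reproducibility
  expect_equal(rarefy_counts(counts, depth = 1000, seed = 3, quiet = TRUE),
               rar)
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- make_counts(matrix(c(30L, 70L), 2, 1))
  draws <- vapply(1:1000, function(s) {
    otu_matrix(rarefy_counts(counts, depth = 10, seed = s, quiet = TRUE))[, 1]
  }, numeric(2))
  # E[count_i] = depth * c_i / total; MC error ~ sd/sqrt(1000)
  expect_equal(rowMeans(draws), c(3, 7), tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("rarefaction never increases observed richness", {
  set.seed(5)
  for (i in 1:5) {
    counts <- make_counts(matrix(rpois(40, 3), 10, 4))
    counts[[2]] <- counts[[2]] + 10L  # ensure depth reachable
    before <- colSums(otu_matrix(counts) > 0)
    rar <- rarefy_counts(counts, depth = 20, seed = i, quiet = TRUE)
    after <- colSums(otu_matrix(rar) > 0)
    expect_true(all(after <= before[names(after)]))
  }
})

test_that("alpha diversity matches closed forms", {
  counts <- make_counts(matrix(c(25, 25, 25, 25,
                                 100, 0, 0, 0,
                                 50, 25, 25, 0), 4, 3),
                        sample_ids = c("uniform", "single", "mixed"))
  a <- alpha_diversity(counts)
  expect_equal(a$shannon[a$sample_id == "uniform"], 2)     # 4 even OTUs, bits
  expect_equal(a$simpson[a$sample_id == "uniform"], 0.75)
  expect_equal(a$observed_otus[a$sample_id == "uniform"], 4)
  expect_equal(a$shannon[a$sample_id == "single"], 0)
  expect_equal(a$simpson[a$sample_id == "single"], 0)
  expect_equal(a$observed_otus[a$sample_id == "single"], 1)
  # (0.5, 0.25, 0.25): 0.5*1 + 0.25*2 + 0.25*2 = 1.5 bits
  expect_equal(a$shannon[a$sample_id == "mixed"], 1.5)
  # natural-log option and dominance form
  an <- alpha_diversity(counts, shannon_base = exp(1), simpson = "dominance")
  expect_equal(an$shannon[1], log(4))
  expect_equal(an$simpson[1], 0.25)
})

test_that("uniform composition maximises Shannon and Simpson at fixed richness", {
  set.seed(9)
  uni <- alpha_diversity(make_counts(matrix(rep(10, 6), 6, 1)))
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 600, rep(1 / 6, 6)))
    if (all(p == 100)) next
    pert <- alpha_diversity(make_counts(matrix(p, 6, 1)))
    expect_lt(pert$shannon, uni$shannon)
    expect_lt(pert$simpson, uni$simpson)
  }
})

test_that("one-way ANOVA matches the classical F statistic", {
  # degenerate: identical values
  flat <- tibble::tibble(v = rep(2, 6), g = rep(c("a", "b"), 3))
  a <- anova_oneway(flat, "v", "g")
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)

  # two groups: F equals the squared pooled t statistic
  set.seed(21)
  df <- tibble::tibble(v = rnorm(12), g = rep(c("a", "b"), each = 6))
  a <- anova_oneway(df, "v", "g")
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)

  # random data vs the textbook sums-of-squares formula
  for (i in 1:5) {
    v <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
    gm <- tapply(v, g, mean); n <- tapply(v, g, length)
    ssb <- sum(n * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    f_ref <- (ssb / 2) / (ssw / 12)
    a <- anova_oneway(tibble::tibble(v = v, g = g), "v", "g")
    expect_equal(a$statistic, f_ref, tolerance = 1e-8)
    expect_equal(a$p_value, pf(f_ref, 2, 12, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("Tukey HSD matches the studentized-range formula", {
  # identical constants: all pairwise p = 1
  flat <- tibble::tibble(v = rep(1, 9), g = rep(c("a", "b", "c"), 3))
  tk <- tukey_hsd(flat, "v", "g")
  expect_true(all(tidy(tk)$adj_p_value == 1))

  # random 3-group data vs direct Tukey-Kramer computation
  set.seed(31)
  for (i in 1:5) {
    n <- c(4, 6, 5)
    g <- rep(c("a", "b", "c"), n)
    v <- rnorm(sum(n), mean = c(0, 0.5, 1)[match(g, c("a", "b", "c"))])
    tk <- tidy(tukey_hsd(tibble::tibble(v = v, g = g), "v", "g"))
    gm <- tapply(v, g, mean)
    mse <- sum((v - gm[g])^2) / (sum(n) - 3)
    for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
      ni <- n[match(pair, c("a", "b", "c"))]
      q <- abs(gm[pair[1]] - gm[pair[2]]) /
        sqrt(mse / 2 * (1 / ni[1] + 1 / ni[2]))
      p_ref <- ptukey(q, nmeans = 3, df = sum(n) - 3, lower.tail = FALSE)
      row <- tk[tk$contrast == paste(pair, collapse = "-"), ]
      expect_equal(row$adj_p_value, unname(p_ref), tolerance = 1e-6)
    }
  }

  # size-1 groups excluded with a warning; error when < 2 remain
  df <- tibble::tibble(v = c(1, 2, 3, 4, 5), g = c("a", "a", "b", "b", "c"))
  expect_warning(tk <- tukey_hsd(df, "v", "g"), "excluding")
  expect_equal(tk$groups, c("a", "b"))
  expect_error(suppressWarnings(
    tukey_hsd(tibble::tibble(v = 1:3, g = c("a", "b", "c")), "v", "g")),
    ">= 2 groups")
})

test_that("two-group Tukey reduces to the studentized range with k = 2", {
  set.seed(41)
  df <- tibble::tibble(v = rnorm(10), g = rep(c("a", "b"), each = 5))
  tk <- tidy(tukey_hsd(df, "v", "g"))
  gm <- tapply(df$v, df$g, mean)
  mse <- sum((df$v - gm[df$g])^2) / 8
  q <- unname(abs(diff(gm))) / sqrt(mse / 5)
  expect_equal(tk$adj_p_value,
               ptukey(q, nmeans = 2, df = 8, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("dominant OTUs use a strict pooled threshold", {
  counts <- make_counts(matrix(c(50, 1, 49, 0,
                                 50, 1, 0, 49), 4, 2))
  dom <- dominant_otus(counts)   # pooled over 200 reads
  expect_true("O1" %in% dom$otu_id)           # 50%
  expect_false("O2" %in% dom$otu_id)          # exactly 1.0%: strict
  uni <- make_counts(matrix(1L, 200, 3))
  expect_equal(nrow(dominant_otus(uni)), 0)   # each OTU at 0.5%
  expect_error(dominant_otus(counts, samples = "nope"), "Unknown sample")
})

test_that("Venn partition classifies zone membership patterns", {
  md <- make_metadata(n_sites = 1, n_samples = 2)
  n <- nrow(md)
  m <- matrix(0L, 3, n, dimnames = list(c("core", "one", "two"), md$sample_id))
  m["core", ] <- 1L
  m["one", md$sample_id[md$zone == "humid"][1]] <- 4L
  m["two", c(md$sample_id[md$zone == "humid"][1],
             md$sample_id[md$zone == "lower_arid"][1])] <- 2L
  vp <- venn_partition(as_otu_table(m), md, "rhizosphere")
  expect_equal(vp$category[vp$otu_id == "core"], "core")
  expect_equal(vp$category[vp$otu_id == "one"], "humid")
  expect_equal(vp$category[vp$otu_id == "two"], "partial")
})

test_that("Venn membership patterns partition the observed OTUs", {
  set.seed(13)
  md <- make_metadata(n_sites = 2, n_samples = 1)
  for (i in 1:5) {
    m <- matrix(rbinom(20 * nrow(md), 1, 0.3) * rpois(20 * nrow(md), 5),
                20, nrow(md), dimnames = list(paste0("O", 1:20), md$sample_id))
    observed <- sum(rowSums(m) > 0)
    vp <- venn_partition(as_otu_table(m), md, "rhizosphere")
    expect_equal(nrow(vp), observed)
    # categories partition by n_zones pattern
    expect_equal(sum(vp$category == "core") +
                   sum(vp$category %in% zone_levels) +
                   sum(vp$category == "partial"), observed)
    expect_true(all(vp$n_zones[vp$category == "core"] == 4))
    expect_true(all(vp$n_zones[vp$category %in% zone_levels] == 1))
  }
})
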