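#' Simulate a gradient-structured microbiome survey with known truth
#'
#' Generates an OTU count table across 4 ordered bioclimatic zones x sites x
#' 2 compartments, with planted monotone trends. Base relative abundances are
#' heavy-tailed (lognormal); planted increased OTUs are multiplied by
#' `fold_change^zone_rank` and decreased OTUs by `fold_change^(3 - zone_rank)`;
#' compositions are renormalised per sample and counts drawn from a
#' Dirichlet-multinomial at `depth` reads, so sample totals equal `depth`
#' exactly. Soil parameters follow signed linear trends in zone rank with
#' lognormal noise. Everything is reproducible from `seed`.
#'
#' Planted labels are assigned among OTUs whose base abundance is at least
#' `min_planted_abundance`: a trend planted on a vanishingly rare OTU would be
#' unobservable at any realistic sequencing depth, so such "truths" would test
#' the depth, not the classifier. Equal numbers of increased and decreased
#' OTUs keep the total planted mass roughly constant across zones, which
#' limits the compositional drift induced on neutral OTUs.
#'
#' @param n_otus Number of OTUs (default 300).
#' @param n_sites_per_zone Sites per zone (default 3; the humid zone gets the
#'   same number so group tests have replication).
#' @param n_samples_per_site Samples per site per compartment (default 3).
#' @param n_increased,n_decreased Planted monotone OTUs (default 20 each).
#' @param fold_change Multiplicative abundance step per zone rank (>= 1;
#'   default 2; 1 = null, no planted signal).
#' @param depth Reads per sample (default 5000).
#' @param dispersion Dirichlet-multinomial concentration (default 1000;
#'   smaller = more overdispersed).
#' @param base_sdlog sdlog of the lognormal base abundances (default 1.5).
#' @param min_planted_abundance Minimum base proportion for a planted OTU
#'   (default 0.003).
#' @param compartment_sdlog sdlog of the lognormal factor differentiating the
#'   endosphere base composition from the rhizosphere one (default 0.6).
#' @param soil_gradient_strength Named vector of signed per-variable trend
#'   strengths over the gradient (fractional change from humid to lower-arid
#'   midpoints); the default follows the field expectation that humidity,
#'   phosphorus, organic carbon, iron, potassium and CEC fall with aridity
#'   while calcium rises and pH and nitrogen stay flat.
#' @param soil_noise_sdlog Lognormal noise on soil values (default 0.15).
#' @param seed Integer seed.
#' @return List with `counts` (OTU table), `metadata`, `taxonomy`, `soil`,
#'   and `truth` (list of `otus`: per-OTU planted label; `soil`: per-variable
#'   planted sign; `config`: the arguments).
#' @export
simulate_gradient_community <- function(
    n_otus = 300, n_sites_per_zone = 3, n_samples_per_site = 3,
    n_increased = 20, n_decreased = 20, fold_change = 2,
    depth = 5000, dispersion = 1000, base_sdlog = 1.5,
    min_planted_abundance = 0.003, compartment_sdlog = 0.6,
    soil_gradient_strength = c(pH = 0, humidity = -0.5, TP = -0.5, TOC = -0.4,
                               TN = 0, Fe = -0.4, Ca = 0.5, K = -0.5,
                               CEC = -0.4),
    soil_noise_sdlog = 0.15, seed = 1L) {
  if (n_increased + n_decreased > n_otus) {
    abort("More planted OTUs than n_otus.")
  }
  stopifnot(fold_change >= 1, dispersion > 0, depth >= 1,
            n_sites_per_zone >= 1, n_samples_per_site >= 1)
  withr::with_seed(seed, {
    otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))

    base <- exp(rnorm(n_otus, 0, base_sdlog))
    base <- base / sum(base)

    # compartment-specific base compositions
    comp_mult <- exp(rnorm(n_otus, 0, compartment_sdlog))
    base_comp <- list(rhizosphere = base,
                      endosphere = base * comp_mult / sum(base * comp_mult))

    # a planted trend is shared by both compartments, so it must be
    # observable in both: eligibility uses the smaller of the two bases
    eligible <- which(pmin(base_comp$rhizosphere, base_comp$endosphere) >=
                        min_planted_abundance)
    if (length(eligible) < n_increased + n_decreased) {
      abort(paste0("Only ", length(eligible), " OTUs reach the minimum base ",
                   "abundance for planting; need ", n_increased + n_decreased,
                   ". Lower min_planted_abundance or n_planted."))
    }
    planted <- sample(eligible, n_increased + n_decreased)
    inc <- planted[seq_len(n_increased)]
    dec <- setdiff(planted, inc)
    label <- rep("neutral", n_otus)
    label[inc] <- "increased"
    label[dec] <- "decreased"

    zone_prefix <- c(humid = "HU", semi_arid = "SA",
                     upper_arid = "UA", lower_arid = "LA")
    sites <- tidyr::expand_grid(zone = zone_levels,
                                i = seq_len(n_sites_per_zone)) |>
      mutate(site_id = paste0(zone_prefix[.data$zone], .data$i),
             zone_rank = zone_rank(.data$zone))
    metadata <- tidyr::expand_grid(
      site_id = sites$site_id,
      compartment = compartment_levels,
      rep = seq_len(n_samples_per_site)) |>
      left_join(select(sites, "site_id", "zone", "zone_rank"), by = "site_id") |>
      mutate(sample_id = paste(.data$site_id,
                               compartment_prefix[.data$compartment],
                               .data$rep, sep = "_")) |>
      select("sample_id", "compartment", "zone", "zone_rank", "site_id")

    mult_for_rank <- function(z) {
      m <- rep(1, n_otus)
      m[inc] <- fold_change^z
      m[dec] <- fold_change^(3 - z)
      m
    }
    counts <- matrix(0L, n_otus, nrow(metadata),
                     dimnames = list(otu_ids, metadata$sample_id))
    for (k in seq_len(nrow(metadata))) {
      lam <- base_comp[[metadata$compartment[k]]] *
        mult_for_rank(metadata$zone_rank[k])
      pi_k <- lam / sum(lam)
      g <- rgamma(n_otus, shape = dispersion * pi_k, rate = 1)
      if (sum(g) == 0) g <- pi_k
      counts[, k] <- rmultinom(1, depth, g / sum(g))[, 1]
    }

    taxonomy <- synthetic_taxonomy(otu_ids)

    soil_baseline <- c(pH = 7.3, humidity = 3.8, TP = 5, TOC = 1.2, TN = 0.6,
                       Fe = 15, Ca = 3000, K = 100, CEC = 7)
    soil <- purrr::map(soil_variables, function(v) {
      s <- soil_gradient_strength[[v]]
      mu <- soil_baseline[[v]] *
        (1 + s * (sites$zone_rank - 1.5) / 1.5)
      pmax(mu * exp(rnorm(nrow(sites), 0, soil_noise_sdlog)), 0)
    }) |>
      rlang::set_names(soil_variables) |>
      as_tibble() |>
      bind_cols(tibble(site_id = sites$site_id)) |>
      relocate("site_id")

    truth <- list(
      otus = tibble(otu_id = otu_ids, label = label,
                    base_abundance = base,
                    fold_change = ifelse(label == "neutral", 1, fold_change)),
      soil = tibble(variable = soil_variables,
                    sign = sign(soil_gradient_strength[soil_variables]),
                    strength = unname(soil_gradient_strength[soil_variables])),
      config = list(n_otus = n_otus, n_sites_per_zone = n_sites_per_zone,
                    n_samples_per_site = n_samples_per_site,
                    n_increased = n_increased, n_decreased = n_decreased,
                    fold_change = fold_change, depth = depth,
                    dispersion = dispersion, seed = seed)
    )
    list(counts = as_otu_table(counts), metadata = metadata,
         taxonomy = taxonomy, soil = validate_soil_profiles(soil),
         truth = truth)
  })
}

# plausible lineages for synthetic OTUs; proteobacterial classes present so
# aggregate_taxa's split path is exercised on generated data
synthetic_taxonomy <- function(otu_ids) {
  phyla <- c("Proteobacteria", "Actinobacteria", "Firmicutes", "Chloroflexi",
             "Acidobacteria", "Bacteroidetes", "Cyanobacteria",
             "Verrucomicrobia", "Gemmatimonadetes", "Euryarchaeota")
  wts <- c(0.30, 0.25, 0.12, 0.08, 0.06, 0.06, 0.05, 0.03, 0.03, 0.02)
  proteo_classes <- c("Alphaproteobacteria", "Betaproteobacteria",
                      "Gammaproteobacteria", "Deltaproteobacteria")
  n <- length(otu_ids)
  ph <- sample(phyla, n, replace = TRUE, prob = wts)
  dom <- ifelse(ph == "Euryarchaeota", "Archaea", "Bacteria")
  cl <- ifelse(ph == "Proteobacteria",
               sample(proteo_classes, n, replace = TRUE),
               paste0(ph, "_class"))
  lineage <- paste0("k__", dom, ";p__", ph, ";c__", cl,
                    ";o__", ph, "_order;f__", ph, "_family",
                    ";g__Genus", seq_len(n))
  parse_lineage(otu_ids, lineage)
}

#' Soil physicochemical survey of the 19 cactus plantation sites
#'
#' The bundled per-site soil measurements (pH, humidity \%, total phosphorus
#' mg/l, total organic carbon \%, total nitrogen \%, Fe / Ca / K mg/kg, cation
#' exchange capacity mol/kg) for the 19 Tunisian *Opuntia ficus-indica* sites
#' spanning the four bioclimatic zones.
#'
#' The published value of pH at the humid site BZ is 74.3, which is not a
#' possible pH; `corrected = TRUE` replaces it with 7.43 (the likely intended
#' value) and records the substitution in the `"corrections"` attribute. Note
#' also that the table's potassium values are largest at the lower-arid sites
#' (e.g. GF2, 274.63 mg/kg) even though potassium is usually reported to fall
#' with aridity; the values are kept exactly as measured.
#'
#' @param corrected Replace the impossible BZ pH with 7.43 (default `FALSE`:
#'   values exactly as published).
#' @return Validated soil tibble (19 sites x 9 variables).
#' @export
load_soil_survey <- function(corrected = FALSE) {
  path <- system.file("extdata", "soil_survey.tsv", package = "aridnet")
  soil <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (corrected) {
    soil$pH[soil$site_id == "BZ"] <- 7.43
    attr(soil, "corrections") <- "BZ pH 74.3 -> 7.43 (impossible as printed)"
  }
  validate_soil_profiles(soil)
}

#' Site-to-zone assignments of the cactus plantation survey
#'
#' The 19 sampled sites with their bioclimatic zone (humid: BZ; semi-arid:
#' BA1-BA3, KA1-KA3; upper-arid: KS1-KS6, SB1-SB3; lower-arid: GF1-GF3),
#' location name and annual precipitation band.
#'
#' @return Tibble `site_id`, `zone`, `zone_rank`, `location`,
#'   `precipitation_mm`.
#' @export
load_site_zones <- function() {
  path <- system.file("extdata", "sites.tsv", package = "aridnet")
  sites <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sites$zone_rank <- zone_rank(sites$zone)
  relocate(as_tibble(sites), "site_id", "zone", "zone_rank")
}
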