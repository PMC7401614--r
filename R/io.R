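#' @include aridnet-package.R
NULL

taxonomy_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Validate an OTU count table
#'
#' An OTU table is a tibble whose first column `otu_id` holds unique OTU
#' identifiers and whose remaining columns are per-sample non-negative integer
#' counts. Most functions in the package call this internally; it is exported
#' so externally assembled tables can be checked up front.
#'
#' @param counts A data frame with an `otu_id` column and numeric sample
#'   columns.
#' @param integer_counts Require whole numbers (`TRUE` for raw counts; relative
#'   abundance tables set this to `FALSE`).
#' @return The validated table, as a tibble, invisibly usable in a pipe.
#' @export
validate_otu_table <- function(counts, integer_counts = TRUE) {
  counts <- as_tibble(counts)
  if (!"otu_id" %in% names(counts)) {
    abort("OTU table must have an 'otu_id' column.")
  }
  counts <- relocate(counts, "otu_id")
  ids <- as.character(counts$otu_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate otu_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  samp <- setdiff(names(counts), "otu_id")
  if (length(samp) == 0L) abort("OTU table has no sample columns.")
  if (anyDuplicated(samp)) abort("Duplicate sample columns in OTU table.")
  for (s in samp) {
    v <- counts[[s]]
    if (!is.numeric(v)) {
      abort(paste0("Sample column '", s, "' is not numeric."))
    }
    if (anyNA(v)) abort(paste0("Missing values in sample column '", s, "'."))
    if (any(v < 0)) {
      bad <- ids[which(v < 0)[1]]
      abort(paste0("Negative count at otu '", bad, "', sample '", s, "'."))
    }
    if (integer_counts && any(v != floor(v))) {
      bad <- ids[which(v != floor(v))[1]]
      abort(paste0("Non-integer count at otu '", bad, "', sample '", s, "'."))
    }
  }
  counts$otu_id <- ids
  counts
}

#' Convert an OTU table to a numeric matrix (OTUs x samples)
#'
#' @param counts An OTU table (see [validate_otu_table]).
#' @return Numeric matrix with OTU ids as rownames and sample ids as colnames.
#' @export
otu_matrix <- function(counts) {
  counts <- as_tibble(counts)
  samp <- setdiff(names(counts), "otu_id")
  m <- as.matrix(counts[, samp, drop = FALSE])
  rownames(m) <- counts$otu_id
  m
}

#' Build an OTU table tibble from a matrix
#'
#' @param m Numeric matrix, OTUs in rows (rownames = OTU ids), samples in
#'   columns (colnames = sample ids).
#' @return A tibble with `otu_id` plus one column per sample.
#' @export
as_otu_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  bind_cols(tibble(otu_id = rownames(m)),
            as_tibble(m, .name_repair = "minimal"))
}

#' Read an OTU count table
#'
#' TSV tables are OTU rows by sample columns with the first column named
#' `otu_id`. BIOM files (JSON or HDF5) are read through the biomformat
#' package.
#'
#' @param path Path to the table.
#' @param format `"auto"` (by extension), `"tsv"`, or `"biom"`.
#' @return A validated OTU table tibble.
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM requires the biomformat package.")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    tbl <- as_otu_table(m)
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (names(tbl)[1] != "otu_id") {
      # tolerate the common '#OTU ID' header
      if (grepl("otu", names(tbl)[1], ignore.case = TRUE)) {
        names(tbl)[1] <- "otu_id"
      } else {
        abort(paste0("Malformed header: first column is '", names(tbl)[1],
                     "', expected 'otu_id'."))
      }
    }
    tbl$otu_id <- as.character(tbl$otu_id)
  }
  validate_otu_table(tbl)
}

#' Write an OTU table as TSV
#'
#' @param counts OTU table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path) {
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `compartment`, `zone`, `site_id`. A
#' `zone_rank` column (0 = humid ... 3 = lower-arid) is appended.
#'
#' @param path TSV path.
#' @return A tibble of validated metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(md)
}

#' Validate sample metadata
#'
#' @param md Data frame with `sample_id`, `compartment`, `zone`, `site_id`.
#' @return Tibble with `zone_rank` added and enum levels checked.
#' @export
validate_sample_metadata <- function(md) {
  md <- as_tibble(md)
  need <- c("sample_id", "compartment", "zone", "site_id")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    abort(paste0("Metadata missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) abort("Duplicate sample_id in metadata.")
  bad <- setdiff(unique(md$compartment), compartment_levels)
  if (length(bad)) {
    abort(paste0("Unknown compartment(s): ", paste(bad, collapse = ", ")))
  }
  md$zone_rank <- zone_rank(md$zone)
  site_zone <- distinct(md, .data$site_id, .data$zone)
  if (anyDuplicated(site_zone$site_id)) {
    abort("A site_id maps to more than one zone.")
  }
  md
}

#' Read a taxonomy map
#'
#' TSV with columns `otu_id` and `lineage`, the lineage a semicolon-delimited
#' ranked string. Greengenes-style rank prefixes (`k__`, `p__`, ...) are
#' stripped. Missing ranks become `NA`.
#'
#' @param path TSV path.
#' @return Tibble with `otu_id`, the six ranks (domain..genus) and the raw
#'   `lineage` string.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(tx))) {
    abort("Taxonomy TSV needs columns 'otu_id' and 'lineage'.")
  }
  parse_lineage(tx$otu_id, tx$lineage)
}

#' Build a taxonomy tibble from lineage strings
#'
#' @param otu_id Character vector of OTU ids.
#' @param lineage Semicolon-delimited lineage strings, ranks ordered
#'   domain;phylum;class;order;family;genus.
#' @return Taxonomy tibble (one row per OTU, one column per rank).
#' @export
parse_lineage <- function(otu_id, lineage) {
  if (anyDuplicated(otu_id)) abort("Duplicate otu_id in taxonomy.")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  clean <- purrr::map(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(taxonomy_ranks)   # pad with NA
    p
  })
  ranks <- do.call(rbind, clean)
  colnames(ranks) <- taxonomy_ranks
  bind_cols(tibble(otu_id = as.character(otu_id)),
            as_tibble(ranks),
            tibble(lineage = as.character(lineage)))
}

soil_variables <- c("pH", "humidity", "TP", "TOC", "TN", "Fe", "Ca", "K", "CEC")

#' Read soil physicochemical profiles
#'
#' One row per site; columns `site_id` plus the nine soil variables
#' (pH, humidity \%, TP mg/l, TOC \%, TN \%, Fe mg/kg, Ca mg/kg, K mg/kg,
#' CEC mol/kg).
#'
#' @param path TSV path.
#' @return Validated soil tibble.
#' @export
read_soil_profiles <- function(path) {
  soil <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_soil_profiles(soil)
}

#' Validate soil profiles
#'
#' Checks schema, non-negative concentrations and percentage ranges.
#'
#' @param soil Data frame with `site_id` and the nine soil variables.
#' @return The soil tibble.
#' @export
validate_soil_profiles <- function(soil) {
  soil <- as_tibble(soil)
  miss <- setdiff(c("site_id", soil_variables), names(soil))
  if (length(miss)) {
    abort(paste0("Soil table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(soil$site_id)) abort("Duplicate site_id in soil table.")
  for (v in setdiff(soil_variables, "pH")) {
    if (any(soil[[v]] < 0, na.rm = TRUE)) {
      abort(paste0("Negative value in soil variable '", v, "'."))
    }
  }
  for (v in c("humidity", "TOC", "TN")) {
    if (any(soil[[v]] > 100, na.rm = TRUE)) {
      abort(paste0("Soil variable '", v, "' is a percentage; value > 100."))
    }
  }
  soil
}
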