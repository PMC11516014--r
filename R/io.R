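#' Region schemes
#'
#' Two regional partitions of the study area are used: the
#' cultural-geographical scheme `SB` (Scania and Bornholm), `DI` (Danish
#' Isles), `EJ` (Eastern Jutland), `WJ` (Western Jutland), and the pollen
#' reference scheme `NJ` (Northern Jutland), `SJ` (Southern Jutland),
#' `Zealand`. Region membership is always read from the input table's
#' region column; no geometry is computed.
#' @keywords internal
region_schemes <- list(
  cultural = c("SB", "DI", "EJ", "WJ"),
  pollen = c("NJ", "SJ", "Zealand")
)

# canonical columns of a radiocarbon date table
.date_cols <- c(lab_id = "lab_id", c14_age = "c14_age", error = "error",
                site_id = "site_id", region = "region",
                material = "material", site_type = "site_type")

#' Read a radiocarbon date table
#'
#' Reads a CSV of laboratory determinations into the package's canonical
#' layout: one row per date with columns `lab_id`, `c14_age` (14C yr BP),
#' `error` (1-sigma 14C yr), `site_id`, `region`, `material`, `site_type`.
#' Column names in the file are mapped through `schema`, so supplementary
#' tables with their own headers can be read without editing the file.
#' No row is dropped silently: rows with unparseable or non-positive age
#' or error are collected and reported as an error listing the offending
#' rows.
#'
#' @param path CSV path (UTF-8, header row; `#` comment lines allowed).
#' @param schema named character vector mapping canonical names (see
#'   above) to the file's column names; defaults to the canonical names.
#' @param region_scheme optional character vector of allowed region codes;
#'   unknown codes raise an error. `NULL` skips the check.
#' @return `data.frame` with the canonical columns (extra columns kept),
#'   with attribute `n_rows` giving the row count read.
#' @export
read_dates_csv <- function(path, schema = NULL, region_scheme = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  map <- .date_cols
  if (!is.null(schema)) map[names(schema)] <- schema
  missing <- setdiff(unname(map), names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  out <- df
  for (canon in names(map)) names(out)[names(out) == map[[canon]]] <- canon
  out$c14_age <- suppressWarnings(as.numeric(out$c14_age))
  out$error <- suppressWarnings(as.numeric(out$error))
  bad <- which(is.na(out$c14_age) | is.na(out$error) |
                 out$c14_age <= 0 | out$error <= 0)
  if (length(bad) > 0) {
    stop("unparseable or non-positive age/error in row(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(region_scheme)) {
    unknown <- setdiff(unique(out$region), region_scheme)
    if (length(unknown) > 0) {
      stop("region code(s) outside declared scheme: ",
           paste(unknown, collapse = ", "))
    }
  }
  attr(out, "n_rows") <- nrow(out)
  out
}

#' Write a radiocarbon date table
#'
#' Inverse of [read_dates_csv()]; fields round-trip exactly. An optional
#' provenance block (e.g. generator family, parameters, seed) is written
#' as `#` comment lines before the header.
#'
#' @param dates data.frame in canonical layout.
#' @param path output CSV path.
#' @param provenance optional named list written as `# key: value` lines.
#' @export
write_dates_csv <- function(dates, path, provenance = NULL) {
  write_csv_prov(dates, path, provenance)
}

write_csv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k,
                         paste(format(provenance[[k]]), collapse = " ")), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a typologically dated artifact table
#'
#' One row per artifact with columns `artifact_id`, `category`
#' (`battle_axe`, `flint_dagger` or `other`), `type_code`, `span_start`
#' and `span_end` (years BCE; `span_start >= span_end`; may be empty when
#' the span is to be resolved through a typochronology table), `region`,
#' `context` (`grave`, `settlement`, `hoard`, `stray`).
#'
#' @param path CSV path.
#' @return data.frame in canonical layout.
#' @export
read_artifacts_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("artifact_id", "category", "type_code", "span_start",
            "span_end", "region", "context")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$span_start <- suppressWarnings(as.numeric(df$span_start))
  df$span_end <- suppressWarnings(as.numeric(df$span_end))
  bad <- which(!is.na(df$span_start) & !is.na(df$span_end) &
                 df$span_start < df$span_end)
  if (length(bad) > 0) {
    stop("span_start < span_end (spans run old to young BCE) in row(s): ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a pollen sample table
#'
#' One row per pollen sample: `record_id` (core/site), `sample_id`,
#' `age_bce` (absolute age from the record's externally supplied
#' age-depth model), then one column of grain counts per taxon. All
#' columns other than the three identifiers are treated as taxa.
#'
#' @param path CSV path.
#' @return data.frame; attribute `taxa` lists the taxon columns.
#' @export
read_pollen_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("record_id", "sample_id", "age_bce")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  taxa <- setdiff(names(df), need)
  if (length(taxa) == 0) stop("no taxa count columns found")
  for (tx in taxa) {
    df[[tx]] <- suppressWarnings(as.numeric(df[[tx]]))
    if (anyNA(df[[tx]]) || any(df[[tx]] < 0)) {
      stop("negative or non-numeric counts in taxon column: ", tx)
    }
  }
  if (any(rowSums(df[taxa]) <= 0)) stop("sample(s) with zero total count")
  attr(df, "taxa") <- taxa
  df
}

#' Export a proxy time series as CSV
#'
#' Writes the common exchange layout `year_bce, value[, lower, upper]`.
#' Accepts any object with an [as.data.frame()] method producing those
#' columns (SPD, KDE model, growth, aoristic and openness series).
#'
#' @param series series object or data.frame.
#' @param path output path.
#' @param provenance optional named list written as `#` comment lines.
#' @export
write_series_csv <- function(series, path, provenance = NULL) {
  df <- as.data.frame(series)
  keep <- intersect(c("year_bce", "value", "lower", "upper"), names(df))
  write_csv_prov(df[keep], path, provenance)
}

#' Read a proxy time series CSV
#'
#' @param path CSV written by [write_series_csv()].
#' @return data.frame with `year_bce`, `value` and optional bounds.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Material-class lookup
#'
#' Maps free-text material strings to the semantic classes used by the
#' date filters (`short-lived`, `bone-human`, `bone-animal`,
#' `food-remains`, `shell`, `other`). A default lookup ships with the
#' package (`inst/extdata/material_classes.csv`) and is user-editable:
#' pass your own table with columns `pattern` (regular expression,
#' matched case-insensitively) and `class`.
#'
#' @param materials character vector of raw material strings.
#' @param lookup data.frame with columns `pattern`, `class`; default read
#'   from the shipped config.
#' @return character vector of material classes (`other` when unmatched).
#' @export
material_class <- function(materials, lookup = default_material_lookup()) {
  out <- rep("other", length(materials))
  low <- tolower(as.character(materials))
  # already-canonical class labels pass through
  canon <- c("short-lived", "bone-human", "bone-animal", "food-remains",
             "shell", "other")
  out[low %in% canon] <- low[low %in% canon]
  for (i in seq_len(nrow(lookup))) {
    hit <- out == "other" & grepl(lookup$pattern[i], low, ignore.case = TRUE)
    out[hit] <- lookup$class[i]
  }
  out
}

#' @rdname material_class
#' @export
default_material_lookup <- function() {
  path <- system.file("extdata", "material_classes.csv", package = "paleodem")
  if (nzchar(path)) {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    data.frame(
      pattern = c("shell|mollus|oyster", "human", "bone|antler|tooth",
                  "food|crust|residue", "charcoal|seed|grain|twig|hazel|cereal|nut"),
      class = c("shell", "bone-human", "bone-animal", "food-remains",
                "short-lived"),
      stringsAsFactors = FALSE
    )
  }
}
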