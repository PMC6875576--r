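# readers, writers and run configuration

PHYSCHEM_KNOWN <- c(
  "temperature", "water_temperature", "temp", "depth", "flow_velocity",
  "flow", "velocity", "ec", "conductivity", "ph", "do", "dissolved_oxygen",
  "bod5", "bod", "nitrate", "phosphate"
)

read_table_dialect <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mindu("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

#' Read a long-format macroinvertebrate abundance table
#'
#' Reads a CSV/TSV with one row per (station, date, taxon) holding the count
#' of individuals in that composite sample. A `season` column (`wet`/`dry`)
#' is optional: when absent it is inferred from the sampling month
#' (April-September wet, October-March dry); when present it must agree
#' with the month on every row.
#'
#' @param path path to a delimited text file with header columns
#'   `station`, `date` (ISO dates), `taxon`, `count` and optionally `season`.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return an `abundance_table`: a data.frame with columns `station`,
#'   `date` (Date), `season`, `taxon`, `count`.
#' @seealso [as_abundance_table()] to validate an in-memory data.frame.
#' @export
read_abundance_table <- function(path, dialect = c("csv", "tsv")) {
  as_abundance_table(read_table_dialect(path, dialect))
}

#' Validate a data.frame as an abundance table
#'
#' @param df data.frame with columns `station`, `date`, `taxon`, `count`
#'   and optionally `season`.
#' @return an `abundance_table` (see [read_abundance_table()]).
#' @export
as_abundance_table <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("station", "date", "taxon", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_mindu("abundance table is missing column(s): ",
               paste(missing_cols, collapse = ", "))

  date <- suppressWarnings(as.Date(as.character(df$date)))
  if (anyNA(date))
    stop_mindu("unparseable date(s) at row(s): ",
               paste(which(is.na(date)), collapse = ", "))

  count <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(count) | !is.finite(count) | count < 0 | count != round(count)
  if (any(bad))
    stop_mindu("counts must be non-negative integers; offending row(s): ",
               paste(which(bad), collapse = ", "))

  inferred <- season_from_date(date)
  if ("season" %in% names(df)) {
    season <- tolower(trimws(as.character(df$season)))
    if (!all(season %in% c("wet", "dry")))
      stop_mindu("season values must be 'wet' or 'dry'")
    clash <- season != inferred
    if (any(clash))
      stop_mindu("season column contradicts the sampling month at row(s): ",
                 paste(which(clash), collapse = ", "))
  } else {
    season <- inferred
  }

  out <- data.frame(station = as.character(df$station), date = date,
                    season = season, taxon = as.character(df$taxon),
                    count = as.integer(round(count)),
                    stringsAsFactors = FALSE)
  key <- paste(out$station, out$date, out$taxon, sep = "\r")
  if (anyDuplicated(key))
    stop_mindu("duplicated (station, date, taxon) record(s) at row(s): ",
               paste(which(duplicated(key)), collapse = ", "))
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "abundance_table: %d records, %d stations, %d taxa, %d sampling occasions\n",
    nrow(x), length(unique(x$station)), length(unique(x$taxon)),
    nrow(unique(x[, c("station", "date")]))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a station-by-variable physicochemistry table
#'
#' One row per station, one numeric column per variable (water temperature,
#' depth, flow velocity, EC, pH, DO, BOD5, nitrate, phosphate). Variables
#' outside the canonical set are carried through with a warning. Values are
#' per-station means over the period of interest.
#'
#' @inheritParams read_abundance_table
#' @return a `physchem_table`: data.frame with a `station` column and
#'   numeric variable columns.
#' @export
read_physchem_table <- function(path, dialect = c("csv", "tsv")) {
  as_physchem_table(read_table_dialect(path, dialect))
}

#' Validate a data.frame as a physicochemistry table
#'
#' @param df data.frame with a `station` column and numeric variables.
#' @return a `physchem_table` (see [read_physchem_table()]).
#' @export
as_physchem_table <- function(df) {
  names(df)[1] <- if (tolower(names(df)[1]) %in% c("station", "stations",
                                                   "station_id", "site"))
    "station" else names(df)[1]
  names(df) <- ifelse(tolower(names(df)) == "station", "station", names(df))
  if (!"station" %in% names(df))
    stop_mindu("physchem table needs a 'station' column (first column)")
  station <- as.character(df$station)
  if (anyDuplicated(station))
    stop_mindu("duplicated station id(s): ",
               paste(unique(station[duplicated(station)]), collapse = ", "))

  vars <- setdiff(names(df), "station")
  if (!length(vars)) stop_mindu("physchem table has no variable columns")
  for (v in vars) {
    val <- suppressWarnings(as.numeric(df[[v]]))
    if (anyNA(val) || any(!is.finite(val)))
      stop_mindu("non-numeric or non-finite value(s) in variable '", v, "'")
    df[[v]] <- val
  }
  ph_col <- vars[tolower(vars) == "ph"]
  if (length(ph_col) && any(df[[ph_col[1]]] < 0 | df[[ph_col[1]]] > 14))
    stop_mindu("pH values must lie in [0, 14]")
  unknown <- vars[!tolower(gsub("[^A-Za-z0-9]+", "_", vars)) %in%
                    PHYSCHEM_KNOWN]
  if (length(unknown))
    warn_mindu("carrying through unrecognised variable(s): ",
               paste(unknown, collapse = ", "))
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  out$station <- station
  class(out) <- c("physchem_table", "data.frame")
  out
}

#' Read a taxon-by-trait-modality fuzzy affinity table
#'
#' Fuzzy-coded trait affinities: each (taxon, modality) pair carries an
#' integer affinity 0 (none) to 3 (high). Affinities are later normalised
#' per taxon across modalities, so profiles need not sum to any constant.
#'
#' @inheritParams read_abundance_table
#' @return a `trait_table`: data.frame with columns `taxon`,
#'   `trait_modality`, `affinity`.
#' @export
read_trait_table <- function(path, dialect = c("csv", "tsv")) {
  as_trait_table(read_table_dialect(path, dialect))
}

#' Validate a data.frame as a fuzzy trait affinity table
#'
#' @param df data.frame with columns `taxon`, `trait_modality` (or
#'   `modality`), `affinity`.
#' @return a `trait_table` (see [read_trait_table()]).
#' @export
as_trait_table <- function(df) {
  names(df) <- tolower(names(df))
  if ("modality" %in% names(df) && !"trait_modality" %in% names(df))
    names(df)[names(df) == "modality"] <- "trait_modality"
  need <- c("taxon", "trait_modality", "affinity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_mindu("trait table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  aff <- suppressWarnings(as.numeric(df$affinity))
  if (any(is.na(aff)) || !all(aff %in% 0:3))
    stop_mindu("affinities must be integers in 0..3")
  out <- data.frame(taxon = as.character(df$taxon),
                    trait_modality = as.character(df$trait_modality),
                    affinity = as.integer(aff), stringsAsFactors = FALSE)
  key <- paste(out$taxon, out$trait_modality, sep = "\r")
  if (anyDuplicated(key))
    stop_mindu("duplicated (taxon, modality) entries in trait table")
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Write a pipeline product to CSV or JSON
#'
#' Dispatches on the object's class; the format follows the file extension
#' (`.json` for JSON, anything else for CSV). Numeric fields are written
#' with full precision so that re-reading reproduces integers bit-for-bit
#' and reals to at least 12 significant digits.
#'
#' @param object a pipeline product (threshold table, index result, metric
#'   matrix, station gradient, screening or correspondence report, or any
#'   data.frame/list).
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_results <- function(object, path) UseMethod("write_results")

write_df <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(df), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    num <- vapply(df, function(v) is.double(v) && !inherits(v, "Date"),
                  logical(1))
    out <- as.data.frame(df)
    out[num] <- lapply(out[num], as.character)  # full ~15-digit precision
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @export
write_results.data.frame <- function(object, path) write_df(object, path)

#' @export
write_results.list <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
write_results.correspondence_report <- function(object, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(object), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(path)
  } else {
    write_df(object$cells, path)
  }
}

#' Read a per-metric threshold table written by [write_results()]
#'
#' @param path CSV or JSON file with columns `metric`, `direction`, `min`,
#'   `q25`, `q50`, `q75`, `max`.
#' @return a `threshold_table`.
#' @export
read_threshold_table <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_threshold_table(df)
}

#' Run configuration for screening and delineation
#'
#' Bundles the tuning constants of the index-development pipeline: the
#' significance level shared by all nonparametric tests, the Spearman
#' correlation bound above which two metrics are declared redundant, and
#' the percentile cutpoints of the impact-category partition.
#'
#' @param alpha significance level for all tests (default 0.05).
#' @param spearman_cutoff redundancy bound on |rho| (default 0.78,
#'   inclusive).
#' @param percentile_cutpoints decreasing pair of percentiles (default
#'   `c(90, 50)`) splitting percent distances into LIS/MIS/HIS.
#' @param quantile_rule identifier of the quantile convention; only
#'   `"excel-inclusive"` (linear interpolation, R type 7) is implemented.
#' @param seed integer seed used by any randomised step.
#' @return a `run_config` list.
#' @export
run_config <- function(alpha = 0.05, spearman_cutoff = 0.78,
                       percentile_cutpoints = c(90, 50),
                       quantile_rule = "excel-inclusive", seed = 1L) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop_mindu("alpha must lie in (0, 1)")
  if (!(is.numeric(spearman_cutoff) && spearman_cutoff > 0 &&
        spearman_cutoff <= 1))
    stop_mindu("spearman_cutoff must lie in (0, 1]")
  cp <- as.numeric(percentile_cutpoints)
  if (length(cp) != 2 || any(cp <= 0) || any(cp >= 100) || cp[1] <= cp[2])
    stop_mindu("percentile_cutpoints must be strictly decreasing within (0, 100)")
  if (!identical(quantile_rule, "excel-inclusive"))
    stop_mindu("unsupported quantile rule: ", quantile_rule)
  structure(list(alpha = alpha, spearman_cutoff = spearman_cutoff,
                 percentile_cutpoints = cp, quantile_rule = quantile_rule,
                 seed = as.integer(seed)),
            class = "run_config")
}
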