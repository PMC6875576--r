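# quartile thresholds, 5/3/1 scoring, index aggregation and class lookup

#' Validate a data.frame as a per-metric threshold table
#'
#' @param df data.frame with columns `metric`, `direction`, `min`, `q25`,
#'   `q50`, `q75`, `max`.
#' @return a `threshold_table`.
#' @export
as_threshold_table <- function(df) {
  need <- c("metric", "direction", "min", "q25", "q50", "q75", "max")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_mindu("threshold table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if (!all(df$direction %in% c("increase", "decrease")))
    stop_mindu("direction must be 'increase' or 'decrease'")
  for (col in c("min", "q25", "q50", "q75", "max"))
    df[[col]] <- as.numeric(df[[col]])
  ok <- df$min <= df$q25 & df$q25 <= df$q50 & df$q50 <= df$q75 &
    df$q75 <= df$max
  if (!all(ok))
    stop_mindu("non-monotone quartile row(s) for metric(s): ",
               paste(df$metric[!ok], collapse = ", "))
  if (anyDuplicated(df$metric)) stop_mindu("duplicated metric names")
  out <- as.data.frame(df[, need], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Derive scoring thresholds from reference-station metric values
#'
#' Computes the five summary statistics (minimum, lower quartile, median,
#' upper quartile, maximum) of each metric over the least-impacted-station
#' development data, under the inclusive linear-interpolation quantile
#' rule. These statistics are the band edges of the 5/3/1 scoring scheme
#' (see [score_metric_value()]).
#'
#' @param lis_values named list: metric name -> numeric vector of LIS
#'   development values (at least 4 non-missing values each).
#' @param directions named character vector: metric name -> `"increase"`
#'   or `"decrease"` (predicted response to pollution).
#' @return a `threshold_table`.
#' @examples
#' derive_thresholds(list(`Hem Abun` = c(7, 9, 12, 16.5, 20)),
#'                   c(`Hem Abun` = "decrease"))
#' @export
derive_thresholds <- function(lis_values, directions) {
  if (!length(lis_values)) stop_mindu("no metrics supplied")
  mnames <- names(lis_values)
  if (is.null(mnames)) stop_mindu("lis_values must be a named list")
  missing_dir <- setdiff(mnames, names(directions))
  if (length(missing_dir))
    stop_mindu("no direction for metric(s): ",
               paste(missing_dir, collapse = ", "))
  rows <- lapply(mnames, function(nm) {
    v <- lis_values[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < 4)
      stop_mindu("metric '", nm, "' has fewer than 4 reference values")
    q <- quantile_inclusive(v, c(0, .25, .5, .75, 1))
    data.frame(metric = nm, direction = unname(directions[nm]),
               min = q[1], q25 = q[2], q50 = q[3], q75 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  as_threshold_table(do.call(rbind, rows))
}

#' Score a single metric value against its threshold row
#'
#' Direction-aware banded scoring. For a metric predicted to increase
#' with pollution: 5 when the value is below the reference upper quartile,
#' 3 from the upper quartile up to the reference maximum (inclusive), 1
#' above the maximum. For a metric predicted to decrease: 5 at or above
#' the reference lower quartile, 3 from the minimum up to (but excluding)
#' the lower quartile, 1 below the minimum. Equality at the upper quartile
#' of an increase metric takes the poorer score (3).
#'
#' @param value metric value (NA returns NA: the sample is unscorable).
#' @param thresholds a single-row `threshold_table` row (or the full table,
#'   with `metric` naming the row to use).
#' @param metric metric name selecting the row when `thresholds` has
#'   several.
#' @return integer score 5, 3 or 1 (or NA).
#' @export
score_metric_value <- function(value, thresholds, metric = NULL) {
  tt <- as.data.frame(thresholds)
  if (nrow(tt) > 1) {
    if (is.null(metric)) stop_mindu("give 'metric' to select a threshold row")
    tt <- tt[tt$metric == metric, , drop = FALSE]
    if (nrow(tt) != 1) stop_mindu("no threshold row for metric '", metric, "'")
  }
  if (is.na(value)) return(NA_integer_)
  if (tt$direction == "increase") {
    if (value < tt$q75) 5L else if (value <= tt$max) 3L else 1L
  } else {
    if (value >= tt$q25) 5L else if (value >= tt$min) 3L else 1L
  }
}

#' Water-quality class bands of the index
#'
#' Index sums of five 5/3/1 metric scores range 5-25 and map onto five
#' classes: 5-9 F (very poor), 10-13 E (poor), 14-17 D (fair), 18-21 C
#' (good), 22-25 B (very good).
#'
#' @return data.frame with columns `lo`, `hi`, `class`, `label`.
#' @export
mindu_class_bands <- function() {
  data.frame(lo = c(5L, 10L, 14L, 18L, 22L),
             hi = c(9L, 13L, 17L, 21L, 25L),
             class = c("F", "E", "D", "C", "B"),
             label = c("very poor", "poor", "fair", "good", "very good"),
             stringsAsFactors = FALSE)
}

#' Aggregate metric scores into the index value and class
#'
#' @param metric_scores named vector of per-metric scores in `{1, 3, 5}`;
#'   any NA makes the sample unscorable.
#' @return list with `metric_scores`, `mindu` (integer sum), `wq_class`,
#'   `label`; or with `mindu = NA` and `scorable = FALSE` when any score is
#'   missing.
#' @export
compute_index <- function(metric_scores) {
  if (anyNA(metric_scores))
    return(list(metric_scores = metric_scores, mindu = NA_integer_,
                wq_class = NA_character_, label = NA_character_,
                scorable = FALSE))
  if (!all(metric_scores %in% c(1L, 3L, 5L)))
    stop_mindu("metric scores must be 1, 3 or 5")
  total <- as.integer(sum(metric_scores))
  bands <- mindu_class_bands()
  hit <- which(total >= bands$lo & total <= bands$hi)
  if (length(hit) != 1)
    stop_mindu("index value ", total, " outside the class bands")
  list(metric_scores = metric_scores, mindu = total,
       wq_class = bands$class[hit], label = bands$label[hit],
       scorable = TRUE)
}

#' The packaged MINDU threshold table
#'
#' The published five-metric parameterisation of the Multimetric Index for
#' Niger Delta Urban rivers: Hemiptera abundance, %Coleoptera + Hemiptera,
#' %Chironomidae + Oligochaeta, evenness, and log relative abundance of
#' very large body size, with their reference-station summary statistics
#' exactly as published.
#'
#' @return a `threshold_table` of five rows.
#' @export
load_packaged_mindu <- function() {
  path <- system.file("extdata", "mindu_thresholds.csv", package = "mindu",
                      mustWork = TRUE)
  read_threshold_table(path)
}

#' Score every sampling occasion of a metric matrix
#'
#' Applies [score_metric_value()] to each threshold metric on every
#' occasion and aggregates with [compute_index()]. Occasions with any
#' missing metric value are flagged unscorable and carry no index value.
#'
#' @param mm a `metric_matrix` containing (at least) the threshold
#'   metrics' columns.
#' @param thresholds a `threshold_table` (default the packaged MINDU).
#' @return an `index_result` data.frame: `station`, `date`, `season`, one
#'   `score: <metric>` column per metric, `mindu`, `wq_class`, `label`,
#'   `scorable`.
#' @export
score_samples <- function(mm, thresholds = load_packaged_mindu()) {
  tt <- as.data.frame(thresholds)
  missing_cols <- setdiff(tt$metric, names(mm))
  if (length(missing_cols))
    stop_mindu("metric matrix lacks threshold metric(s): ",
               paste(missing_cols, collapse = ", "))
  out <- as.data.frame(mm)[, c("station", "date", "season"), drop = FALSE]
  score_mat <- matrix(NA_integer_, nrow(out), nrow(tt),
                      dimnames = list(NULL, paste("score:", tt$metric)))
  for (j in seq_len(nrow(tt))) {
    row <- tt[j, , drop = FALSE]
    score_mat[, j] <- vapply(mm[[tt$metric[j]]],
                             function(v) score_metric_value(v, row),
                             integer(1))
  }
  out <- cbind(out, as.data.frame(score_mat, check.names = FALSE))
  agg <- apply(score_mat, 1, function(s) {
    r <- compute_index(stats::setNames(as.integer(s), tt$metric))
    c(mindu = r$mindu, wq_class = r$wq_class, label = r$label,
      scorable = r$scorable)
  })
  out$mindu <- as.integer(agg["mindu", ])
  out$wq_class <- as.character(agg["wq_class", ])
  out$label <- as.character(agg["label", ])
  out$scorable <- as.logical(agg["scorable", ])
  rownames(out) <- NULL
  class(out) <- c("index_result", "data.frame")
  out
}

#' Score a survey with the index
#'
#' Convenience wrapper: computes the threshold metrics from a long-format
#' abundance table and scores every sampling occasion. With the default
#' thresholds this applies the packaged MINDU.
#'
#' @param abundance an `abundance_table`.
#' @param thresholds a `threshold_table` (default the packaged MINDU).
#' @param traits a `trait_table`, required when the thresholds include
#'   trait metrics (the packaged MINDU does: log relative abundance of
#'   very large body size).
#' @param registry metric registry used to compute the threshold metrics
#'   (default [default_metric_registry()], subset to the threshold
#'   metrics).
#' @return an `index_result` (see [score_samples()]).
#' @examples
#' sim <- simulate_survey(simulation_config(seed = 1))
#' res <- score_survey(sim$abundance, traits = sim$traits)
#' table(res$label)
#' @export
score_survey <- function(abundance, thresholds = load_packaged_mindu(),
                         traits = NULL,
                         registry = default_metric_registry()) {
  tt <- as.data.frame(thresholds)
  reg <- registry_subset(registry, tt$metric)
  have <- vapply(reg, `[[`, character(1), "name")
  missing_m <- setdiff(tt$metric, have)
  if (length(missing_m))
    stop_mindu("registry has no definition for metric(s): ",
               paste(missing_m, collapse = ", "))
  mm <- compute_metric_matrix(abundance, reg, traits)
  score_samples(mm, thresholds)
}

#' @export
print.index_result <- function(x, ...) {
  ns <- sum(x$scorable)
  cat(sprintf("index_result: %d occasions (%d scorable)\n", nrow(x), ns))
  if (ns) {
    tab <- table(factor(x$label[x$scorable],
                        levels = rev(mindu_class_bands()$label)))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
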