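# index validation: percent correspondence with the physicochemical categories

#' Acceptable water-quality labels per impact category
#'
#' A least-impacted station should score very good or good; a moderately
#' impacted station good or fair; a heavily impacted station fair, poor or
#' very poor. Correspondence is the percent of a category's occasions
#' whose index label falls in its acceptable set.
#'
#' @return named list: category label -> character vector of acceptable
#'   index labels.
#' @export
default_correspondence_rule <- function() {
  list(LIS = c("very good", "good"),
       MIS = c("good", "fair"),
       HIS = c("fair", "poor", "very poor"))
}

#' Percent correspondence between index classes and impact categories
#'
#' For each impact category, the label histogram of its scorable occasions
#' (percent of the category's total) and the correspondence percent — the
#' summed share of acceptable labels. All percentages use the category's
#' pooled occasion count as denominator, so per-season cells (see
#' [seasonal_correspondence()]) add up to the overall cells.
#'
#' @param results an `index_result` with a `category` column, or an
#'   `index_result` plus `categories` mapping station to category.
#' @param categories optional named vector (station -> 1/2/3 or
#'   LIS/MIS/HIS), e.g. from [delineate_stations()].
#' @param rule acceptable-label rule
#'   (default [default_correspondence_rule()]).
#' @return a `correspondence_report`: list with `summary` (category, n,
#'   correspondence), `cells` (category x label percent), and the `rule`.
#' @examples
#' sim <- simulate_survey(simulation_config(seed = 1))
#' res <- score_survey(sim$abundance, traits = sim$traits)
#' correspondence(res, sim$categories)$summary
#' @export
correspondence <- function(results, categories = NULL,
                           rule = default_correspondence_rule()) {
  df <- attach_categories(results, categories)
  build_correspondence(df, rule, by_season = FALSE)
}

#' Season-stratified percent correspondence
#'
#' The [correspondence()] computation stratified by season. Cell
#' percentages keep the category's pooled (both-season) occasion count as
#' denominator, so a category's wet and dry shares of a label sum to its
#' overall share, and the two seasonal correspondences sum to the overall
#' correspondence.
#'
#' @inheritParams correspondence
#' @return a `correspondence_report` whose `summary` and `cells` carry a
#'   `season` column.
#' @export
seasonal_correspondence <- function(results, categories = NULL,
                                    rule = default_correspondence_rule()) {
  df <- attach_categories(results, categories)
  build_correspondence(df, rule, by_season = TRUE)
}

attach_categories <- function(results, categories) {
  df <- as.data.frame(results)
  if (!is.null(categories)) {
    code <- normalize_categories(categories)
    missing_st <- setdiff(unique(df$station), names(code))
    if (length(missing_st))
      stop_mindu("no impact category for station(s): ",
                 paste(missing_st, collapse = ", "))
    df$category <- IMPACT_LABELS[code[df$station]]
  }
  if (!"category" %in% names(df))
    stop_mindu("results need a 'category' column or a 'categories' mapping")
  if (is.numeric(df$category)) df$category <- IMPACT_LABELS[df$category]
  df
}

build_correspondence <- function(df, rule, by_season) {
  df <- df[df$scorable %||% TRUE & !is.na(df$label), , drop = FALSE]
  labels <- mindu_class_bands()$label
  seasons <- if (by_season) sort(unique(df$season)) else "all"
  cells <- expand.grid(category = names(rule), season = seasons,
                       label = labels, stringsAsFactors = FALSE)
  cells$percent <- NA_real_
  summ <- expand.grid(category = names(rule), season = seasons,
                      stringsAsFactors = FALSE)
  summ$n <- NA_integer_
  summ$correspondence <- NA_real_

  for (cat in names(rule)) {
    in_cat <- df$category == cat
    n_cat <- sum(in_cat)                       # pooled denominator
    for (ss in seasons) {
      sel <- in_cat & (if (ss == "all") TRUE else df$season == ss)
      i_s <- summ$category == cat & summ$season == ss
      summ$n[i_s] <- sum(sel)
      if (n_cat == 0) next                     # empty category -> missing
      for (lb in labels) {
        i_c <- cells$category == cat & cells$season == ss & cells$label == lb
        cells$percent[i_c] <- 100 * sum(sel & df$label == lb) / n_cat
      }
      acc <- rule[[cat]]
      summ$correspondence[i_s] <-
        100 * sum(sel & df$label %in% acc) / n_cat
    }
  }
  if (!by_season) {
    cells$season <- NULL
    summ$season <- NULL
  }
  structure(list(summary = summ, cells = cells, rule = rule),
            class = c("correspondence_report", "list"))
}

#' @export
print.correspondence_report <- function(x, ...) {
  cat("correspondence_report\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}
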