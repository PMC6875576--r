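# shared helpers

#' Spreadsheet-inclusive quantiles
#'
#' Quantiles by linear interpolation between order statistics (R type 7,
#' identical to the inclusive percentile/quartile rule of common
#' spreadsheets). All quartile and percentile computations in the package
#' go through this one function so that thresholds, box-plot criteria and
#' gradient cutpoints use a single convention.
#'
#' @param x numeric vector (NAs dropped).
#' @param probs probabilities in \[0, 1\].
#' @return unnamed numeric vector of quantiles.
#' @export
quantile_inclusive <- function(x, probs) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing values to take quantiles of")
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# months April-September are the wet season, October-March the dry season
season_from_date <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 4L & m <= 9L, "wet", "dry")
}

# evaluate `expr` with the RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_mindu <- function(...) stop(..., call. = FALSE)
warn_mindu <- function(...) warning(..., call. = FALSE)
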