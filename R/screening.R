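# metric screening: sensitivity, seasonal stability, redundancy

#' Box-plot discrimination between reference and impaired groups
#'
#' A metric discriminates when the interquartile ranges (IQRs) of the two
#' groups do not overlap, or, failing that, when each group's median lies
#' strictly outside the other group's IQR. Quartiles use the inclusive
#' linear-interpolation rule.
#'
#' @param ref metric values at the least impacted stations.
#' @param imp metric values at the impaired (moderately + heavily
#'   impacted) stations.
#' @return list with `pass` (TRUE/FALSE, or NA when either group has fewer
#'   than 4 values) and `criterion` (`"IQR-disjoint"`, `"median-outside"`,
#'   `"none"`, or `"inconclusive"`).
#' @export
boxplot_discrimination <- function(ref, imp) {
  ref <- ref[!is.na(ref)]
  imp <- imp[!is.na(imp)]
  if (length(ref) < 4 || length(imp) < 4)
    return(list(pass = NA, criterion = "inconclusive"))
  qr <- quantile_inclusive(ref, c(.25, .5, .75))
  qi <- quantile_inclusive(imp, c(.25, .5, .75))
  if (qr[3] < qi[1] || qi[3] < qr[1])
    return(list(pass = TRUE, criterion = "IQR-disjoint"))
  if ((qr[2] < qi[1] || qr[2] > qi[3]) && (qi[2] < qr[1] || qi[2] > qr[3]))
    return(list(pass = TRUE, criterion = "median-outside"))
  list(pass = FALSE, criterion = "none")
}

#' Mann-Whitney confirmation of metric sensitivity
#'
#' Two-sided Mann-Whitney U test of the reference against the impaired
#' values. The exact null distribution is used for small untied samples;
#' otherwise the tie-corrected normal approximation. A metric is sensitive
#' when `p < alpha`.
#'
#' @inheritParams boxplot_discrimination
#' @param alpha significance level (default 0.05).
#' @return list with `U`, `p`, `sensitive`.
#' @export
mann_whitney_confirm <- function(ref, imp, alpha = 0.05) {
  ref <- ref[!is.na(ref)]
  imp <- imp[!is.na(imp)]
  if (!length(ref) || !length(imp)) stop_mindu("both groups must be non-empty")
  if (length(unique(c(ref, imp))) == 1L)
    return(list(U = length(ref) * length(imp) / 2, p = 1, sensitive = FALSE))
  wt <- suppressWarnings(stats::wilcox.test(ref, imp,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       sensitive = wt$p.value < alpha)
}

#' Kolmogorov-Smirnov normality gate (informational)
#'
#' One-sample KS test of the metric values against a normal distribution
#' with the sample mean and standard deviation. The screening pipeline is
#' nonparametric throughout regardless of the outcome; the flag is logged
#' so that the choice of rank tests is documented per metric.
#'
#' @param x metric values (n >= 5).
#' @param alpha significance level (default 0.05).
#' @return list with `D`, `p`, `normal`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop_mindu("need at least 5 values for the normality gate")
  if (stats::sd(x) == 0)
    return(list(D = NA_real_, p = 0, normal = FALSE))
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(kt$statistic), p = kt$p.value,
       normal = kt$p.value >= alpha)
}

#' Kruskal-Wallis seasonal-stability screen
#'
#' Tests a metric's reference-station (LIS) values for differences across
#' seasons; only reference stations are used so that seasonal signal is not
#' confounded with pollution. A metric is seasonally stable when
#' `p >= alpha`.
#'
#' @param values_by_season named list (`wet`, `dry`, ...) of metric values
#'   at the reference stations.
#' @param alpha significance level (default 0.05).
#' @return list with `H`, `p`, `stable`.
#' @export
seasonality_screen <- function(values_by_season, alpha = 0.05) {
  values_by_season <- lapply(values_by_season, function(v) v[!is.na(v)])
  short <- names(values_by_season)[lengths(values_by_season) < 2]
  if (length(short))
    stop_mindu("season(s) with fewer than 2 values: ",
               paste(short, collapse = ", "))
  if (length(values_by_season) < 2)
    stop_mindu("need at least 2 seasons")
  v <- unlist(values_by_season, use.names = FALSE)
  g <- factor(rep(names(values_by_season), lengths(values_by_season)))
  if (length(unique(v)) == 1L)
    return(list(H = 0, p = 1, stable = TRUE))
  kw <- stats::kruskal.test(v, g)
  list(H = unname(kw$statistic), p = kw$p.value,
       stable = kw$p.value >= alpha)
}

#' Spearman redundancy groups
#'
#' Pairwise Spearman rank correlations over complete observation pairs;
#' metric pairs with `|rho| >= cutoff` (inclusive) and `p < alpha` are
#' redundant. Redundancy groups are the connected components of the
#' resulting graph, so redundancy is transitive by construction.
#'
#' @param mat numeric matrix or data.frame, occasions x metrics.
#' @param cutoff redundancy bound on |rho| (default 0.78).
#' @param alpha significance level (default 0.05).
#' @param min_pairs minimum complete pairs per correlation (default 5).
#' @return data.frame with columns `metric`, `group` (integer id; NA for
#'   metrics excluded for zero variance).
#' @export
redundancy_screen <- function(mat, cutoff = 0.78, alpha = 0.05,
                              min_pairs = 5) {
  mat <- as.matrix(as.data.frame(mat, check.names = FALSE))
  storage.mode(mat) <- "double"
  if (ncol(mat) < 2) stop_mindu("need at least 2 metrics")
  v <- apply(mat, 2, stats::var, na.rm = TRUE)
  excluded <- is.na(v) | v == 0
  if (any(excluded))
    warn_mindu("excluding zero-variance metric(s) from redundancy: ",
               paste(colnames(mat)[excluded], collapse = ", "))
  keep <- which(!excluded)
  m <- length(keep)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    x <- mat[, keep[i]]; y <- mat[, keep[j]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < min_pairs) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman"))
    if (!is.na(ct$estimate) && abs(ct$estimate) >= cutoff &&
        !is.na(ct$p.value) && ct$p.value < alpha)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  # connected components by label propagation
  comp <- seq_len(m)
  repeat {
    new <- comp
    for (i in seq_len(m))
      if (any(adj[i, ])) new[i] <- min(new[c(i, which(adj[i, ]))])
    if (identical(new, comp)) break
    comp <- new
  }
  group <- rep(NA_integer_, ncol(mat))
  group[keep] <- match(comp, sort(unique(comp)))
  data.frame(metric = colnames(mat), group = group,
             stringsAsFactors = FALSE)
}

#' Choose one metric per redundancy group
#'
#' Non-redundant (singleton-group) candidates are kept outright. Within a
#' redundancy group the retained metric is the one named earliest in
#' `preferences`; with no applicable preference, the member with the
#' smallest Mann-Whitney p-value (ties broken alphabetically). The
#' preference hook exists because the choice among redundant metrics is,
#' in practice, partly a literature judgement.
#'
#' @param report a `screening_report` (or data.frame with columns `metric`,
#'   `mw_p`, `sensitive`, `seasonally_stable`, `redundancy_group`).
#' @param preferences character vector of metric names in priority order.
#' @return character vector of retained metric names (report order).
#' @export
select_final_metrics <- function(report, preferences = character()) {
  df <- as.data.frame(report)
  unknown <- setdiff(preferences, df$metric)
  if (length(unknown))
    warn_mindu("ignoring unknown preference(s): ",
               paste(unknown, collapse = ", "))
  cand <- df[isTRUE_v(df$sensitive) & isTRUE_v(df$seasonally_stable) &
               !is.na(df$redundancy_group), , drop = FALSE]
  retained <- character()
  for (g in unique(cand$redundancy_group)) {
    members <- cand[cand$redundancy_group == g, , drop = FALSE]
    pref_hit <- preferences[preferences %in% members$metric]
    pick <- if (length(pref_hit)) {
      pref_hit[1]
    } else {
      ord <- order(members$mw_p, members$metric)
      members$metric[ord][1]
    }
    retained <- c(retained, pick)
  }
  df$metric[df$metric %in% retained]
}

isTRUE_v <- function(x) !is.na(x) & x

#' Run the full metric-screening pipeline
#'
#' Stage 1 (sensitivity): box-plot discrimination of reference (LIS)
#' against impaired occasions, confirmed by a Mann-Whitney test. By
#' default the impaired group pools MIS and HIS occasions; with
#' `pairwise = TRUE` the LIS-vs-MIS and LIS-vs-HIS comparisons are run
#' separately and both must pass. Stage 2 (seasonal stability):
#' Kruskal-Wallis across seasons on LIS occasions only. Stage 3
#' (redundancy): Spearman groups among the sensitive + stable metrics,
#' one metric retained per group.
#'
#' @param mm a `metric_matrix` (see [compute_metric_matrix()]).
#' @param categories named vector mapping station to impact category
#'   (codes 1/2/3 or labels LIS/MIS/HIS), e.g. from
#'   [delineate_stations()].
#' @param config a [run_config()].
#' @param pairwise require discrimination against MIS and HIS separately.
#' @param preferences passed to [select_final_metrics()].
#' @return a `screening_report` data.frame, one row per metric, with a
#'   `"retained"` attribute listing the final metric names.
#' @examples
#' sim <- simulate_survey(simulation_config(seed = 1))
#' mm <- compute_metric_matrix(sim$abundance, traits = sim$traits)
#' rep <- screen_metrics(mm, sim$categories)
#' attr(rep, "retained")
#' @export
screen_metrics <- function(mm, categories, config = run_config(),
                           pairwise = FALSE, preferences = character()) {
  code <- normalize_categories(categories)
  st <- mm$station
  missing_st <- setdiff(unique(st), names(code))
  if (length(missing_st))
    stop_mindu("no impact category for station(s): ",
               paste(missing_st, collapse = ", "))
  cat_of <- code[st]
  mnames <- metric_names(mm)
  dirs <- attr(mm, "directions")
  alpha <- config$alpha

  rows <- lapply(mnames, function(nm) {
    vals <- mm[[nm]]
    ref <- vals[cat_of == 1L]
    bp_mw <- function(imp_vals) {
      bp <- boxplot_discrimination(ref, imp_vals)
      mw <- tryCatch(mann_whitney_confirm(ref, imp_vals, alpha),
                     error = function(e) list(U = NA_real_, p = NA_real_,
                                              sensitive = NA))
      list(bp = bp, mw = mw)
    }
    if (pairwise) {
      a <- bp_mw(vals[cat_of == 2L])
      b <- bp_mw(vals[cat_of == 3L])
      bp_pass <- isTRUE(a$bp$pass) && isTRUE(b$bp$pass)
      bp_crit <- paste(a$bp$criterion, b$bp$criterion, sep = "/")
      mw_U <- max(a$mw$U, b$mw$U)
      mw_p <- max(a$mw$p, b$mw$p)
    } else {
      r <- bp_mw(vals[cat_of %in% c(2L, 3L)])
      bp_pass <- r$bp$pass
      bp_crit <- r$bp$criterion
      mw_U <- r$mw$U
      mw_p <- r$mw$p
    }
    sensitive <- isTRUE(bp_pass) && !is.na(mw_p) && mw_p < alpha

    ks <- tryCatch(normality_gate(vals[!is.na(vals)], alpha),
                   error = function(e) list(D = NA_real_, p = NA_real_,
                                            normal = NA))
    lis <- mm[cat_of == 1L, , drop = FALSE]
    kw <- tryCatch(
      seasonality_screen(split(lis[[nm]], lis$season), alpha),
      error = function(e) list(H = NA_real_, p = NA_real_, stable = NA))

    data.frame(metric = nm,
               direction = unname(dirs[nm] %||% NA_character_),
               boxplot_pass = bp_pass, boxplot_criterion = bp_crit,
               mw_U = mw_U, mw_p = mw_p, sensitive = sensitive,
               ks_D = ks$D, ks_p = ks$p, normal = ks$normal,
               kw_H = kw$H, kw_p = kw$p, seasonally_stable = kw$stable,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)

  cand <- report$metric[isTRUE_v(report$sensitive) &
                          isTRUE_v(report$seasonally_stable)]
  report$redundancy_group <- NA_integer_
  if (length(cand) >= 2) {
    red <- redundancy_screen(mm[, cand, drop = FALSE],
                             cutoff = config$spearman_cutoff, alpha = alpha)
    report$redundancy_group[match(red$metric, report$metric)] <- red$group
  } else if (length(cand) == 1) {
    report$redundancy_group[report$metric == cand] <- 1L
  }
  retained <- select_final_metrics(report, preferences)
  report$retained <- report$metric %in% retained
  attr(report, "retained") <- retained
  class(report) <- c("screening_report", "data.frame")
  report
}

normalize_categories <- function(categories) {
  if (is.data.frame(categories)) {
    if (all(c("station", "category") %in% names(categories)))
      categories <- stats::setNames(categories$category, categories$station)
    else stop_mindu("categories data.frame needs 'station' and 'category'")
  }
  if (is.character(categories) || is.factor(categories)) {
    code <- match(toupper(as.character(categories)), IMPACT_LABELS)
    if (anyNA(code)) stop_mindu("category labels must be LIS/MIS/HIS")
    stats::setNames(as.integer(code), names(categories))
  } else {
    code <- as.integer(categories)
    if (!all(code %in% 1:3)) stop_mindu("category codes must be 1, 2 or 3")
    stats::setNames(code, names(categories))
  }
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "screening_report: %d metrics; %d sensitive, %d seasonally stable, %d retained\n",
    nrow(x), sum(isTRUE_v(x$sensitive)), sum(isTRUE_v(x$seasonally_stable)),
    sum(x$retained)))
  if (length(attr(x, "retained")))
    cat("  retained:", paste(attr(x, "retained"), collapse = ", "), "\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
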