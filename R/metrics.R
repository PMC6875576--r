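# candidate-metric computation: abundance, composition, diversity, traits

#' Summed abundance of a taxon group
#'
#' @param sample named integer vector of counts per taxon (one sampling
#'   occasion).
#' @param taxa character vector of family names belonging to the group
#'   (see [group_members()]).
#' @return total count over the group's taxa (0 when none occur).
#' @export
group_abundance <- function(sample, taxa) {
  if (any(sample < 0, na.rm = TRUE)) stop_mindu("counts must be >= 0")
  sum(sample[names(sample) %in% taxa])
}

#' Percent composition of a taxon group
#'
#' @inheritParams group_abundance
#' @return `100 * group_abundance / total`, or `NA` for an empty sample.
#' @export
percent_composition <- function(sample, taxa) {
  n <- sum(sample)
  if (is.na(n) || n <= 0) return(NA_real_)
  100 * group_abundance(sample, taxa) / n
}

#' Community diversity indices
#'
#' Shannon-Wiener `H = -sum p_i ln p_i` (natural log), Simpson diversity
#' `1 - sum p_i^2`, Margalef richness `(S - 1)/ln N` (undefined at N = 1),
#' and Pielou evenness `J = H/ln S` (undefined at S = 1).
#'
#' @param sample named integer vector of counts per taxon.
#' @return list with components `shannon`, `simpson`, `margalef`,
#'   `evenness`; all `NA` for an empty sample.
#' @export
diversity_indices <- function(sample) {
  n <- sum(sample)
  if (is.na(n) || n <= 0)
    return(list(shannon = NA_real_, simpson = NA_real_,
                margalef = NA_real_, evenness = NA_real_))
  cnt <- sample[sample > 0]
  s <- length(cnt)
  p <- cnt / n
  h <- -sum(p * log(p))
  list(shannon = h,
       simpson = 1 - sum(p^2),
       margalef = if (n == 1) NA_real_ else (s - 1) / log(n),
       evenness = if (s == 1) NA_real_ else h / log(s))
}

#' Log relative abundance of a fuzzy-coded trait modality
#'
#' Each taxon's affinity profile (0-3 per modality) is normalised to
#' weights summing to 1; taxa with an all-zero profile, or absent from the
#' trait table, contribute nothing. The modality's weighted abundance
#' `A = sum count_t * w_t` is expressed relative to the total count `N`
#' and the metric is `log10(1 + A/N)`, which lies in \[0, log10 2\].
#'
#' @param sample named integer vector of counts per taxon.
#' @param traits a `trait_table` (see [read_trait_table()]).
#' @param modality trait modality name, e.g.
#'   `"very_large_body_>40-80mm"`.
#' @return the metric value, or `NA` for an empty sample.
#' @export
trait_log_relative_abundance <- function(sample, traits, modality) {
  if (!modality %in% traits$trait_modality)
    stop_mindu("modality '", modality, "' not present in the trait table")
  n <- sum(sample)
  if (is.na(n) || n <= 0) return(NA_real_)
  w <- vapply(names(sample), function(tx) {
    rows <- traits$taxon == tx
    tot <- sum(traits$affinity[rows])
    if (tot == 0) return(0)
    sum(traits$affinity[rows & traits$trait_modality == modality]) / tot
  }, numeric(1))
  a <- sum(sample * w)
  log10(1 + a / n)
}

#' Define a candidate metric
#'
#' @param name metric name (used as column name and threshold key).
#' @param family one of `"abundance"`, `"composition"`, `"richness"`,
#'   `"diversity"`, `"trait"`.
#' @param direction predicted response to increasing urban pollution:
#'   `"increase"` or `"decrease"`.
#' @param formula_id registry key: one of `"group_abundance"`,
#'   `"percent_group"`, `"total_abundance"`, `"richness"`, `"shannon"`,
#'   `"simpson"`, `"margalef"`, `"evenness"`, `"trait_log_rel_abund"`.
#' @param taxa family names for group metrics (already resolved, see
#'   [group_members()]).
#' @param trait_modality modality name for trait metrics.
#' @return a `metric_definition`.
#' @export
metric_definition <- function(name, family, direction, formula_id,
                              taxa = NULL, trait_modality = NULL) {
  family <- match.arg(family, c("abundance", "composition", "richness",
                                "diversity", "trait"))
  direction <- match.arg(direction, c("increase", "decrease"))
  structure(list(name = name, family = family, direction = direction,
                 formula_id = formula_id, taxa = taxa,
                 trait_modality = trait_modality),
            class = "metric_definition")
}

METRIC_FORMULAE <- c("group_abundance", "percent_group", "total_abundance",
                     "richness", "shannon", "simpson", "margalef",
                     "evenness", "trait_log_rel_abund")

eval_metric <- function(def, sample, traits) {
  switch(def$formula_id,
    group_abundance = group_abundance(sample, def$taxa),
    percent_group = percent_composition(sample, def$taxa),
    total_abundance = sum(sample),
    richness = sum(sample > 0),
    shannon = diversity_indices(sample)$shannon,
    simpson = diversity_indices(sample)$simpson,
    margalef = diversity_indices(sample)$margalef,
    evenness = diversity_indices(sample)$evenness,
    trait_log_rel_abund = {
      if (is.null(traits))
        stop_mindu("metric '", def$name, "' needs a trait table")
      trait_log_relative_abundance(sample, traits, def$trait_modality)
    }
  )
}

#' Modality name of the very-large-body-size trait
#' @return character scalar.
#' @export
very_large_modality <- function() "very_large_body_>40-80mm"

#' Default candidate-metric registry
#'
#' Ships the seasonally stable metrics of the MINDU development study
#' (Chironomidae/Oligochaeta/Hemiptera/Diptera group abundances and percent
#' compositions, evenness, and the log relative abundance of very large
#' body size), the four classical diversity measures, total abundance and
#' family richness. The registry is an ordinary list: add or drop
#' [metric_definition()]s to extend the candidate pool.
#'
#' @param taxonomy family-to-group table, default [default_taxonomy()].
#' @return list of `metric_definition`s.
#' @export
default_metric_registry <- function(taxonomy = default_taxonomy()) {
  gm <- function(...) group_members(c(...), taxonomy)
  list(
    metric_definition("Chi Abun", "abundance", "increase",
                      "group_abundance", taxa = gm("Chironomidae")),
    metric_definition("Oli Abun", "abundance", "increase",
                      "group_abundance", taxa = gm("Oligochaeta")),
    metric_definition("Chi+Oli Abun", "abundance", "increase",
                      "group_abundance",
                      taxa = gm("Chironomidae", "Oligochaeta")),
    metric_definition("Hem Abun", "abundance", "decrease",
                      "group_abundance", taxa = gm("Hemiptera")),
    metric_definition("Dip Abun", "abundance", "increase",
                      "group_abundance", taxa = gm("Diptera")),
    metric_definition("Mol+Dip Abun", "abundance", "increase",
                      "group_abundance", taxa = gm("Mollusca", "Diptera")),
    metric_definition("%Chi + Oli", "composition", "increase",
                      "percent_group",
                      taxa = gm("Chironomidae", "Oligochaeta")),
    metric_definition("%Oligochaeta", "composition", "increase",
                      "percent_group", taxa = gm("Oligochaeta")),
    metric_definition("%Diptera", "composition", "increase",
                      "percent_group", taxa = gm("Diptera")),
    metric_definition("%Hemiptera", "composition", "decrease",
                      "percent_group", taxa = gm("Hemiptera")),
    metric_definition("%Coleoptera", "composition", "decrease",
                      "percent_group", taxa = gm("Coleoptera")),
    metric_definition("%Col + Hem", "composition", "decrease",
                      "percent_group", taxa = gm("Coleoptera", "Hemiptera")),
    metric_definition("%Mol + Dip", "composition", "increase",
                      "percent_group", taxa = gm("Mollusca", "Diptera")),
    metric_definition("Taxa richness", "richness", "decrease", "richness"),
    metric_definition("Total Abun", "abundance", "increase",
                      "total_abundance"),
    metric_definition("Shannon", "diversity", "decrease", "shannon"),
    metric_definition("Simpson", "diversity", "decrease", "simpson"),
    metric_definition("Margalef", "diversity", "decrease", "margalef"),
    metric_definition("Even Ind", "diversity", "decrease", "evenness"),
    metric_definition("Log VeL", "trait", "decrease",
                      "trait_log_rel_abund",
                      trait_modality = very_large_modality())
  )
}

#' The five-metric registry of the packaged MINDU
#'
#' Hemiptera abundance, %Coleoptera + Hemiptera, %Chironomidae +
#' Oligochaeta, evenness, and log relative abundance of very large body
#' size — the metrics scored by the packaged index.
#'
#' @inheritParams default_metric_registry
#' @return list of five `metric_definition`s.
#' @export
mindu_registry <- function(taxonomy = default_taxonomy()) {
  keep <- c("Hem Abun", "%Col + Hem", "%Chi + Oli", "Even Ind", "Log VeL")
  reg <- default_metric_registry(taxonomy)
  reg[vapply(reg, function(d) d$name %in% keep, logical(1))]
}

#' Subset a registry by metric name
#'
#' @param registry list of `metric_definition`s.
#' @param names metric names to keep (order preserved).
#' @return list of `metric_definition`s.
#' @export
registry_subset <- function(registry, names) {
  reg_names <- vapply(registry, `[[`, character(1), "name")
  registry[match(names, reg_names, nomatch = 0L)]
}

#' Predicted pollution-response directions of a registry
#'
#' @param registry list of `metric_definition`s.
#' @return named character vector (`"increase"`/`"decrease"`).
#' @export
registry_directions <- function(registry) {
  stats::setNames(vapply(registry, `[[`, character(1), "direction"),
                  vapply(registry, `[[`, character(1), "name"))
}

#' Evaluate a metric registry over all sampling occasions
#'
#' One row per (station, date) composite sample; every registered metric is
#' evaluated on the occasion's taxon counts. Missing values (e.g. percent
#' composition of an empty sample) are propagated, never zero-filled.
#'
#' @param abundance an `abundance_table`.
#' @param registry list of `metric_definition`s
#'   (default [default_metric_registry()]).
#' @param traits a `trait_table`; required when the registry contains trait
#'   metrics.
#' @return a `metric_matrix`: data.frame with columns `station`, `date`,
#'   `season` followed by one numeric column per metric, and a
#'   `"directions"` attribute.
#' @examples
#' sim <- simulate_survey(simulation_config(seed = 1))
#' mm <- compute_metric_matrix(sim$abundance, traits = sim$traits)
#' head(mm[, 1:6])
#' @export
compute_metric_matrix <- function(abundance,
                                  registry = default_metric_registry(),
                                  traits = NULL) {
  if (!length(registry)) stop_mindu("metric registry is empty")
  ids <- vapply(registry, `[[`, character(1), "formula_id")
  bad <- setdiff(ids, METRIC_FORMULAE)
  if (length(bad))
    stop_mindu("unknown formula_id(s): ", paste(unique(bad), collapse = ", "))
  if (any(ids == "trait_log_rel_abund") && is.null(traits))
    stop_mindu("registry contains trait metrics but no trait table was given")

  ab <- as.data.frame(abundance)
  occ <- unique(ab[, c("station", "date", "season")])
  occ <- occ[order(occ$station, occ$date), , drop = FALSE]
  metric_names <- vapply(registry, `[[`, character(1), "name")

  vals <- matrix(NA_real_, nrow(occ), length(registry),
                 dimnames = list(NULL, metric_names))
  for (i in seq_len(nrow(occ))) {
    rows <- ab$station == occ$station[i] & ab$date == occ$date[i]
    sample <- stats::setNames(ab$count[rows], ab$taxon[rows])
    for (j in seq_along(registry))
      vals[i, j] <- as.numeric(eval_metric(registry[[j]], sample, traits))
  }
  out <- cbind(occ, as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "directions") <- registry_directions(registry)
  class(out) <- c("metric_matrix", "data.frame")
  out
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat(sprintf("metric_matrix: %d sampling occasions x %d metrics\n",
              nrow(x), ncol(x) - 3L))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Metric columns of a metric matrix
#'
#' @param mm a `metric_matrix`.
#' @return character vector of metric column names.
#' @export
metric_names <- function(mm) setdiff(names(mm), c("station", "date", "season"))
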