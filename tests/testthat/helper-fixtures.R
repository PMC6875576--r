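# in-code fixtures shared across tests

# published delineation fixture: PCA axis-1 coordinates of the 11 stations
fixture_coords <- function() {
  c(Wa = -19.811, An1 = -11.592, An2 = -9.4896, Ad = -8.3649,
    Ol = -5.7767, Et1 = -2.1216, Et2 = 10.287, Ob = 7.0565,
    Og1 = 22.909, Og2 = 17.97, Or = -1.0664)
}

fixture_printed_distances <- function() {
  c(Wa = 42.72, An1 = 34.501, An2 = 32.3986, Ad = 31.2739, Ol = 28.6857,
    Et1 = 25.0306, Et2 = 12.622, Ob = 15.8525, Og1 = 0, Og2 = 4.939,
    Or = 23.9754)
}

fixture_printed_percents <- function() {
  c(Wa = 100, An1 = 80.76077, An2 = 75.83942, Ad = 73.20669,
    Ol = 67.14817, Et1 = 58.59223, Et2 = 29.54588, Ob = 37.10791,
    Og1 = 0, Og2 = 11.56133, Or = 56.12219)
}

fixture_categories <- function() {
  c(Wa = 1L, An1 = 1L, An2 = 2L, Ad = 2L, Ol = 2L, Et1 = 2L,
    Et2 = 3L, Ob = 3L, Og1 = 3L, Og2 = 3L, Or = 3L)
}

# minimal well-formed abundance data.frame
fixture_abundance_df <- function() {
  data.frame(
    station = c("A", "A", "B"),
    date = c("2009-05-15", "2009-05-15", "2009-11-20"),
    taxon = c("Chironomidae", "Baetidae", "Naucoridae"),
    count = c(50L, 12L, 7L),
    stringsAsFactors = FALSE)
}

# 11-station x 9-variable physicochemistry fixture with a planted gradient
fixture_physchem_df <- function(seed = 42) {
  set.seed(seed)
  cat <- fixture_categories()
  mk <- function(lo, mid, hi, sd) {
    mu <- c(lo, mid, hi)[cat]
    round(mu * exp(rnorm(length(cat), 0, sd)), 3)
  }
  data.frame(
    station = names(cat),
    temperature = mk(26, 27.5, 29, 0.02),
    depth = mk(1.2, 1.0, 0.8, 0.05),
    flow_velocity = mk(0.45, 0.3, 0.15, 0.05),
    ec = mk(60, 180, 450, 0.05),
    ph = round(7 + rnorm(length(cat), 0, 0.1), 2),
    do = mk(7.5, 5, 2.8, 0.05),
    bod5 = mk(2, 6, 14, 0.05),
    nitrate = mk(0.6, 2.5, 7, 0.05),
    phosphate = mk(0.08, 0.35, 1.2, 0.05),
    stringsAsFactors = FALSE)
}

# number of printed decimal places of a value
nchar_dec <- function(x) {
  s <- sub("^[^.]*\\.?", "", format(x, scientific = FALSE))
  nchar(s)
}

# write a data.frame to a temp CSV and return the path
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# registry metrics with a planted response in the default synthetic survey
# (built on tolerant or sensitive taxa; Hemiptera/Coleoptera families are
# 'moderate' in the default pool and carry no planted signal)
planted_sensitive_metrics <- function() {
  c("Chi Abun", "Oli Abun", "Chi+Oli Abun", "Dip Abun", "Mol+Dip Abun",
    "%Chi + Oli", "%Oligochaeta", "%Diptera", "Even Ind", "Shannon",
    "Simpson", "Log VeL")
}

mindu_metric_names <- function() {
  c("Hem Abun", "%Col + Hem", "%Chi + Oli", "Even Ind", "Log VeL")
}
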