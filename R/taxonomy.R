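# family-level taxonomic groups used by group metrics

#' Default family-to-group membership table
#'
#' Maps common Afrotropical freshwater macroinvertebrate families to the
#' higher groups used by the packaged metrics (Diptera, Oligochaeta,
#' Hemiptera, Coleoptera, Mollusca, Ephemeroptera, Trichoptera, Odonata,
#' Decapoda). Taxa are family-level free-text names; extend the table for
#' surveys recording families not listed here.
#'
#' @return data.frame with columns `taxon`, `group`.
#' @export
default_taxonomy <- function() {
  g <- list(
    Diptera = c("Chironomidae", "Culicidae", "Psychodidae", "Simuliidae",
                "Syrphidae", "Tipulidae", "Ceratopogonidae"),
    Oligochaeta = c("Naididae", "Tubificidae", "Lumbriculidae"),
    Hemiptera = c("Naucoridae", "Belostomatidae", "Notonectidae",
                  "Corixidae", "Gerridae", "Nepidae", "Veliidae"),
    Coleoptera = c("Dytiscidae", "Gyrinidae", "Elmidae", "Hydrophilidae",
                   "Haliplidae"),
    Mollusca = c("Physidae", "Planorbidae", "Thiaridae", "Bithyniidae",
                 "Unionidae", "Ampullariidae"),
    Ephemeroptera = c("Baetidae", "Caenidae", "Heptageniidae",
                      "Leptophlebiidae"),
    Trichoptera = c("Hydropsychidae", "Leptoceridae", "Philopotamidae"),
    Odonata = c("Libellulidae", "Gomphidae", "Coenagrionidae", "Aeshnidae"),
    Decapoda = c("Atyidae", "Palaemonidae")
  )
  data.frame(taxon = unlist(g, use.names = FALSE),
             group = rep(names(g), lengths(g)),
             stringsAsFactors = FALSE)
}

#' Resolve group names to member families
#'
#' A group name expands to all families mapped to it in `taxonomy`; a name
#' with no group entry is treated as a family-level taxon and kept as-is,
#' so mixed lists such as `c("Chironomidae", "Oligochaeta")` work.
#'
#' @param groups character vector of group and/or family names.
#' @param taxonomy data.frame with columns `taxon`, `group`
#'   (default [default_taxonomy()]).
#' @return character vector of family names.
#' @export
group_members <- function(groups, taxonomy = default_taxonomy()) {
  out <- unlist(lapply(groups, function(g) {
    hit <- taxonomy$taxon[taxonomy$group == g]
    if (length(hit)) hit else g
  }))
  unique(out)
}
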