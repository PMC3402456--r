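#' Build a disease-class map
#'
#' Facts name specific diseases (`gastric_cancer`,
#' `acute_lymphoblastic_leukemia`) while the inference goal is a disease
#' class (`cancer`).  A disease-class map collects a class into which
#' diseases are folded: either by explicit membership, or by
#' case-insensitive substring patterns applied to the disease atom.
#' Explicit membership takes precedence over patterns; mapping is
#' deterministic for a fixed pattern list.
#'
#' @param target_class Disease-class identifier.
#' @param members Character vector of diseases explicitly in the class.
#' @param patterns Ordered character vector of substring patterns.  The
#'   default lexicon covers the common oncology nomenclature.
#' @return A `moa_disease_map` object.
#' @examples
#' m <- disease_class_map()
#' map_disease_class(c("gastric_cancer", "depression"), m)
#' @export
disease_class_map <- function(target_class = "cancer",
                              members = character(),
                              patterns = c("cancer", "carcinoma", "leukemia",
                                           "lymphoma", "tumor", "tumour",
                                           "melanoma", "sarcoma", "glioma")) {
  structure(
    list(
      target_class = as.character(target_class),
      members = unique(normalize_atom(members)),
      patterns = tolower(as.character(patterns))
    ),
    class = "moa_disease_map"
  )
}

#' Map diseases into a disease class
#'
#' @param disease Character vector of disease identifiers.
#' @param map A [disease_class_map()].
#' @return Character vector: the map's `target_class` where the disease
#'   is an explicit member or matches any pattern, `NA` otherwise.
#' @export
map_disease_class <- function(disease, map) {
  disease <- tolower(as.character(disease))
  hit <- disease %in% map$members
  for (p in map$patterns) {
    hit <- hit | str_detect(disease, fixed(p))
  }
  ifelse(hit, map$target_class, NA_character_)
}

#' Read a disease-class map from a YAML/JSON config
#'
#' The config has keys `target_class`, `members`, `patterns`; absent
#' keys fall back to the [disease_class_map()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `moa_disease_map` object.
#' @export
read_disease_map <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list(
    target_class = cfg$target_class %||% "cancer",
    members = as.character(cfg$members %||% character())
  )
  if (!is.null(cfg$patterns)) args$patterns <- as.character(cfg$patterns)
  do.call(disease_class_map, args)
}

#' @export
print.moa_disease_map <- function(x, ...) {
  cat(sprintf("<moa_disease_map> class '%s': %d explicit member(s), %d pattern(s)\n",
              x$target_class, length(x$members), length(x$patterns)))
  invisible(x)
}
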