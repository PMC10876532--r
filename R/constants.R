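#' Names of the 15 modeled PM2.5 constituents
#'
#' Chemical constituents of fine particulate matter used throughout the
#' package, in canonical column order: elemental carbon (ec), ammonium
#' (nh4), nitrate (no3), organic carbon (oc), sulfate (so4), bromine (br),
#' calcium (ca), copper (cu), iron (fe), potassium (k), nickel (ni),
#' lead (pb), silicon (si), vanadium (v), zinc (zn).
#'
#' @return Character vector of length 15 (lower-case column names).
#' @export
pm_constituents <- function() {
  c("ec", "nh4", "no3", "oc", "so4", "br", "ca", "cu", "fe",
    "k", "ni", "pb", "si", "v", "zn")
}

#' Outcome categories for non-respiratory infection admissions
#'
#' @return Character vector: total non-respiratory infections plus the
#'   four subtypes (central nervous system, intestinal, urinary tract,
#'   septicemia).
#' @export
pm_outcomes <- function() {
  c("non_respiratory", "cns", "intestinal", "urinary", "septicemia")
}

#' Tracer rules mapping dominant constituents to emission sources
#'
#' Receptor-modelling tracer table: each candidate source is identified by
#' the constituents diagnostic of it (Ni/V for residual-oil combustion,
#' sulfate and ammonium for coal burning, Cu/Fe/Zn/EC for traffic
#' (brake/tire wear and exhaust), Si/Ca for crustal soil, K/OC for biomass
#' burning, NO3/NH4 for regionally transported nitrate). The table is an
#' ordinary named list and can be edited before passing to
#' [label_sources()].
#'
#' @return Named list; names are source labels, values character vectors
#'   of tracer constituents.
#' @export
pm_tracer_rules <- function() {
  list(
    "oil combustion"                 = c("ni", "v"),
    "coal burning"                   = c("so4", "nh4"),
    "traffic"                        = c("cu", "fe", "zn", "ec"),
    "soil"                           = c("si", "ca"),
    "biomass burning"                = c("k", "oc"),
    "regionally transported nitrate" = c("no3", "nh4")
  )
}

# Internal: count column name for an outcome category.
count_col <- function(outcome) {
  if (outcome %in% pm_outcomes()) paste0("count_", outcome) else outcome
}
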