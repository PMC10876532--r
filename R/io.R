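#' Map CCS / CCSR diagnosis groups to infection outcome categories
#'
#' Implements the diagnosis-group definitions of the outcome categories.
#' Under the ICD-9 CCS scheme, non-respiratory infection comprises groups
#' 2-9, 76-78, 90, 135, 159, 197, 201 and 248; CNS infection is groups
#' 76-78, intestinal infection group 135, urinary tract infection group
#' 159 and septicemia group 2. Under the ICD-10 CCSR scheme the
#' non-respiratory set is INF002-004, INF006-011, MUS001-002, MUS027,
#' NVS001-003, GEN001, SKN001 and DIG001, excluding any admission whose
#' groups intersect the respiratory set RSP002-006; CNS is NVS001-003,
#' intestinal DIG001, urinary GEN001 and septicemia INF002 (subtype
#' membership is not affected by the respiratory exclusion).
#'
#' @param scheme "CCS" (ICD-9 groups, numeric) or "CCSR" (ICD-10 groups,
#'   character such as "INF002").
#' @param groups A single group id or the set of group ids attached to
#'   one admission record.
#' @return Character vector of outcome categories the record belongs to
#'   (possibly empty).
#' @export
map_outcome_groups <- function(scheme, groups) {
  scheme <- toupper(scheme)
  if (scheme == "CCS") {
    groups <- as.integer(groups)
    nonresp <- c(2:9, 76:78, 90, 135, 159, 197, 201, 248)
    defs <- list(non_respiratory = nonresp, cns = 76:78, intestinal = 135,
                 urinary = 159, septicemia = 2)
    return(names(defs)[vapply(defs, function(g) any(groups %in% g),
                              logical(1))])
  }
  if (scheme == "CCSR") {
    groups <- toupper(as.character(groups))
    inf <- sprintf("INF%03d", c(2:4, 6:11))
    nonresp <- c(inf, "MUS001", "MUS002", "MUS027",
                 sprintf("NVS%03d", 1:3), "GEN001", "SKN001", "DIG001")
    rsp <- sprintf("RSP%03d", 2:6)
    defs <- list(non_respiratory = nonresp,
                 cns = sprintf("NVS%03d", 1:3), intestinal = "DIG001",
                 urinary = "GEN001", septicemia = "INF002")
    hit <- names(defs)[vapply(defs, function(g) any(groups %in% g),
                              logical(1))]
    if (any(groups %in% rsp)) hit <- setdiff(hit, "non_respiratory")
    return(hit)
  }
  stopf("unknown scheme '%s' (use CCS or CCSR)", scheme)
}

# Required columns of a panel CSV.
panel_schema <- function() {
  c("zip", "year", "beneficiaries", "pm25", pm_constituents())
}

#' Read and validate a ZIP-code-year panel CSV
#'
#' Reads a long-format panel, checks the documented schema (zip, year,
#' beneficiaries, pm25, the 15 constituent columns and at least one
#' `count_*` column; any numeric covariate columns are carried along),
#' verifies numeric types and non-negative concentrations, checks that
#' (zip, year) pairs are unique, and drops rows with 100 or fewer
#' beneficiaries (the panel includes only ZIP codes with more than 100
#' beneficiaries), reporting the number removed.
#'
#' @param path CSV file path.
#' @param covariates Optional character vector naming covariate columns
#'   to record in the panel's `covariates` attribute (default: all
#'   `z*` columns present).
#' @return Validated panel data frame.
#' @export
read_panel <- function(path, covariates = NULL) {
  if (!file.exists(path)) stopf("panel file '%s' does not exist", path)
  panel <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stopf("empty or malformed panel file: %s",
                                              conditionMessage(e)))
  if (nrow(panel) == 0 || ncol(panel) < 2) stopf("empty or malformed panel file")
  missing <- setdiff(panel_schema(), names(panel))
  if (length(missing))
    stopf("panel is missing required column(s): %s",
          paste(missing, collapse = ", "))
  counts <- grep("^count_", names(panel), value = TRUE)
  if (!length(counts)) stopf("panel has no count_* outcome column")
  for (cl in c("year", "beneficiaries", "pm25", pm_constituents(), counts)) {
    if (!is.numeric(panel[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(panel[[cl]]))))[1]
      stopf("non-numeric value in column '%s' (row %s)", cl,
            ifelse(is.na(bad), "?", bad))
    }
  }
  if (any(panel[, pm_constituents()] < 0))
    stopf("negative constituent concentration found")
  if (anyDuplicated(panel[, c("zip", "year")]))
    stopf("duplicate (zip, year) pairs in panel")
  drop <- panel$beneficiaries <= 100
  if (any(drop))
    message(sprintf("read_panel: dropped %d row(s) with <= 100 beneficiaries",
                    sum(drop)))
  panel <- panel[!drop, , drop = FALSE]
  if (nrow(panel) == 0) stopf("no rows remain after the beneficiary filter")
  rownames(panel) <- NULL
  if (is.null(covariates))
    covariates <- grep("^z[0-9]+$", names(panel), value = TRUE)
  attr(panel, "covariates") <- covariates
  panel
}

#' Write a panel to CSV
#'
#' @param panel Panel data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
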