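#' Canonicalize a concentration to micrograms per cubic metre
#'
#' All concentrations inside the package live in ug/m3. Chemical analyses
#' commonly report mg/m3; inhalation unit risks (IUR) are expressed per
#' (ug/m3), so ug/m3 is the one unit in which hazard quotients and cancer
#' risks can be formed without further conversion. Conversion happens exactly
#' once, at ingest.
#'
#' @param value numeric vector of non-negative concentrations.
#' @param unit character scalar or vector, one of `"mg/m3"` or `"ug/m3"`
#'   (the spellings `"µg/m3"`, `"mg/m^3"` etc. are accepted).
#' @return numeric vector in ug/m3.
#' @examples
#' canonicalize_concentration(1, "mg/m3")    # 1000
#' canonicalize_concentration(13.79, "ug/m3") # unchanged
#' @export
canonicalize_concentration <- function(value, unit) {
  stopifnot(is.numeric(value))
  if (any(!is.na(value) & value < 0)) {
    stop("concentrations must be non-negative")
  }
  unit <- normalize_unit(unit)
  factor <- ifelse(unit == "mg/m3", 1000, 1)
  value * factor
}

# Map unit spellings onto the two canonical tokens; unknown units are an error
# naming the offending string so bad CSV rows are easy to locate.
normalize_unit <- function(unit) {
  u <- tolower(gsub("\\s|\\^|³", "", as.character(unit)))
  u[u %in% c("mg/m3", "mg/m")] <- "mg/m3"
  u[u %in% c("ug/m3", "ug/m", "µg/m3", "µg/m", "μg/m3", "μg/m")] <- "ug/m3"
  bad <- setdiff(unique(u), c("mg/m3", "ug/m3"))
  if (length(bad) > 0) {
    stop("unknown concentration unit: ", paste(sQuote(bad), collapse = ", "),
         " (expected mg/m3 or ug/m3)")
  }
  u
}
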