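#' Congener panel for vehicle-dust flame retardants
#'
#' Builds the default analyte panel: eight organophosphate esters (OPEs) and
#' eight polybrominated diphenyl ethers (PBDEs) routinely reported in vehicle
#' dust. Each congener carries its method detection limit (MDL, ng g^-1), an
#' oral chronic reference dose (RfD, mg kg^-1 day^-1) where one is available,
#' an oral cancer slope factor (SF, (mg kg^-1 day^-1)^-1) where one is
#' available, and a congener-specific dermal uptake fraction.
#'
#' RfDs are available for six OPEs (TnBP, TBOEP, TCEP, TCiPP, TDCiPP, TPhP)
#' and four PBDEs (BDE-47, BDE-99, BDE-153, BDE-209); slope factors for five
#' congeners (TnBP, TEHP, TCEP, TDCiPP, BDE-209). The shipped RfD/SF values
#' are documented defaults in the range of US EPA IRIS/PPRTV assessments and
#' should be re-verified against the current IRIS record before regulatory
#' use. Dermal uptake fractions are calibrated so that the default exposure
#' parameter sets reproduce the package's reference average-daily-dose table
#' (see [default_exposure_params()]).
#'
#' @param congeners optional character vector to subset the panel.
#' @return A `data.frame` with columns `name`, `family` (`"OPE"`/`"PBDE"`),
#'   `mdl` (ng g^-1), `rfd`, `sf` (NA where not assessed), `dermal_abs`.
#' @export
#' @examples
#' default_panel()[, c("name", "family", "mdl")]
default_panel <- function(congeners = NULL) {
  p <- data.frame(
    name = c("TnBP", "TBOEP", "TEHP", "TCEP", "TCiPP", "TDCiPP", "TPhP",
             "EHDPP", "BDE-28", "BDE-47", "BDE-99", "BDE-100", "BDE-153",
             "BDE-154", "BDE-183", "BDE-209"),
    family = rep(c("OPE", "PBDE"), each = 8L),
    mdl = c(5.00e-2, 7.40e-2, 1.20e-1, 7.20e-2, 1.00e-1, 6.70e-2, 2.30e-1,
            7.80e-2, 3.00e-2, 3.00e-3, 3.00e-4, 3.00e-3, 1.00e-3, 3.00e-3,
            1.00e-2, 9.39e-2),
    rfd = c(0.024, 0.015, NA, 0.022, 0.08, 0.015, 0.07, NA,
            NA, 1e-4, 1e-4, NA, 2e-4, NA, NA, 7e-3),
    sf = c(0.009, NA, 0.0032, 0.02, NA, 0.07, NA, NA,
           NA, NA, NA, NA, NA, NA, NA, 7e-4),
    # calibrated dermal uptake fractions (unitless, see exposure docs)
    dermal_abs = c(0.019397, 0.021205, 0.021189, 0.027444, 0.026545,
                   0.012293, 0.021194, 0.021290, 0.009726, 0.009695,
                   0.009684, 0.009692, 0.009728, 0.009683, 0.009710,
                   0.009641),
    stringsAsFactors = FALSE
  )
  if (!is.null(congeners)) {
    unknown <- setdiff(congeners, p$name)
    if (length(unknown))
      stop("unknown congener(s): ", paste(unknown, collapse = ", "))
    p <- p[match(congeners, p$name), , drop = FALSE]
    rownames(p) <- NULL
  }
  validate_panel(p)
  p
}

validate_panel <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("name", "family", "mdl") %in% names(p)))
  if (anyDuplicated(p$name))
    stop("congener names must be unique within a panel")
  if (any(!is.finite(p$mdl)) || any(p$mdl <= 0))
    stop("every MDL must be a positive number")
  if (!all(p$family %in% c("OPE", "PBDE")))
    stop("family must be 'OPE' or 'PBDE'")
  if ("rfd" %in% names(p) && any(!is.na(p$rfd) & p$rfd <= 0))
    stop("RfD values must be positive where present")
  if ("sf" %in% names(p) && any(!is.na(p$sf) & p$sf < 0))
    stop("slope factors must be nonnegative where present")
  invisible(p)
}

#' Reference concentration summary for vehicle dust
#'
#' Reads the packaged per-congener summary of literature-compiled vehicle-dust
#' concentrations (mean, range, SD, MDL; ng g^-1) used throughout the
#' package's worked examples and calibration.
#'
#' @return data.frame with columns `compound`, `family`, `mean_ng_g`,
#'   `min_ng_g`, `max_ng_g`, `sd_ng_g`, `mdl_ng_g`.
#' @export
reference_concentrations <- function() {
  read.csv(system.file("extdata", "table1_congeners.csv",
                       package = "dustrisk"),
           stringsAsFactors = FALSE, check.names = TRUE)
}

#' Reference average-daily-dose table
#'
#' Reads the packaged per-congener average daily doses (mg kg^-1 day^-1) via
#' ingestion, inhalation and dermal contact for occupational and
#' nonoccupational adults, and the accompanying family-total rows.
#'
#' Note: in the per-congener table the nonoccupational dermal column for the
#' PBDE congeners duplicates the occupational values and is inconsistent with
#' the family-total row; the family totals are the authoritative values for
#' that column.
#'
#' @return list with elements `add` (per-congener table) and `sums`
#'   (family-total rows).
#' @export
reference_add_table <- function() {
  list(
    add = read.csv(system.file("extdata", "table2_add.csv",
                               package = "dustrisk"),
                   stringsAsFactors = FALSE),
    sums = read.csv(system.file("extdata", "table2_sums.csv",
                                package = "dustrisk"),
                    stringsAsFactors = FALSE)
  )
}
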