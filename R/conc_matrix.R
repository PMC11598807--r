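#' Concentration matrix with below-MDL censoring
#'
#' Container for a samples-by-congeners table of dust concentrations
#' (ng g^-1) together with a logical censoring mask marking cells reported
#' below the method detection limit (MDL) and the congener panel (which
#' carries the MDLs).
#'
#' @param values numeric matrix, n_samples x n_congeners, nonnegative.
#' @param censored logical matrix of the same shape; `TRUE` where the cell
#'   was reported below the MDL.
#' @param panel congener panel `data.frame` (see [default_panel()]); its rows
#'   must match the columns of `values` by name.
#' @param sample_ids optional character vector of sample identifiers.
#' @return an object of class `conc_matrix`.
#' @export
conc_matrix <- function(values, censored = NULL, panel = default_panel(),
                        sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- panel$name[seq_len(ncol(values))]
  unknown <- setdiff(colnames(values), panel$name)
  if (length(unknown))
    stop("unknown congener column(s): ", paste(unknown, collapse = ", "))
  panel <- panel[match(colnames(values), panel$name), , drop = FALSE]
  rownames(panel) <- NULL
  if (any(!is.finite(values)))
    stop("concentration values must be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative concentration at row %d, column '%s'",
                 bad[1L], colnames(values)[bad[2L]]))
  }
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(values), ncol(values))
  censored <- as.matrix(censored)
  if (!identical(dim(censored), dim(values)))
    stop("censoring mask shape does not match values")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("S", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match number of rows")
  structure(
    list(values = values, censored = censored, panel = panel,
         sample_ids = as.character(sample_ids)),
    class = "conc_matrix"
  )
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat(sprintf("conc_matrix: %d samples x %d congeners (%d cells below MDL)\n",
              nrow(x$values), ncol(x$values), sum(x$censored)))
  invisible(x)
}

#' @export
dim.conc_matrix <- function(x) dim(x$values)

#' Read a concentration table from CSV
#'
#' Parses a CSV with one header row of congener names and one row per sample.
#' Cells are either nonnegative numbers (ng g^-1) or a below-MDL token
#' (default `"<MDL"`), which sets the censoring flag; no value substitution
#' is applied at read time (see [substitute_below_mdl()]). A value exactly
#' equal to the MDL is treated as observed, not censored.
#'
#' @param path CSV file path. First column may be a sample identifier column
#'   named `sample_id`.
#' @param panel congener panel providing MDLs.
#' @param mdl_token string marking a below-MDL cell.
#' @return a [conc_matrix()].
#' @export
read_concentration_table <- function(path, panel = default_panel(),
                                     mdl_token = "<MDL") {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (nrow(raw) == 0L)
    stop("empty concentration table: ", path)
  sample_ids <- NULL
  if (tolower(names(raw)[1L]) %in% c("sample_id", "sample", "id")) {
    sample_ids <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  unknown <- setdiff(names(raw), panel$name)
  if (length(unknown))
    stop("unknown congener column(s): ", paste(unknown, collapse = ", "))
  cens <- vals <- matrix(NA_real_, nrow(raw), ncol(raw),
                         dimnames = list(NULL, names(raw)))
  cens[] <- FALSE
  for (j in seq_along(raw)) {
    cell <- trimws(raw[[j]])
    below <- cell == mdl_token
    num <- suppressWarnings(as.numeric(cell))
    if (any(!below & is.na(num)))
      stop(sprintf("non-numeric cell in column '%s': '%s'", names(raw)[j],
                   cell[which(!below & is.na(num))[1L]]))
    if (any(!below & num < 0, na.rm = TRUE))
      stop(sprintf("negative value at row %d, column '%s'",
                   which(!below & num < 0)[1L], names(raw)[j]))
    num[below] <- 0
    vals[, j] <- num
    cens[, j] <- below
  }
  conc_matrix(vals, cens == 1, panel, sample_ids)
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentration_table()]: censored cells are written as the
#' below-MDL token so that a read/write round trip reproduces both values and
#' mask exactly.
#'
#' @param m a [conc_matrix()].
#' @param path output CSV path.
#' @param mdl_token token to write for censored cells.
#' @export
write_concentration_table <- function(m, path, mdl_token = "<MDL") {
  stopifnot(inherits(m, "conc_matrix"))
  out <- as.data.frame(matrix(format(m$values, digits = 17, trim = TRUE,
                                     scientific = TRUE),
                              nrow(m$values), ncol(m$values)))
  names(out) <- colnames(m$values)
  out[m$censored] <- mdl_token
  out <- cbind(sample_id = m$sample_ids, out)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute half the detection limit for censored cells
#'
#' Replaces every below-MDL cell with half its congener's MDL, the standard
#' convention for left-censored environmental concentrations. Uncensored
#' cells are untouched and the operation is idempotent (the mask is kept, so
#' applying it twice rewrites the same MDL/2 values).
#'
#' @param m a [conc_matrix()].
#' @return a `conc_matrix` with substituted values.
#' @export
substitute_below_mdl <- function(m) {
  stopifnot(inherits(m, "conc_matrix"))
  if (!any(m$censored)) return(m)
  mdl <- m$panel$mdl
  need <- colSums(m$censored) > 0
  if (any(need & (is.na(mdl) | mdl <= 0)))
    stop("missing or nonpositive MDL for censored congener(s): ",
         paste(m$panel$name[need & (is.na(mdl) | mdl <= 0)], collapse = ", "))
  half <- matrix(mdl / 2, nrow(m$values), ncol(m$values), byrow = TRUE)
  m$values[m$censored] <- half[m$censored]
  m
}

#' Per-congener summary statistics
#'
#' Mean, minimum, maximum and sample standard deviation (n-1 convention) per
#' congener, in ng g^-1. Intended to be called after
#' [substitute_below_mdl()]. With a single sample the SD is reported as 0
#' with a warning, so that single literature-mean rows can flow through the
#' exposure equations.
#'
#' @param m a [conc_matrix()].
#' @return data.frame with columns `congener`, `family`, `n`, `mean`, `min`,
#'   `max`, `sd`.
#' @export
summarize_concentrations <- function(m) {
  stopifnot(inherits(m, "conc_matrix"))
  n <- nrow(m$values)
  if (n == 0L) stop("no samples to summarize")
  if (n == 1L) {
    warning("single sample: standard deviation reported as 0")
    sds <- rep(0, ncol(m$values))
  } else {
    sds <- apply(m$values, 2L, sd)
  }
  data.frame(
    congener = colnames(m$values),
    family = m$panel$family,
    n = n,
    mean = colMeans(m$values),
    min = apply(m$values, 2L, min),
    max = apply(m$values, 2L, max),
    sd = sds,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
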