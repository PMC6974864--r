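#' Incomplete 2^3 capture-history table
#'
#' Container for the seven observed capture-history counts of a
#' three-list study: `n100`, `n010`, `n001`, `n110`, `n101`, `n011`,
#' `n111` (bit order A, B, C). The eighth cell, pattern 000, is
#' structurally unobservable and never stored here; it is estimated by
#' model projection (see [fit_crc()]).
#'
#' Counts may be real-valued: tables recovered from published rounded
#' estimates (see [recover_cells()]) carry decimals.
#'
#' @param n100,n010,n001,n110,n101,n011,n111 non-negative cell counts.
#' @return An object of class `incomplete_table`: a named numeric vector
#'   of the seven cells.
#' @examples
#' tab <- incomplete_table(n100 = 12, n010 = 8, n001 = 5,
#'                         n110 = 4, n101 = 3, n011 = 2, n111 = 1)
#' n_obs(tab)
#' @export
incomplete_table <- function(n100, n010, n001, n110, n101, n011, n111) {
  x <- c(n100 = n100, n010 = n010, n001 = n001,
         n110 = n110, n101 = n101, n011 = n011, n111 = n111)
  validate_incomplete_table(structure(x, class = "incomplete_table"))
}

#' Coerce a named vector or list to an incomplete table
#'
#' @param x a named numeric vector, list or single-row data frame with
#'   elements `n100` ... `n111`.
#' @return An `incomplete_table`.
#' @export
as_incomplete_table <- function(x) {
  if (inherits(x, "incomplete_table")) {
    return(validate_incomplete_table(x))
  }
  x <- unlist(x)
  missing_cells <- setdiff(.CELL_NAMES, names(x))
  if (length(missing_cells) > 0) {
    stop("missing cells: ", paste(missing_cells, collapse = ", "))
  }
  y <- as.numeric(x[.CELL_NAMES])
  names(y) <- .CELL_NAMES
  validate_incomplete_table(structure(y, class = "incomplete_table"))
}

validate_incomplete_table <- function(x) {
  if (length(x) != 7 || !identical(names(unclass(x)), .CELL_NAMES)) {
    stop("an incomplete_table has exactly the seven cells ",
         paste(.CELL_NAMES, collapse = ", "))
  }
  if (anyNA(x) || any(!is.finite(x))) stop("cell counts must be finite")
  if (any(x < 0)) stop("cell counts must be non-negative")
  x
}

#' Observed total of a capture-history table
#'
#' @param table an [incomplete_table()].
#' @return The sum of the seven observed cells.
#' @export
n_obs <- function(table) {
  sum(as_incomplete_table(table))
}

#' @export
print.incomplete_table <- function(x, ...) {
  cat("Incomplete 2^3 capture-history table (lists A, B, C)\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  cat("n_obs =", format(sum(x)), "\n")
  invisible(x)
}

#' Read or write an incomplete table as JSON
#'
#' Serialisation is a flat JSON object `{"n100": ..., ..., "n111": ...}`.
#'
#' @param table an [incomplete_table()].
#' @param path file path.
#' @return `write_incomplete_table()` returns `path` invisibly;
#'   `read_incomplete_table()` returns an `incomplete_table`.
#' @export
write_incomplete_table <- function(table, path) {
  table <- as_incomplete_table(table)
  jsonlite::write_json(as.list(setNames(as.numeric(table), names(unclass(table)))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_incomplete_table
#' @export
read_incomplete_table <- function(path) {
  as_incomplete_table(jsonlite::read_json(path, simplifyVector = TRUE))
}
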