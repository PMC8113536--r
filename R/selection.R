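# Per-year and all-years selection runs and the binary selection matrix.

#' Run per-year and all-years LSSGLASSO selection
#'
#' For each year with at least `min_rows` observations, fits the SIVCM on
#' that year's rows alone (the year coordinate of the index is constant
#' within a year and is dropped automatically, reducing the index to
#' longitude/latitude) and records the selected variable set; years with
#' too few or no responses are coded missing. A final `"allyrs"` column
#' records the selection over all rows pooled.
#'
#' @param design a `sivcm_design` (see [lag_align()]) whose rows are tagged
#'   by year in `design$meta$year`.
#' @param control a [sivcm_control()] list; `control$min_rows` gates the
#'   per-year fits.
#' @param years full set of years that should appear as columns; defaults
#'   to the years present in the design.
#' @return object of class `selection_matrix`: integer matrix (rows =
#'   variables, columns = years plus `"allyrs"`) with cells 1 (selected),
#'   0 (not selected), `NA` (missing response / too few rows), and
#'   attributes `n_per_column`, `fits` metadata.
#' @export
run_yearly_selection <- function(design, control = sivcm_control(),
                                 years = NULL) {
  stopifnot(inherits(design, "sivcm_design"))
  if (length(design$y) == 0) stop("empty design: no usable rows")
  vars <- colnames(design$X)[-1]
  yr <- design$meta$year
  if (is.null(years)) years <- sort(unique(yr))
  cols <- c(as.character(years), "allyrs")
  M <- matrix(NA_integer_, nrow = length(vars), ncol = length(cols),
              dimnames = list(vars, cols))
  ncol_n <- setNames(integer(length(cols)), cols)
  run_one <- function(idx) {
    tryCatch({
      fit <- lssglasso_fit(design$y[idx], design$X[idx, , drop = FALSE],
                           design$Z[idx, , drop = FALSE], control = control)
      as.integer(vars %in% fit$selected)
    }, error = function(e) {
      warning("selection fit skipped: ", conditionMessage(e))
      rep(NA_integer_, length(vars))
    })
  }
  any_usable <- FALSE
  for (ycol in as.character(years)) {
    idx <- which(yr == as.integer(ycol))
    ncol_n[ycol] <- length(idx)
    if (length(idx) >= control$min_rows) {
      M[, ycol] <- run_one(idx)
      any_usable <- any_usable || !anyNA(M[, ycol])
    }
  }
  ncol_n["allyrs"] <- length(design$y)
  if (length(design$y) >= control$min_rows) {
    M[, "allyrs"] <- run_one(seq_along(design$y))
    any_usable <- any_usable || !anyNA(M[, "allyrs"])
  }
  if (!any_usable) stop("no year (nor the pooled run) had enough rows to fit")
  structure(M,
            n_per_column = ncol_n,
            species = design$meta$species[1],
            response = design$meta$response[1],
            lag_years = design$lag_years,
            class = c("selection_matrix", "matrix"))
}

#' Write a selection matrix as a delimited text table
#'
#' One row per variable, one column per year plus the `"allyrs"` column;
#' cell legend `{1, 0, NA}`.
#'
#' @param sel a `selection_matrix`.
#' @param path output file path (TSV).
#' @return the path, invisibly.
#' @export
selection_matrix_to_table <- function(sel, path) {
  df <- data.frame(variable = rownames(sel),
                   unclass(sel)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a selection matrix written by [selection_matrix_to_table()]
#'
#' @param path TSV path.
#' @return integer matrix with variables as row names.
#' @export
read_selection_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$variable
  m
}

#' Plot a selection matrix as a heatmap
#'
#' Variables on the y axis, years (plus `"allyrs"`) on the x axis; selected
#' cells filled, missing-response columns hatched grey.
#'
#' @param x a `selection_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.selection_matrix <- function(x, ...) {
  m <- unclass(x)
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = c("grey90", "steelblue"), zlim = c(0, 1),
                  axes = FALSE, xlab = "year", ylab = "", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}
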