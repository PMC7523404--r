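# Delimited-text readers and writers. Input is comma-separated with a
# header row, '.' decimal, UTF-8. Output is tab-separated with '#'
# comment lines for metadata, so results paste cleanly into spreadsheets.

#' Read a long-format qPCR well table
#'
#' Expects a delimited file with header columns `sample_id`, `gene`,
#' `role`, `cq`, `efficiency` (one row per well; technical replicates
#' pre-collapsed). Records are validated strictly: non-positive cq,
#' efficiency at or below 1.2, or efficiency above 2.2 (almost always a
#' percentage that should have been converted as `E = 1 + pct/100`) are
#' errors naming the offending row.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A tibble of validated well records.
#' @export
read_well_table <- function(path, delim = ",") {
  df <- read_delim_checked(path, delim)
  missing_cols <- setdiff(well_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(df) == 0) abort(paste0("No records in ", path, "."))
  for (col in c("cq", "efficiency")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(paste0("Unparseable ", col, " value '", df[[col]][bad[1]],
                   "' at data row ", bad[1], " of ", path, "."))
    }
    df[[col]] <- v
  }
  validate_wells(as_tibble(df[well_columns]), strict = TRUE)
}

#' Read a two-column (x, y) table
#'
#' Reads the first two numeric columns after the header as ordered (x, y)
#' pairs. Blank or non-numeric cells are rejected with the row number;
#' fewer than 3 complete rows is an error.
#'
#' @inheritParams read_well_table
#' @return A tibble with columns `x`, `y`; the original column names are
#'   kept in attribute `"source_names"`.
#' @export
read_xy_table <- function(path, delim = ",") {
  df <- read_delim_checked(path, delim)
  if (ncol(df) < 2) abort(paste0(path, " needs at least two columns."))
  if (nrow(df) == 0) abort(paste0("No data rows in ", path, "."))
  out <- tibble(
    x = suppressWarnings(as.numeric(df[[1]])),
    y = suppressWarnings(as.numeric(df[[2]]))
  )
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad) > 0) {
    abort(paste0("Blank or non-numeric cell at data row ", bad[1],
                 " of ", path, "."))
  }
  if (nrow(out) < 3) {
    abort(paste0(path, " has fewer than 3 complete rows."))
  }
  attr(out, "source_names") <- names(df)[1:2]
  out
}

#' Read a grouped covariate table for ANCOVA
#'
#' Expects columns `group`, `x` (covariate) and `delta_cq`, or any three
#' columns in that order.
#'
#' @inheritParams read_well_table
#' @return A tibble with columns `group`, `x`, `delta_cq`.
#' @export
read_grouped_table <- function(path, delim = ",") {
  df <- read_delim_checked(path, delim)
  if (ncol(df) < 3) abort(paste0(path, " needs at least three columns."))
  if (!all(c("group", "x", "delta_cq") %in% names(df))) {
    names(df)[1:3] <- c("group", "x", "delta_cq")
  }
  out <- tibble(
    group = as.character(df$group),
    x = suppressWarnings(as.numeric(df$x)),
    delta_cq = suppressWarnings(as.numeric(df$delta_cq))
  )
  bad <- which(!is.finite(out$x) | !is.finite(out$delta_cq))
  if (length(bad) > 0) {
    abort(paste0("Blank or non-numeric cell at data row ", bad[1],
                 " of ", path, "."))
  }
  out
}

read_delim_checked <- function(path, delim) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- tryCatch(
    read.csv(path, sep = delim, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort(paste0("Cannot parse ", path, ": ",
                                     conditionMessage(e)))
  )
  as_tibble(df)
}

#' Write a curve, contrast table or fit report as annotated TSV
#'
#' Numeric columns are rounded to `precision` decimals (full precision is
#' kept internally; rounding happens only here, at report time). Metadata
#' - mode, slope, slope CI, confidence level, baseline - is written as
#' '#'-prefixed comment lines above the header so the file remains
#' machine-readable. Output has no timestamps, so identical inputs give
#' byte-identical files.
#'
#' @param x A `cb_curve`/`cb_response` tibble, `cb_contrasts` table, or
#'   any data frame.
#' @param path Output path, or `""` for standard output.
#' @param precision Decimal places for numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path = "", precision = 3) {
  meta <- character()
  if (inherits(x, "cb_curve") || inherits(x, "cb_response")) {
    b <- attr(x, "baseline")
    meta <- c(
      paste0("# mode: ", attr(x, "mode")),
      paste0("# m: ", format(attr(x, "m"))),
      paste0("# slope_ci: ", format(attr(x, "ci")[1]), " ",
             format(attr(x, "ci")[2])),
      paste0("# conf_level: ", format(attr(x, "conf_level"))),
      paste0("# x0: ", format(b$x0)),
      paste0("# baseline_policy: ", b$policy)
    )
    if (isTRUE(attr(x, "null_slope"))) {
      meta <- c(meta, paste0(
        "# note: slope not distinguishable from 0; no evidence the ",
        "input affects expression (R = 1 interpretation applies)"
      ))
    }
    if (!is.null(attr(x, "y0_hat"))) {
      meta <- c(meta, paste0("# y0_hat: ", format(attr(x, "y0_hat"))))
    }
  }
  if (inherits(x, "cb_contrasts")) {
    meta <- c(
      paste0("# conf_level: ", format(attr(x, "conf_level"))),
      paste0("# df: ", attr(x, "df"))
    )
  }
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = precision)
  con <- if (identical(path, "")) stdout() else file(path, open = "wt")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(meta, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read back an annotated TSV written by [write_result_tsv()]
#'
#' @param path File path.
#' @return A tibble; '#' metadata lines are parsed into attribute
#'   `"metadata"` (a named character vector).
#' @export
read_result_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- character()
  if (length(meta_lines) > 0) {
    kv <- sub("^#\\s*", "", meta_lines)
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- setNames(vals, keys)
  }
  df <- read.csv(text = lines[!grepl("^#", lines)], sep = "\t",
                 stringsAsFactors = FALSE)
  out <- as_tibble(df)
  attr(out, "metadata") <- meta
  out
}

#' One-row TSV report of a linear fit
#'
#' @param fit A [fit_ols()] result.
#' @inheritParams write_result_tsv
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path = "", precision = 6) {
  stopifnot(inherits(fit, "cb_fit"))
  df <- tibble(
    m = fit$m, b = fit$b, r2 = fit$r2, se_m = fit$se_m, df = fit$df,
    conf_level = fit$conf_level, ci_low = fit$ci[1], ci_high = fit$ci[2],
    p_slope = fit$p_slope, x_min = fit$x_min, x_max = fit$x_max,
    n = fit$n
  )
  write_result_tsv(df, path, precision = precision)
}
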