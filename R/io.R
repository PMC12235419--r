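#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `time_h,x,L`, preceded by `#`-prefixed provenance
#' comment lines (package version and all model parameters), numbers at 15
#' significant digits so a write/read round trip is lossless to 12
#' significant digits.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @param extra Optional named character vector of extra provenance lines
#'   (e.g. `c(seed = "7")`).
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data frame with columns `time_h`,
#'   `x`, `L`.
#' @export
write_trajectory_csv <- function(traj, path, extra = NULL) {
  p <- attr(traj, "params")
  prov <- c(sprintf("# biolumin %s trajectory",
                    as.character(utils::packageVersion("biolumin"))),
            if (!is.null(p))
              sprintf("# params: %s",
                      paste(sprintf("%s=%.15g", names(unclass(p)),
                                    unlist(unclass(p))), collapse = " ")),
            if (!is.null(extra))
              sprintf("# %s: %s", names(extra), extra))
  body <- sprintf("%s,%s,%s",
                  format_num(traj$time_h), format_num(traj$x),
                  format_num(traj$L))
  writeLines(c(prov, "time_h,x,L", body), path)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read luminescence time series as CSV
#'
#' Long format has columns `time_h,value`; wide format has `time_h`
#' followed by one column per replicate trace (`sample1`, `sample2`, ...).
#' `#`-prefixed comment lines carry provenance and are skipped on read.
#'
#' @param ts A [lum_series] (long) or list of them (wide).
#' @param path File path.
#' @param extra Optional named character vector of provenance lines.
#' @return Writers return `path` invisibly. `read_series_csv()` returns a
#'   list of [lum_series] (length 1 for long format), named by column.
#' @export
write_series_csv <- function(ts, path, extra = NULL) {
  prov <- c(sprintf("# biolumin %s series",
                    as.character(utils::packageVersion("biolumin"))),
            if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra))
  if (inherits(ts, "lum_series")) {
    body <- sprintf("%s,%s", format_num(ts$time_h), format_num(ts$value))
    writeLines(c(prov, "time_h,value", body), path)
  } else {
    stopifnot(is.list(ts), length(ts) >= 1L)
    t0 <- ts[[1L]]$time_h
    vals <- vapply(ts, function(s) s$value, numeric(length(t0)))
    hdr <- paste(c("time_h", sprintf("sample%d", seq_along(ts))),
                 collapse = ",")
    body <- apply(cbind(format_num(t0),
                        matrix(format_num(vals), nrow = length(t0))),
                  1L, paste, collapse = ",")
    writeLines(c(prov, hdr, body), path)
  }
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!identical(names(d)[1L], "time_h"))
    stop("first column must be 'time_h'", call. = FALSE)
  if (ncol(d) < 2L) stop("no value columns found", call. = FALSE)
  out <- lapply(names(d)[-1L], function(nm) lum_series(d$time_h, d[[nm]]))
  names(out) <- names(d)[-1L]
  out
}

#' Read a single-cell intensity CSV
#'
#' Expects a column `intensity_photons_per_min` (an optional `cell_id`
#' column is ignored).
#'
#' @param path File path.
#' @return A positive numeric vector of intensities.
#' @export
read_cell_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!"intensity_photons_per_min" %in% names(d))
    stop("expected a column 'intensity_photons_per_min'", call. = FALSE)
  d$intensity_photons_per_min
}

#' @rdname read_cell_csv
#' @param x Positive intensities.
#' @param extra Optional named character vector of provenance lines.
#' @export
write_cell_csv <- function(x, path, extra = NULL) {
  prov <- c(sprintf("# biolumin %s cell intensities",
                    as.character(utils::packageVersion("biolumin"))),
            if (!is.null(extra)) sprintf("# %s: %s", names(extra), extra))
  writeLines(c(prov, "cell_id,intensity_photons_per_min",
               sprintf("%d,%s", seq_along(x), format_num(x))), path)
  invisible(path)
}
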