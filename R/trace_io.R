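#' Read a time-series trace from a delimited text file
#'
#' Two dialects are accepted. The *header* dialect stores one `value` column
#' and declares acquisition parameters in comment lines of the form
#' `# sampling_rate_hz=<value>`, `# channel_role=<role>`, `# t0_s=<value>`,
#' plus arbitrary metadata as `# meta:<key>=<value>`. The *time-column*
#' dialect stores two columns (`time_s`, `value`); the sampling rate is then
#' inferred as the reciprocal of the median time step, and the time grid must
#' be uniform to within 1 ppm of that step.
#'
#' @param path Path to a CSV or TSV file.
#' @param format `"csv"` or `"tsv"`.
#' @return A [trace()].
#' @seealso [write_timeseries()]
#' @export
read_timeseries <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "synscale_io_error")
  }
  header <- parse_comment_header(path)
  sep <- if (format == "csv") "," else "\t"
  # base parser (strtod): bit-exact round trip of %.17g output
  dat <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "numeric")
  if (!is.null(header$sampling_rate_hz)) {
    if (!"value" %in% names(dat)) {
      abort("Header-dialect file must contain a `value` column.",
            class = "synscale_format_error")
    }
    rate <- as.numeric(header$sampling_rate_hz)
    t0 <- as.numeric(header$t0_s %||% 0)
    samples <- dat$value
  } else if (all(c("time_s", "value") %in% names(dat))) {
    dt <- diff(dat$time_s)
    step <- stats::median(dt)
    if (!is.finite(step) || step <= 0) {
      abort("Time column is not strictly increasing.",
            class = "synscale_format_error")
    }
    if (max(abs(dt - step)) > 1e-6 * step) {
      abort("Time grid is non-uniform (> 1 ppm deviation from median step).",
            class = "synscale_format_error")
    }
    rate <- 1 / step
    t0 <- dat$time_s[1]
    samples <- dat$value
  } else {
    abort(paste("Cannot determine sampling rate: no `# sampling_rate_hz=`",
                "header and no (time_s, value) columns."),
          class = "synscale_format_error")
  }
  role <- header$channel_role %||% "vclamp_current"
  trace(samples, sampling_rate = rate, channel_role = role, t0 = t0,
        metadata = header$metadata)
}

#' Write a trace to a delimited text file
#'
#' Samples are written at full double precision (`%.17g`) so a
#' write/read round trip is lossless. The header dialect (default) records
#' the sampling rate, channel role, start time, and all metadata as comment
#' lines; the time-column dialect writes an explicit uniform `time_s` column.
#'
#' @param x A [trace()].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @param layout `"header"` (single value column, commented header; compact)
#'   or `"time"` (explicit time column).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, format = c("csv", "tsv"),
                             layout = c("header", "time")) {
  stopifnot(is_trace(x))
  format <- match.arg(format)
  layout <- match.arg(layout)
  delim <- if (format == "csv") "," else "\t"
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(sprintf("Cannot write to %s", path),
                                            class = "synscale_io_error"))
  on.exit(close(con))
  meta_lines <- character(0)
  if (length(x$metadata)) {
    meta_lines <- sprintf("# meta:%s=%s", names(x$metadata),
                          vapply(x$metadata, as.character, character(1)))
  }
  if (layout == "header") {
    writeLines(c(sprintf("# sampling_rate_hz=%.17g", x$sampling_rate),
                 sprintf("# channel_role=%s", x$channel_role),
                 sprintf("# t0_s=%.17g", x$t0),
                 meta_lines,
                 "value",
                 sprintf("%.17g", x$samples)), con)
  } else {
    writeLines(c(sprintf("# channel_role=%s", x$channel_role),
                 meta_lines,
                 paste("time_s", "value", sep = delim),
                 paste(sprintf("%.17g", trace_times(x)),
                       sprintf("%.17g", x$samples), sep = delim)), con)
  }
  invisible(path)
}

parse_comment_header <- function(path) {
  out <- list(metadata = list())
  con <- file(path, open = "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    body <- trimws(sub("^#\\s*", "", line))
    if (!grepl("=", body, fixed = TRUE)) next
    key <- sub("=.*$", "", body)
    val <- sub("^[^=]*=", "", body)
    if (startsWith(key, "meta:")) {
      out$metadata[[sub("^meta:", "", key)]] <- utils::type.convert(val, as.is = TRUE)
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Write a table of records to CSV/TSV
#'
#' Thin wrapper around readr writers that additionally accepts a list of
#' homogeneous named records and refuses heterogeneous ones. Numeric fields
#' are written at full precision (readr's shortest round-trip
#' representation).
#'
#' @param rows A data frame, or a list of named lists with identical key
#'   sets.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) {
      abort("`rows` must be a data frame or list of named records.",
            class = "synscale_schema_error")
    }
    if (length(rows) == 0L) {
      abort("Empty record list without schema; pass a 0-row data frame instead.",
            class = "synscale_schema_error")
    }
    keys <- lapply(rows, function(r) sort(names(r)))
    if (length(unique(keys)) != 1L) {
      abort("Heterogeneous record keys; all records must share one key set.",
            class = "synscale_schema_error")
    }
    rows <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  if (format == "csv") readr::write_csv(rows, path, progress = FALSE)
  else readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path Input path.
#' @param format `"csv"` or `"tsv"`.
#' @return A tibble.
#' @export
read_table_file <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  delim <- if (format == "csv") "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a multi-sweep recording container
#'
#' Stores a set of neurons, each holding one or more sweeps, as a plain
#' directory tree: one subdirectory per neuron, one headered CSV per sweep
#' (`sweep_001.csv`, ...), with all per-sweep metadata (e.g. injected
#' current) carried in the file headers. The layout groups sweeps the way a
#' step protocol needs while remaining fully text-based.
#'
#' @param neurons Named list: `neuron_id -> list of traces`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_container <- function(neurons, path) {
  if (!is.list(neurons) || is.null(names(neurons))) {
    abort("`neurons` must be a named list of sweep lists.",
          class = "synscale_schema_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (id in names(neurons)) {
    nd <- file.path(path, paste0("neuron_", id))
    dir.create(nd, showWarnings = FALSE)
    sweeps <- neurons[[id]]
    for (k in seq_along(sweeps)) {
      write_timeseries(sweeps[[k]], file.path(nd, sprintf("sweep_%03d.csv", k)))
    }
  }
  invisible(path)
}

#' Read a multi-sweep recording container
#' @param path Directory written by [write_container()].
#' @return Named list `neuron_id -> list of traces`.
#' @export
read_container <- function(path) {
  if (!dir.exists(path)) {
    abort(sprintf("Container directory not found: %s", path),
          class = "synscale_io_error")
  }
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[grepl("neuron_", basename(dirs))]
  out <- list()
  for (nd in dirs) {
    id <- sub("^neuron_", "", basename(nd))
    files <- sort(list.files(nd, pattern = "^sweep_\\d+\\.csv$",
                             full.names = TRUE))
    out[[id]] <- lapply(files, read_timeseries)
  }
  out
}
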