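#' Read and write state-label trajectories
#'
#' Labels are stored one integer per line, one file per trajectory.
#'
#' @param labels Integer vector of state labels.
#' @param file Path.
#' @return `read_labels` returns an integer vector.
#' @export
write_labels <- function(labels, file) {
  writeLines(as.character(as.integer(labels)), file)
  invisible(file)
}

#' @rdname write_labels
#' @export
read_labels <- function(file) {
  as.integer(readLines(file))
}

#' Read and write feature/projection matrices as columnar text
#'
#' Whitespace-separated numeric columns, one frame per row, preceded by
#' comment lines (`#`) recording the producing stage and parameters and a
#' header line naming the features.
#'
#' @param x A [feature_trajectory()], `tica_projection`, or numeric matrix.
#' @param file Path.
#' @param comments Character vector of provenance lines written as
#'   `# `-prefixed headers.
#' @return `read_features` returns a numeric matrix with column names.
#' @export
write_features <- function(x, file, comments = character(0)) {
  vals <- if (inherits(x, "feature_trajectory")) x$values
          else .projection_values(x)
  con <- file(file, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  writeLines(paste(colnames(vals), collapse = " "), con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  lines <- readLines(file)
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\\s+")[[1]]
  vals <- utils::read.table(text = body[-1])
  vals <- as.matrix(vals)
  colnames(vals) <- header
  vals
}

#' Read and write count/transition matrices as labeled sparse triplets
#'
#' Triplet text format: comment header recording `n_states`, `lag` and
#' `dt`, then one `row col value` line per nonzero entry.
#'
#' @param cm A `count_matrix` (or plain matrix).
#' @param file Path.
#' @return `read_counts` returns a `count_matrix`.
#' @export
write_counts <- function(cm, file) {
  cm <- .as_count_matrix(cm)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("# n_states:", cm$n_states),
               paste("# lag:", cm$lag),
               paste("# dt:", cm$dt),
               paste("# ergodic_subset:",
                     paste(cm$ergodic_subset, collapse = ","))), con)
  nz <- which(cm$counts != 0, arr.ind = TRUE)
  writeLines(sprintf("%d %d %s", nz[, 1], nz[, 2],
                     format(cm$counts[nz], digits = 17)), con)
  invisible(file)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  n <- as.integer(getv("n_states"))
  counts <- matrix(0, n, n)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body)) {
    trip <- utils::read.table(text = body)
    counts[cbind(trip[, 1], trip[, 2])] <- trip[, 3]
  }
  out <- .as_count_matrix(counts, lag = as.integer(getv("lag")),
                          dt = as.numeric(getv("dt")))
  out$ergodic_subset <- as.integer(strsplit(getv("ergodic_subset"), ",")[[1]])
  out
}

#' Read a key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric; comma-separated numeric
#' lists become vectors.  Unknown keys are rejected against the documented
#' pipeline key set unless `keys = NULL`.
#'
#' @param file Path to the config file.
#' @param keys Allowed key names (default: the [run_pipeline()] keys);
#'   `NULL` disables checking.
#' @return Named list of settings.
#' @export
read_config <- function(file, keys = names(.default_config())) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  if (!is.null(keys)) {
    unknown <- setdiff(names(out), keys)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, file) {
  writeLines(vapply(names(config), function(k)
    paste0(k, ": ", paste(config[[k]], collapse = ",")), character(1)), file)
  invisible(file)
}
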