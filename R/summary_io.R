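# CHB-MIT-style seizure summary files and result tables.

#' Parse a CHB-MIT-style seizure summary file
#'
#' Parses the plain-text `chbXX-summary.txt` dialect: blocks introduced by
#' `File Name: <record>.edf`, followed by `Number of Seizures in File: N` and
#' `N` pairs of `Seizure [k ]Start Time: S seconds` / `Seizure [k ]End Time: E
#' seconds` lines. Records declaring zero seizures yield empty lists.
#'
#' @param path path to a summary text file.
#' @return named list: one element per declared record id (file name without
#'   the `.edf` suffix), each a list of [seizure_annotation()] objects.
#' @export
parse_summary <- function(path) {
  if (!file.exists(path)) {
    stop("parse_summary: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- NULL
  starts <- numeric(0)
  ends <- numeric(0)
  declared <- NA_integer_

  perr <- function(i, msg) {
    stop(sprintf("parse_summary: line %d: %s", i, msg), call. = FALSE)
  }
  flush_block <- function() {
    if (is.null(cur)) return()
    if (length(starts) != length(ends)) {
      stop("parse_summary: record ", cur,
           ": unmatched seizure start/end times", call. = FALSE)
    }
    if (!is.na(declared) && declared != length(starts)) {
      stop("parse_summary: record ", cur, ": declared ", declared,
           " seizures but found ", length(starts), call. = FALSE)
    }
    anns <- mapply(function(s, e) seizure_annotation(s, e),
                   starts, ends, SIMPLIFY = FALSE)
    out[[cur]] <<- anns
  }

  num_from <- function(line, i) {
    # the value sits after the colon ("Seizure 2 Start Time: 900 seconds")
    rhs <- sub("^[^:]*:", "", line)
    m <- regmatches(rhs, regexpr("-?[0-9.]+", rhs))
    if (length(m) != 1L) perr(i, "expected a number")
    as.numeric(m)
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (grepl("^File Name:", line)) {
      flush_block()
      cur <- sub("\\.edf$", "",
                 trimws(sub("^File Name:", "", line)), ignore.case = TRUE)
      if (!nzchar(cur)) perr(i, "empty file name")
      starts <- numeric(0); ends <- numeric(0); declared <- NA_integer_
    } else if (grepl("^Number of Seizures in File:", line)) {
      if (is.null(cur)) perr(i, "seizure count before any 'File Name:' line")
      declared <- as.integer(num_from(line, i))
      if (is.na(declared) || declared < 0L) perr(i, "bad seizure count")
    } else if (grepl("^Seizure( [0-9]+)? Start Time:", line)) {
      if (is.null(cur)) perr(i, "seizure time before any 'File Name:' line")
      v <- num_from(line, i)
      if (v < 0) perr(i, "negative seizure start time")
      starts <- c(starts, v)
    } else if (grepl("^Seizure( [0-9]+)? End Time:", line)) {
      if (is.null(cur)) perr(i, "seizure time before any 'File Name:' line")
      v <- num_from(line, i)
      if (length(ends) + 1L > length(starts)) {
        perr(i, "seizure end time without a preceding start time")
      }
      if (v <= starts[length(ends) + 1L]) {
        perr(i, "seizure end time not after its start time")
      }
      ends <- c(ends, v)
    }
    # other lines (channel lists, sampling rate banner, timestamps) ignored
  }
  flush_block()
  out
}

#' Write an evaluation result table
#'
#' Writes per-patient evaluation metrics as a CSV with a fixed column layout:
#' `patient, n_seizures, interictal_hours, sensitivity_pct, precision_pct,
#' fp_per_h, fp_pct, p_value`. Rates are printed with 2 decimals; rows are
#' ordered by patient id.
#'
#' @param result an `eval_result` from [compute_metrics()], or a data frame
#'   with the columns above.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  df <- if (inherits(result, "eval_result")) result$patients else result
  cols <- c("patient", "n_seizures", "interictal_hours", "sensitivity_pct",
            "precision_pct", "fp_per_h", "fp_pct", "p_value")
  if (nrow(df) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_real_
  df <- df[order(df$patient), cols]
  fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  lines <- c(paste(cols, collapse = ","),
             sprintf("%s,%d,%s,%s,%s,%s,%s,%s",
                     df$patient, as.integer(df$n_seizures),
                     fmt2(df$interictal_hours),
                     fmt2(df$sensitivity_pct), fmt2(df$precision_pct),
                     fmt2(df$fp_per_h), fmt2(df$fp_pct), fmt3(df$p_value)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path CSV path.
#' @return data frame of per-patient metrics.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
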