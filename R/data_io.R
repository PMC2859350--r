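#' Construct an agreement data set
#'
#' The universal input record for all model fitting: long-format measurements
#' of one continuous variable taken by exactly two devices, with optional
#' replicates and per-record covariates.
#'
#' @param data a data frame with columns `subject`, `device`, `replicate`,
#'   `value` plus any covariate columns.
#' @param device_order ordered pair of device labels; the mean difference
#'   reported by all fits is *second minus first*. Defaults to the sorted
#'   unique labels.
#' @return An object of class `"agreement_data"`: a list with the validated
#'   data frame (`$data`), `$devices`, `$n` (subjects), `$m` (replicates per
#'   subject-by-device cell when balanced, else `NA`), `$balanced`, and
#'   `$covariates` (names of extra columns).
#' @export
#' @examples
#' df <- data.frame(subject = c(1, 1, 1, 1), device = c("A", "A", "B", "B"),
#'                  replicate = c(1, 2, 1, 2), value = c(120, 122, 118, 121))
#' agreement_data(df)
agreement_data <- function(data, device_order = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("subject", "device", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$subject <- as.character(data$subject)
  data$device <- as.character(data$device)
  devices <- unique(data$device)
  if (length(devices) != 2L) {
    stop("exactly 2 device labels are required, found ", length(devices),
         ": ", paste(devices, collapse = ", "))
  }
  if (is.null(device_order)) {
    device_order <- sort(devices)
  } else {
    device_order <- as.character(device_order)
    if (!setequal(device_order, devices) || length(device_order) != 2L) {
      stop("`device_order` must be a permutation of the device labels (",
           paste(devices, collapse = ", "), ")")
    }
  }
  if (!is.numeric(data$value)) {
    bad <- suppressWarnings(is.na(as.numeric(as.character(data$value))))
    stop("non-numeric `value` in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    stop("non-finite `value` in row(s): ",
         paste(utils::head(which(!is.finite(data$value)), 5L),
               collapse = ", "),
         " (missing values are rejected, not imputed)")
  }
  data$replicate <- as.integer(data$replicate)
  if (anyNA(data$replicate) || any(data$replicate < 1L)) {
    stop("`replicate` must be a positive integer index (1..m)")
  }
  n <- length(unique(data$subject))
  counts <- table(data$subject, data$device)
  m_all <- unique(as.vector(counts))
  balanced <- length(m_all) == 1L && m_all[1L] >= 1L
  if (balanced) {
    dup <- any(duplicated(data[c("subject", "device", "replicate")]))
    if (dup) stop("duplicated (subject, device, replicate) record")
  }
  covariates <- setdiff(names(data), required)
  structure(list(
    data = data[c(required, covariates)],
    devices = device_order,
    n = n,
    m = if (balanced) as.integer(m_all[1L]) else NA_integer_,
    balanced = balanced,
    covariates = covariates
  ), class = "agreement_data")
}

#' @export
print.agreement_data <- function(x, ...) {
  cat(sprintf("Agreement data: %d subjects x 2 devices (%s, %s)%s\n",
              x$n, x$devices[1L], x$devices[2L],
              if (x$balanced) sprintf(", m = %d replicates (balanced)", x$m)
              else " (unbalanced)"))
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  cat(sprintf("  %d records; difference convention: %s - %s\n",
              nrow(x$data), x$devices[2L], x$devices[1L]))
  invisible(x)
}

#' Read long-format agreement data from CSV
#'
#' @param path path to a CSV file with a header row.
#' @param column_map named character vector mapping the canonical names
#'   `subject`, `device`, `replicate`, `value` to the file's column names.
#'   Unmapped names are taken as-is. Columns not mentioned and not canonical
#'   are carried along as covariates.
#' @param device_order see [agreement_data()].
#' @return An [agreement_data()] object.
#' @export
read_agreement_csv <- function(path,
                               column_map = c(subject = "subject",
                                              device = "device",
                                              replicate = "replicate",
                                              value = "value"),
                               device_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  defaults <- c(subject = "subject", device = "device",
                replicate = "replicate", value = "value")
  column_map <- c(column_map, defaults[setdiff(names(defaults),
                                               names(column_map))])
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols)) {
    stop("configured column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  # rename mapped columns to canonical names
  for (canon in names(column_map)) {
    names(df)[names(df) == column_map[[canon]]] <- canon
  }
  agreement_data(df, device_order = device_order)
}

#' Write agreement data to CSV
#'
#' Inverse of [read_agreement_csv()] with canonical column names:
#' `read_agreement_csv(write_agreement_csv(x, f))` reproduces `x`
#' field-for-field.
#'
#' @param x an [agreement_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(x, path) {
  stopifnot(inherits(x, "agreement_data"))
  write.csv(x$data, path, row.names = FALSE)
  invisible(path)
}

#' Reshape wide-format paired measurements to the long layout
#'
#' Convenience melt helper for the common wide layout of one row per subject
#' and one column per device-replicate combination.
#'
#' @param data a data frame, one row per subject.
#' @param subject name of the subject-identifier column.
#' @param device_cols named list: one entry per device label, each a character
#'   vector of value-column names in replicate order.
#' @param device_order see [agreement_data()].
#' @return An [agreement_data()] object.
#' @export
#' @examples
#' wide <- data.frame(id = 1:3, a1 = rnorm(3), a2 = rnorm(3),
#'                    b1 = rnorm(3), b2 = rnorm(3))
#' wide_to_long(wide, "id", list(A = c("a1", "a2"), B = c("b1", "b2")))
wide_to_long <- function(data, subject, device_cols, device_order = NULL) {
  stopifnot(is.data.frame(data), subject %in% names(data),
            is.list(device_cols), length(device_cols) == 2L,
            !is.null(names(device_cols)))
  pieces <- lapply(names(device_cols), function(dev) {
    cols <- device_cols[[dev]]
    stopifnot(all(cols %in% names(data)))
    do.call(rbind, lapply(seq_along(cols), function(l) {
      data.frame(subject = as.character(data[[subject]]),
                 device = dev, replicate = l,
                 value = data[[cols[l]]], stringsAsFactors = FALSE)
    }))
  })
  agreement_data(do.call(rbind, pieces), device_order = device_order)
}

#' Write a machine-readable report of results
#'
#' Serialises a non-empty collection of result objects (`tdi_result`,
#' `cp_result`, `comparator_result`, decision records, or summary data
#' frames) to JSON (full structure, full precision) or CSV (flattened, one
#' row per scalar result).
#'
#' @param results a single result object or a (optionally named) list of
#'   them.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @param meta optional named list of provenance fields (seed, settings,
#'   package version) stored alongside the results.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         meta = list()) {
  format <- match.arg(format)
  if (inherits(results, c("tdi_result", "cp_result", "comparator_result")) ||
      is.data.frame(results)) {
    results <- list(results)
  }
  if (!is.list(results) || length(results) == 0L) {
    stop("`results` must be a non-empty collection")
  }
  if (is.null(names(results))) {
    names(results) <- paste0("result_", seq_along(results))
  }
  payload <- lapply(results, function(r) {
    if (is.data.frame(r)) r else unclass(r)
  })
  if (format == "json") {
    out <- c(list(generated_by = paste0("tdiagree ",
                                        as.character(utils::packageVersion("tdiagree")))),
             if (length(meta)) list(meta = meta), list(results = payload))
    ok <- tryCatch({
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "string")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("could not write report to ", path, ": ",
                          conditionMessage(ok))
  } else {
    # uniform long layout so heterogeneous result objects can share a file
    rows <- do.call(rbind, lapply(names(payload), function(nm) {
      r <- payload[[nm]]
      if (is.data.frame(r)) {
        field <- as.vector(outer(seq_len(nrow(r)), names(r),
                                 function(i, cn) paste0(cn, "[", i, "]")))
        value <- unlist(lapply(r, function(col)
          vapply(col, function(v) format(v, digits = 17), character(1L))),
          use.names = FALSE)
      } else {
        flat <- r[vapply(r, function(v) is.atomic(v) && length(v) == 1L,
                         logical(1L))]
        field <- names(flat)
        value <- vapply(flat, function(v) format(v, digits = 17),
                        character(1L))
      }
      data.frame(result = nm, field = field, value = value,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
    ok <- tryCatch({ write.csv(rows, path, row.names = FALSE); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) stop("could not write report to ", path, ": ",
                          conditionMessage(ok))
  }
  invisible(path)
}
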