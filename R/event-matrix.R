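#' Construct an event matrix
#'
#' An `event_matrix` is the basic container for one flow cytometry sample:
#' a numeric matrix with one row per measured cell (event) and one column per
#' channel (scatter or fluorescence), plus a sample identifier. Values are on
#' whatever scale they were read in; transformations are applied explicitly
#' with [asinh_transform()].
#'
#' @param values numeric matrix, cells x channels. A data frame of numeric
#'   columns is accepted and coerced.
#' @param channel_names character vector of unique channel names; defaults to
#'   the column names of `values`.
#' @param sample_id single string identifying the sample.
#' @return An object of class `event_matrix`: the numeric matrix with
#'   attributes `sample_id`.
#' @examples
#' em <- event_matrix(matrix(rnorm(30), 10, 3),
#'                    channel_names = c("FS", "SS", "CD45"),
#'                    sample_id = "S1")
#' dim(em)
#' @export
event_matrix <- function(values, channel_names = colnames(values),
                         sample_id = "sample") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L) stop("an event matrix needs at least one cell")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(values)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(values))
    stop("length of 'channel_names' must equal the number of columns")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  bad <- !is.finite(values)
  if (any(bad)) {
    rows <- sort(unique(which(bad, arr.ind = TRUE)[, 1L]))
    stop("non-finite values in rows: ",
         paste(utils::head(rows, 10L), collapse = ", "),
         if (length(rows) > 10L) ", ..." else "")
  }
  colnames(values) <- channel_names
  structure(values, sample_id = as.character(sample_id)[1L],
            class = c("event_matrix", "matrix", "array"))
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix '%s': %d cells x %d channels\n",
              sample_id(x), nrow(x), ncol(x)))
  cat("channels:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Sample identifier of an event matrix or clustered sample
#' @param x an `event_matrix` or `clustered_sample`.
#' @return A single string.
#' @export
sample_id <- function(x) {
  id <- attr(x, "sample_id", exact = TRUE)
  if (is.null(id)) id <- x$sample_id
  id
}

# keep class + sample_id when subsetting rows
#' @export
`[.event_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, sample_id = sample_id(x),
                     class = c("event_matrix", "matrix", "array"))
  out
}

#' Read one sample from file
#'
#' Reads a cells x channels event matrix from either a headered CSV file
#' (first row channel names, comma separated, decimal point) or a list-mode
#' FCS 3.0/3.1 file.
#'
#' @param path file path.
#' @param format `"csv"` or `"fcs"`. Default guesses from the file extension.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return An [event_matrix()] with channels in file order, values
#'   untransformed.
#' @export
read_sample <- function(path, format = c("auto", "csv", "fcs"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fcs") {
    fcs <- read_fcs(path)
    return(event_matrix(fcs$data, fcs$channel_names, sample_id))
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("cannot parse CSV '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop("CSV '", path, "' contains no data rows")
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric value in '%s' at row %d, column '%s'",
                     path, bad[1L], names(df)[j]))
      df[[j]] <- v
    }
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    rows <- sort(unique(which(is.na(m), arr.ind = TRUE)[, 1L]))
    stop("missing values in '", path, "' at rows: ",
         paste(utils::head(rows, 10L), collapse = ", "))
  }
  event_matrix(m, names(df), sample_id)
}

#' Write one sample to CSV
#'
#' @param events an [event_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(events, path) {
  utils::write.csv(as.data.frame(unclass(events)), path, row.names = FALSE)
  invisible(path)
}

#' Cohort metadata table
#'
#' Associates sample identifiers with class labels and, optionally, the
#' subject / day / replicate structure of the cohort design.
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param class_label character vector of class labels, recycled if length 1.
#' @param subject,day,replicate optional character vectors.
#' @return A data frame of class `cohort_metadata`.
#' @export
cohort_metadata <- function(sample_id, class_label,
                            subject = NA_character_, day = NA_character_,
                            replicate = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  df <- data.frame(sample_id = sample_id,
                   class_label = as.character(class_label),
                   subject = as.character(subject),
                   day = as.character(day),
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_metadata", "data.frame")
  df
}
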