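#' Interval duration dataset
#'
#' An N x K table of interval durations (msec), one row per sequence
#' rendition and one column per interval, with optional interval-type labels
#' and per-trial metadata (for example day index and hour of day, used by
#' downstream circadian and drift analyses).
#'
#' All durations must be finite and K >= 3 is required (at least one
#' internal boundary flanked on both sides).  Positivity of durations is
#' enforced when reading tables from disk (see [read_intervals_table()]);
#' the constructor itself accepts mean-centred simulated data.  Fitting
#' additionally requires N >= K + 1 so that the data covariance is
#' generically full rank.
#'
#' @param durations numeric N x K matrix (or data.frame) of durations, msec.
#' @param labels optional character K-vector of interval types
#'   (\code{"syllable"}, \code{"gap_within"}, \code{"gap_between"}).
#' @param meta optional data.frame of per-trial metadata with N rows.
#' @param check_positive if TRUE, require all durations > 0.
#' @return an object of class \code{"interval_dataset"}.
#' @export
interval_dataset <- function(durations, labels = NULL, meta = NULL,
                             check_positive = TRUE) {
  Y <- as.matrix(durations)
  storage.mode(Y) <- "double"
  if (any(!is.finite(Y)))
    stop("durations must all be finite", call. = FALSE)
  if (ncol(Y) < 3L)
    stop("need K >= 3 intervals (at least one internal boundary flanked ",
         "on both sides); got K = ", ncol(Y), call. = FALSE)
  if (nrow(Y) < 1L) stop("need at least one trial", call. = FALSE)
  if (check_positive && any(Y <= 0))
    stop("durations must all be > 0", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(Y))
      stop("labels must have length K = ", ncol(Y), call. = FALSE)
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(Y))
      stop("meta must have one row per trial", call. = FALSE)
  }
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("interval_", seq_len(ncol(Y)))
  structure(list(durations = Y, labels = labels, meta = meta),
            class = "interval_dataset")
}

#' @export
print.interval_dataset <- function(x, ...) {
  cat("Interval dataset: N =", nrow(x$durations), "trials, K =",
      ncol(x$durations), "intervals\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = " "), "\n")
  if (!is.null(x$meta))
    cat("  metadata fields:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.interval_dataset <- function(x) dim(x$durations)

## Accept either an interval_dataset or a bare matrix wherever data go in
dataset_matrix <- function(data) {
  if (inherits(data, "interval_dataset")) return(data$durations)
  if (inherits(data, "interval_sim")) return(data$data$durations)
  Y <- as.matrix(data)
  if (!is.numeric(Y)) stop("data must be numeric", call. = FALSE)
  Y
}

#' Read an interval duration table from CSV/TSV
#'
#' Reads a delimited table with a header row of interval identifiers.
#' Columns whose names start with \code{"meta_"} are split off into
#' per-trial metadata.  Rows containing any missing, non-numeric or
#' non-positive duration are rejected with a row-indexed message.
#'
#' @param path path to a .csv or .tsv/.txt file.
#' @param labels optional: a character K-vector of interval-type labels, or
#'   the path of a sidecar JSON file holding one (an array of strings).
#' @param sep field separator; inferred from the file extension by default.
#' @return an [interval_dataset()].
#' @seealso [write_intervals_table()]
#' @export
read_intervals_table <- function(path, labels = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  is_meta <- grepl("^meta_", names(df))
  meta <- if (any(is_meta)) df[, is_meta, drop = FALSE] else NULL
  body <- df[, !is_meta, drop = FALSE]
  num <- lapply(body, function(col) suppressWarnings(as.numeric(col)))
  Y <- do.call(cbind, num)
  colnames(Y) <- names(body)
  if (ncol(Y) < 3L)
    stop("table has K = ", ncol(Y), " interval columns; need K >= 3",
         call. = FALSE)
  bad <- apply(Y, 1L, function(r) any(!is.finite(r) | r <= 0))
  if (any(bad)) {
    message("rejected ", sum(bad), " row(s) with missing/non-numeric/",
            "non-positive durations: rows ",
            paste(utils::head(which(bad), 20L), collapse = ", "),
            if (sum(bad) > 20L) " ..." else "")
    Y <- Y[!bad, , drop = FALSE]
    if (!is.null(meta)) meta <- meta[!bad, , drop = FALSE]
  }
  if (nrow(Y) == 0L) stop("no valid rows left after validation", call. = FALSE)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- as.character(jsonlite::fromJSON(labels))
  interval_dataset(Y, labels = labels, meta = meta)
}

#' Write an interval duration table to CSV/TSV
#'
#' Values are written in full precision so a write/read round trip preserves
#' them exactly.  Metadata columns are prefixed with \code{"meta_"};
#' interval labels, if present, go to a sidecar JSON file
#' \code{<path>.labels.json}.
#'
#' @param data an [interval_dataset()].
#' @param path output path (.csv or .tsv).
#' @return the path, invisibly.
#' @export
write_intervals_table <- function(data, path) {
  stopifnot(inherits(data, "interval_dataset"))
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(format(data$durations, digits = 17, trim = TRUE,
                             scientific = FALSE),
                      stringsAsFactors = FALSE)
  names(df) <- colnames(data$durations)
  if (!is.null(data$meta)) {
    meta <- data$meta
    names(meta) <- ifelse(grepl("^meta_", names(meta)), names(meta),
                          paste0("meta_", names(meta)))
    df <- cbind(df, meta)
  }
  write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = sep, row.names = FALSE, quote = FALSE))
  if (!is.null(data$labels))
    write_atomic(paste0(path, ".labels.json"), function(tmp)
      jsonlite::write_json(data$labels, tmp))
  invisible(path)
}

## write via a temporary file in the target directory, then rename
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
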