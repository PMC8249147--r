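## Core data types: a multichannel time-varying signal and an ordered dataset
## of signals with a fixed class alphabet. Records may differ in length (the
## warping distance handles unequal lengths); they must agree in channel count.

#' Construct a multichannel signal
#'
#' A signal is a real matrix with timepoints as rows and channels as columns,
#' an optional class label and a record identifier. Values must be finite and
#' at least two timepoints are required.
#'
#' @param values Numeric matrix (or vector for a single channel), timepoints
#'   in rows, channels in columns.
#' @param record_id Character identifier for the record.
#' @param label Optional class label (coerced to character).
#' @param channel_names Optional character vector of channel names.
#' @return An object of class `frbain_signal`.
#' @examples
#' s <- signal(cbind(sin(1:50 / 5), cos(1:50 / 5)), record_id = "r1", label = "A")
#' n_channels(s)
#' @export
signal <- function(values, record_id = "record", label = NULL,
                   channel_names = NULL) {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("signal values must be a numeric matrix (record '%s')", record_id)
  if (nrow(values) < 2L)
    stop_validation("record '%s' has %d timepoint(s); at least 2 required",
                    record_id, nrow(values))
  if (ncol(values) < 1L)
    stop_validation("record '%s' has no channels", record_id)
  if (!all(is.finite(values)))
    stop_validation("record '%s' contains non-finite values", record_id)
  if (!is.null(channel_names) && length(channel_names) != ncol(values))
    stop_validation("record '%s': %d channel names for %d channels",
                    record_id, length(channel_names), ncol(values))
  dimnames(values) <- NULL
  structure(list(values = values,
                 channel_names = channel_names,
                 label = if (is.null(label)) NULL else as.character(label),
                 record_id = as.character(record_id)),
            class = "frbain_signal")
}

#' @export
print.frbain_signal <- function(x, ...) {
  cat(sprintf("<signal '%s': %d channels x %d timepoints%s>\n",
              x$record_id, ncol(x$values), nrow(x$values),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Number of channels / timepoints of a signal
#' @param x A `frbain_signal`.
#' @return Integer count.
#' @export
n_channels <- function(x) ncol(x$values)

#' @rdname n_channels
#' @export
n_timepoints <- function(x) nrow(x$values)

#' Construct a signal dataset
#'
#' An ordered collection of signals sharing a channel count, together with an
#' ordered alphabet of K >= 2 class labels. By default the classes are the
#' distinct labels in order of first appearance; this order fixes the internal
#' class indices used by the model.
#'
#' @param signals List of [signal()] objects.
#' @param classes Optional character vector of class labels; defaults to the
#'   unique labels in first-appearance order.
#' @return An object of class `frbain_dataset`.
#' @export
signal_dataset <- function(signals, classes = NULL) {
  if (!is.list(signals) || length(signals) == 0L)
    stop_validation("a dataset needs at least one signal")
  ok <- vapply(signals, inherits, logical(1), "frbain_signal")
  if (!all(ok)) stop_validation("all elements must be frbain_signal objects")
  ncs <- vapply(signals, n_channels, integer(1))
  if (length(unique(ncs)) > 1L)
    stop_validation("inconsistent channel counts across records: %s",
                    paste(unique(ncs), collapse = ", "))
  labels <- lapply(signals, `[[`, "label")
  seen <- unlist(labels[!vapply(labels, is.null, logical(1))], use.names = FALSE)
  if (is.null(classes)) classes <- unique(seen)
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop_validation("duplicated class labels")
  if (length(seen) && !all(seen %in% classes))
    stop_validation("labels not in class alphabet: %s",
                    paste(setdiff(seen, classes), collapse = ", "))
  structure(list(signals = signals, classes = classes),
            class = "frbain_dataset")
}

#' @export
print.frbain_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<signal dataset: %d records, %d channels, %d classes (%s)>\n",
              length(x$signals), n_channels(x$signals[[1]]),
              length(x$classes), paste(x$classes, collapse = ", ")))
  if (any(!is.na(labs))) print(table(factor(labs, levels = x$classes)))
  invisible(x)
}

#' @export
length.frbain_dataset <- function(x) length(x$signals)

#' Record labels / ids of a dataset
#' @param dataset A `frbain_dataset`.
#' @return Character vector (labels may be `NA` for unlabeled records).
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$signals,
         function(s) if (is.null(s$label)) NA_character_ else s$label,
         character(1))
}

#' @rdname dataset_labels
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$signals, `[[`, character(1), "record_id")
}

#' Subset a dataset by record index
#' @param dataset A `frbain_dataset`.
#' @param idx Integer indices of records to keep.
#' @param drop_classes If `TRUE`, recompute the class alphabet from the kept
#'   records; otherwise the original alphabet is retained.
#' @return A `frbain_dataset`.
#' @export
dataset_subset <- function(dataset, idx, drop_classes = FALSE) {
  if (length(idx) == 0L) stop_validation("empty record subset")
  signal_dataset(dataset$signals[idx],
                 classes = if (drop_classes) NULL else dataset$classes)
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_record_file <- function(path, record_id) {
  if (!file.exists(path))
    stop_io("record '%s': file not found: %s", record_id, path)
  sep <- delim_for(path)
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(cells))))
  tab <- tryCatch(
    read.table(path, sep = sep, header = has_header,
               colClasses = "character", strip.white = TRUE),
    error = function(e) stop_io("record '%s': cannot read %s (%s)",
                                record_id, path, conditionMessage(e)))
  mat <- suppressWarnings(apply(as.matrix(tab), 2L, as.numeric))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = ncol(tab))
  bad <- which(is.na(mat) & !toupper(trimws(as.matrix(tab))) %in% c("NA", "NAN"),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_parse("record '%s': non-numeric value at row %d, column %d of %s",
               record_id, bad[1, 1], bad[1, 2], path)
  ch <- if (has_header) colnames(tab) else NULL
  signal(mat, record_id = record_id, channel_names = ch)
}

#' Read a signal dataset from a manifest
#'
#' The manifest is a CSV with header `record_id,file,label`; each referenced
#' file holds one record as a delimited numeric table, timepoints in rows and
#' channels in columns (header row optional, delimiter chosen by extension:
#' `.tsv`/`.txt` tab, otherwise comma). Records may differ in length but must
#' share a channel count.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param data_dir Directory against which relative `file` entries are
#'   resolved; defaults to the manifest's directory.
#' @return A [signal_dataset()] with records in manifest order; the class
#'   alphabet is the unique labels in first-appearance order.
#' @export
load_dataset <- function(manifest_path, data_dir = dirname(manifest_path)) {
  if (!file.exists(manifest_path))
    stop_io("manifest not found: %s", manifest_path)
  man <- read.csv(manifest_path, colClasses = "character")
  need <- c("record_id", "file", "label")
  if (!all(need %in% names(man)))
    stop_parse("manifest %s must have columns %s", manifest_path,
               paste(need, collapse = ", "))
  signals <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- man$file[i]
    if (!grepl("^/", path)) path <- file.path(data_dir, path)
    s <- read_record_file(path, man$record_id[i])
    lab <- man$label[i]
    s$label <- if (is.na(lab) || !nzchar(lab)) NULL else lab
    s$record_id <- man$record_id[i]
    signals[[i]] <- s
  }
  signal_dataset(signals)
}

#' Write a signal dataset to a directory
#'
#' Writes one CSV per record plus `manifest.csv`; [load_dataset()] on the
#' result reproduces labels and record order exactly and values to write
#' precision (~1e-12 relative).
#'
#' @param dataset A [signal_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_dataset <- function(dataset, out_dir) {
  if (!inherits(dataset, "frbain_dataset") || length(dataset$signals) == 0L)
    stop_validation("nothing to write: empty dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io("cannot create directory %s", out_dir)
  ids <- dataset_ids(dataset)
  files <- paste0(make.names(ids), ".csv")
  for (i in seq_along(dataset$signals)) {
    s <- dataset$signals[[i]]
    v <- s$values
    colnames(v) <- s$channel_names %||% paste0("ch", seq_len(ncol(v)))
    ok <- tryCatch({
      write.csv(format(as.data.frame(v), digits = 15, trim = TRUE),
                file.path(out_dir, files[i]), row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io("cannot write record file in %s", out_dir)
  }
  labs <- dataset_labels(dataset)
  man <- data.frame(record_id = ids, file = files,
                    label = ifelse(is.na(labs), "", labs))
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
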