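#' Write / read a trial table as TSV with a JSON sidecar
#'
#' The trial table is written as plain TSV; the task configuration travels
#' in a JSON sidecar (`<path>.json`) so a round trip restores both data and
#' provenance.
#'
#' @param trials a `trial_table`.
#' @param path output TSV path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   restored `trial_table`.
#' @export
write_trials <- function(trials, path) {
  write.table(as.data.frame(trials), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- attr(trials, "task_config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(tab, "task_config") <- structure(cfg, class = "task_config")
  }
  tab
}

#' Write / read a neural tensor as plain text
#'
#' Serializes a `neural_tensor` to a JSON header (`<path>.json`: dimensions,
#' time axis, sampling rate, metadata), a TSV of the flattened activity
#' (`<path>.tsv`, one row per epoch, components and timepoints unrolled
#' time-major), and a TSV of the epoch table (`<path>_epochs.tsv`). The
#' round trip is lossless up to the text representation of doubles (17
#' significant digits).
#'
#' @param tensor a `neural_tensor`.
#' @param path base path (without extension).
#' @return `write_tensor()` returns `path` invisibly; `read_tensor()` the
#'   restored `neural_tensor`.
#' @export
write_tensor <- function(tensor, path) {
  d <- dim(tensor$activity)
  header <- list(dim = d, time = tensor$time, sfreq = tensor$sfreq,
                 meta = tensor$meta)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(tensor$activity, nrow = d[1]) # [epoch, comp*time]
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tensor$epochs)) {
    write.table(tensor$epochs, paste0(path, "_epochs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(read.table(paste0(path, ".tsv"), sep = "\t",
                               header = FALSE))
  act <- array(as.numeric(flat), dim = header$dim)
  ep_path <- paste0(path, "_epochs.tsv")
  epochs <- if (file.exists(ep_path)) {
    read.table(ep_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  neural_tensor(act, time = header$time, sfreq = header$sfreq,
                epochs = epochs, meta = as.list(header$meta))
}

#' Write / read an information result as JSON
#'
#' Preserves all provenance fields (raw value, shuffle mean, shuffle and
#' subsample counts, trial count).
#'
#' @param x an `info_result`.
#' @param path output JSON path.
#' @return `write_info_result()` returns `path` invisibly;
#'   `read_info_result()` the restored `info_result`.
#' @export
write_info_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_info_result
#' @export
read_info_result <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(v, class = "info_result")
}

# small deterministic content hash (FNV-1a over the JSON serialization)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
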