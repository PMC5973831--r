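# File interfaces: trial-table CSV, lead-field CSV, epoch-container
# serialization, and a minimal BrainVision reader.

#' Read / write behavioral trial tables
#'
#' Trial tables are plain CSV with the header
#' `subject,condition,session,trial,intensity,response` (additional
#' columns such as `zResponse` round-trip unchanged).
#'
#' @param path file path.
#' @param table data.frame to write.
#' @return `readTrialTable()` returns the data.frame;
#'   `writeTrialTable()` returns `path` invisibly.
#' @export
readTrialTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "session", "trial", "intensity",
            "response")
  miss <- setdiff(need, names(tab))
  .stopIf(length(miss) > 0,
          "trial table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname readTrialTable
#' @export
writeTrialTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write lead fields as delimited text
#'
#' A lead field is stored as CSV with one row per channel; the first
#' column is the channel name and the remaining columns are the dipole
#' gains, named `<roi>.x`, `<roi>.y`, `<roi>.z`.
#'
#' @param path file path.
#' @param leadfield a [LeadField-class] to write.
#' @return `readLeadField()` returns a [LeadField-class].
#' @export
readLeadField <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  .stopIf(ncol(m) %% 3L != 0L, "gain columns must come in blocks of 3")
  rois <- unique(sub("\\.[xyz]$", "", colnames(m)))
  .stopIf(length(rois) * 3L != ncol(m),
          "gain columns must be named <roi>.x/.y/.z")
  new("LeadField", matrix = m, roiLabels = rois,
      channelNames = as.character(tab[[1L]]))
}

#' @rdname readLeadField
#' @export
writeLeadField <- function(leadfield, path) {
  tab <- data.frame(channel = leadfield@channelNames,
                    leadfield@matrix, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize epoch containers
#'
#' Writes an [EpochSet-class] or [SourceEpochs-class] to `path` (RDS, the
#' package's native container) together with a human-readable JSON sidecar
#' `<path>.json` describing dimensions, sampling rate, events and optional
#' generation parameters, so a container's provenance can be inspected
#' without loading the data.
#'
#' @param epochs the container to write.
#' @param path destination file path.
#' @param parameters optional named list of generation parameters recorded
#'   in the sidecar.
#' @return `writeEpochs()` returns `path` invisibly; `readEpochs()`
#'   returns the container.
#' @export
writeEpochs <- function(epochs, path, parameters = NULL) {
  .stopIf(!(is(epochs, "EpochSet") || is(epochs, "SourceEpochs")),
          "epochs must be an EpochSet or SourceEpochs")
  saveRDS(epochs, path)
  side <- list(class = class(epochs)[1L], dim = dim(epochs@data),
               fs = epochs@fs, t0 = epochs@t0,
               events = as.list(epochs@events))
  if (!is.null(parameters)) side$parameters <- parameters
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  obj <- readRDS(path)
  .stopIf(!(is(obj, "EpochSet") || is(obj, "SourceEpochs")),
          "file does not contain an epoch container")
  obj
}

# Parse one INI-style BrainVision header section into a named list.
.bvSections <- function(lines) {
  secIdx <- grep("^\\[.*\\]", lines)
  sections <- list()
  for (i in seq_along(secIdx)) {
    name <- gsub("^\\[|\\]$", "", trimws(lines[secIdx[i]]))
    to <- if (i < length(secIdx)) secIdx[i + 1] - 1L else length(lines)
    body <- lines[(secIdx[i] + 1L):to]
    body <- body[grepl("=", body) & !grepl("^;", trimws(body))]
    kv <- regmatches(body, regexpr("=", body), invert = TRUE)
    vals <- vapply(kv, function(x) trimws(x[2]), character(1))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
    sections[[name]] <- as.list(vals)
  }
  sections
}

#' Minimal BrainVision reader
#'
#' Reads a BrainVision recording (`.vhdr` header, `.eeg` binary payload,
#' optional `.vmrk` markers) restricted to the multiplexed binary dialects
#' `IEEE_FLOAT_32` and `INT_16`; INT_16 samples are scaled by each
#' channel's resolution.  Marker positions are converted to seconds.
#'
#' @param vhdrPath path to the `.vhdr` header file.
#' @return list with `recording` (a [Recording-class]) and `markers`
#'   (data.frame: `type`, `description`, `time`; NULL without a marker
#'   file).
#' @export
readBrainVision <- function(vhdrPath) {
  lines <- readLines(vhdrPath, warn = FALSE)
  sec <- .bvSections(lines)
  ci <- sec[["Common Infos"]]
  .stopIf(is.null(ci), "not a BrainVision header: no [Common Infos]")
  .stopIf(!is.null(ci$DataOrientation) &&
            toupper(ci$DataOrientation) != "MULTIPLEXED",
          "only MULTIPLEXED data orientation is supported")
  fmt <- toupper(sec[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  .stopIf(!fmt %in% c("IEEE_FLOAT_32", "INT_16"),
          "unsupported binary format: ", fmt)
  nCh <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)   # interval is microseconds
  chInfo <- sec[["Channel Infos"]]
  chNames <- character(nCh)
  resolution <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    entry <- chInfo[[paste0("Ch", i)]]
    .stopIf(is.null(entry), "missing channel info for Ch", i)
    parts <- strsplit(entry, ",")[[1L]]
    chNames[i] <- parts[1L]
    if (length(parts) >= 3L && nzchar(trimws(parts[3L])))
      resolution[i] <- as.numeric(parts[3L])
  }
  dataPath <- file.path(dirname(vhdrPath), ci$DataFile)
  sz <- file.info(dataPath)$size
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(dataPath, "double", n = sz / 4L, size = 4L,
                    endian = "little")
  } else {
    vals <- readBin(dataPath, "integer", n = sz / 2L, size = 2L,
                    signed = TRUE, endian = "little")
  }
  nSamp <- length(vals) %/% nCh
  data <- matrix(vals[seq_len(nSamp * nCh)], nrow = nCh)  # multiplexed
  if (fmt == "INT_16") data <- data * resolution
  rec <- new("Recording", data = data, fs = fs, channelNames = chNames)
  markers <- NULL
  if (!is.null(ci$MarkerFile)) {
    mrkPath <- file.path(dirname(vhdrPath), ci$MarkerFile)
    if (file.exists(mrkPath)) {
      ms <- .bvSections(readLines(mrkPath, warn = FALSE))
      mi <- ms[["Marker Infos"]]
      if (!is.null(mi) && length(mi)) {
        rows <- lapply(mi, function(entry) {
          parts <- strsplit(entry, ",")[[1L]]
          data.frame(type = parts[1L], description = parts[2L],
                     time = (as.numeric(parts[3L]) - 1) / fs,
                     stringsAsFactors = FALSE)
        })
        markers <- do.call(rbind, rows)
        rownames(markers) <- NULL
      }
    }
  }
  list(recording = rec, markers = markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
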