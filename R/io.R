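.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a photon stream as a columnar-text container
#'
#' Serializes a [PhotonStream-class] to a TSV with columns `timestamp`,
#' `excitation_phase`, `detection_channel` (the photon-HDF5 group names)
#' plus a JSON metadata sidecar (`<path>.json`) carrying the alternation
#' period and acquisition duration. `readPhotonContainer()` validates the
#' schema, repopulates the metadata, and sorts unsorted timestamps with a
#' warning; a missing column raises a schema error naming the field.
#'
#' @param stream a [PhotonStream-class].
#' @param path file path (TSV).
#' @return `writePhotonContainer()`: the path, invisibly;
#'   `readPhotonContainer()`: a [PhotonStream-class].
#' @export
writePhotonContainer <- function(stream, path) {
  stopifnot(is(stream, "PhotonStream"))
  df <- data.frame(timestamp = stream@timestamps,
                   excitation_phase = stream@excitationPhase,
                   detection_channel = stream@detectionChannel)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(alternation_period = stream@alternationPeriod,
                            duration = stream@duration),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhotonContainer
#' @export
readPhotonContainer <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("timestamp", "excitation_phase", "detection_channel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("photon container schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyNA(df$timestamp)) stop("photon container schema error: NA timestamps")
  meta <- list(alternation_period = 1e-4, duration = NA_real_)
  if (file.exists(.sidecarPath(path)))
    meta <- utils::modifyList(meta, jsonlite::read_json(.sidecarPath(path),
                                                        simplifyVector = TRUE))
  if (is.unsorted(df$timestamp)) {
    warning("timestamps were unsorted on input; sorting")
    df <- df[order(df$timestamp), , drop = FALSE]
  }
  dur <- meta$duration
  if (!is.finite(dur)) dur <- if (nrow(df)) max(df$timestamp) else 0
  new("PhotonStream", timestamps = df$timestamp,
      excitationPhase = df$excitation_phase,
      detectionChannel = df$detection_channel,
      alternationPeriod = meta$alternation_period, duration = dur)
}

#' Write / read burst tables
#'
#' TSV serialization of a [BurstSet-class] (one row per burst).
#'
#' @param x a [BurstSet-class].
#' @param path file path.
#' @return `writeBurstTable()`: the path, invisibly; `readBurstTable()`: a
#'   [BurstSet-class].
#' @export
writeBurstTable <- function(x, path) {
  stopifnot(is(x, "BurstSet"))
  utils::write.table(bursts(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeBurstTable
#' @export
readBurstTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("tStart", "tEnd", "iDD", "iDA", "iAA")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("burst table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!all(c("e", "s") %in% names(df))) {
    es <- computeES(df$iDD, df$iDA, df$iAA)
    df$e <- es$e; df$s <- es$s
  }
  new("BurstSet", bursts = df)
}

#' Write / read TIRF trace tables
#'
#' Long-format CSV with columns `trace_id`, `frame` (0-based), `time_s`,
#' `donor`, `acceptor` and, for synthetic traces, the ground-truth state in
#' `state_truth` (flagged as ground truth by its name; analysis functions
#' never read it). Per-trace metadata (frame interval, injection time,
#' condition metadata) travels in a JSON sidecar (`<path>.json`).
#' `readTraceTable()` errors on missing columns and on a non-uniform frame
#' interval (beyond 1e-6 s), naming the offending trace.
#'
#' @param traces list of [FretTrace-class].
#' @param path file path (CSV).
#' @return `writeTraceTable()`: the path, invisibly; `readTraceTable()`: a
#'   named list of [FretTrace-class].
#' @export
writeTraceTable <- function(traces, path) {
  if (is(traces, "FretTrace")) traces <- list(traces)
  ids <- names(traces)
  if (is.null(ids)) ids <- sprintf("trace%04d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    df <- data.frame(trace_id = ids[i],
                     frame = seq_along(traceTime(tr)) - 1L,
                     time_s = traceTime(tr),
                     donor = donorIntensity(tr),
                     acceptor = acceptorIntensity(tr))
    if (length(stateTruth(tr))) df$state_truth <- stateTruth(tr)
    df
  })
  # pad the truth column so heterogeneous ensembles still bind
  hasTruth <- vapply(rows, function(d) "state_truth" %in% names(d), logical(1))
  if (any(hasTruth) && !all(hasTruth))
    rows <- lapply(rows, function(d) {
      if (!"state_truth" %in% names(d)) d$state_truth <- NA_character_
      d
    })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  meta <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    list(frame_interval = frameInterval(tr),
         injection_time = if (is.na(injectionTime(tr))) NULL else injectionTime(tr),
         metadata = traceMetadata(tr)[setdiff(names(traceMetadata(tr)),
                                              c("stateE", "path"))])
  })
  names(meta) <- ids
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  meta <- if (file.exists(.sidecarPath(path)))
    jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE) else list()
  out <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    id <- d$trace_id[1]
    dts <- diff(d$time_s)
    if (length(dts) && (max(dts) - min(dts)) > 1e-6)
      stop("non-uniform frame interval in trace '", id, "'")
    m <- meta[[id]]
    dt <- if (!is.null(m$frame_interval)) m$frame_interval
          else if (length(dts)) stats::median(dts) else 0.1
    inj <- if (!is.null(m$injection_time)) m$injection_time else NA_real_
    truth <- if ("state_truth" %in% names(d) && !anyNA(d$state_truth))
      as.character(d$state_truth) else character(0)
    new("FretTrace", time = d$time_s, donor = d$donor, acceptor = d$acceptor,
        frameInterval = dt, injectionTime = inj,
        metadata = if (is.null(m$metadata)) list() else as.list(m$metadata),
        stateTruth = truth)
  })
  out[unique(df$trace_id)]
}

#' Write / read a two-channel image stack as multi-page TIFF
#'
#' Images are stored as 16-bit grayscale pages; intensities are clipped to
#' [0, 65535] counts.
#'
#' @param images list of numeric matrices (photon counts).
#' @param path TIFF path.
#' @return `writeImageStack()`: the path, invisibly; `readImageStack()`:
#'   list of matrices in counts.
#' @export
writeImageStack <- function(images, path) {
  pages <- lapply(images, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) round(m * 65535))
}

#' Build a run report
#'
#' Bundles fitted parameters, counts and full configuration provenance
#' (every parameter affecting the result, the seed, and the package
#' version) into a list that round-trips losslessly through JSON.
#'
#' @param subcommand character label.
#' @param params named list of results (values with units in the names).
#' @param config named list echoing the run configuration.
#' @param seed integer seed (or NULL).
#' @param counts named list of filter-stage counts.
#' @return the report list.
#' @export
makeResultReport <- function(subcommand, params, config = list(),
                             seed = NULL, counts = list()) {
  list(subcommand = subcommand,
       package = "fretx",
       version = as.character(utils::packageVersion("fretx")),
       seed = seed,
       config = config,
       counts = counts,
       params = params)
}

#' @rdname makeResultReport
#' @param report a report list.
#' @param path JSON path.
#' @export
writeResultReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname makeResultReport
#' @export
readResultReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
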