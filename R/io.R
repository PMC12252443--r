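CURVE_COLUMNS <- c("time_h", "biomass_gL", "sugar_gL", "co2", "pH", "temp_C",
                   "alcohol_gL")

#' Write a fermentation curve to CSV
#'
#' Canonical interchange format: columns
#' `time_h, biomass_gL, sugar_gL, co2, pH, temp_C, alcohol_gL`.
#'
#' @param curve A fermentation curve (data.frame).
#' @param path Destination file.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  cols <- intersect(CURVE_COLUMNS, names(df))
  write.csv(df[, c(cols, setdiff(names(df), cols))], path, row.names = FALSE)
  invisible(path)
}

#' Read a fermentation curve from CSV
#'
#' Requires the canonical header (the alcohol column is optional).  Unknown
#' extra columns are preserved with a warning; rows with non-numeric values
#' are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return A `fermentation_curve` data.frame.
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  required <- setdiff(CURVE_COLUMNS, "alcohol_gL")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), CURVE_COLUMNS)
  if (length(extra)) {
    warning("preserving unknown column(s): ", paste(extra, collapse = ", "))
  }
  known <- intersect(CURVE_COLUMNS, names(df))
  bad <- which(!stats::complete.cases(
    vapply(df[known], function(x) suppressWarnings(as.numeric(x)),
           numeric(nrow(df)))))
  if (length(bad)) {
    stop("malformed row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  for (cn in known) df[[cn]] <- as.numeric(df[[cn]])
  structure(df, class = c("fermentation_curve", "data.frame"))
}

#' Encode a fermentation curve as telemetry records
#'
#' One JSON-ready record per time point in the device-telemetry convention:
#' `{"ts": <epoch ms>, "values": {attribute: number, ...}}`, with timestamps
#' spaced `period_min` minutes apart from `start_epoch_ms`.
#'
#' @param curve A fermentation curve.
#' @param start_epoch_ms Epoch milliseconds of the first record.
#' @param period_min Sampling period in minutes (default 5).
#' @return A list of records, each with `ts` (numeric ms) and `values`
#'   (named list).
#' @export
curve_to_telemetry <- function(curve, start_epoch_ms = 0, period_min = 5) {
  df <- as.data.frame(curve)
  attrs <- setdiff(intersect(CURVE_COLUMNS, names(df)), "time_h")
  ts <- start_epoch_ms + (seq_len(nrow(df)) - 1) * period_min * 60 * 1000
  lapply(seq_len(nrow(df)), function(i) {
    list(ts = ts[i], values = as.list(df[i, attrs]))
  })
}

#' Decode telemetry records back into a fermentation curve
#'
#' @param records List of telemetry records from [curve_to_telemetry()] (or
#'   parsed JSON of the same shape).
#' @return A `fermentation_curve` data.frame with `time_h` reconstructed
#'   from the timestamps (hours since the first record).
#' @export
telemetry_to_curve <- function(records) {
  if (!length(records)) stop("no telemetry records")
  ts <- vapply(records, function(r) as.numeric(r$ts), numeric(1))
  if (any(ts < 0)) stop("timestamps must be non-negative")
  attrs <- names(records[[1]]$values)
  df <- data.frame(time_h = (ts - ts[1]) / 3600 / 1000)
  for (a in attrs) {
    df[[a]] <- vapply(records, function(r) as.numeric(r$values[[a]]),
                      numeric(1))
  }
  structure(df, class = c("fermentation_curve", "data.frame"))
}

#' Write / read telemetry as JSON lines
#'
#' One record per line, `{"ts": ..., "values": {...}}`.
#'
#' @param records Telemetry records.
#' @param path Destination file.
#' @export
write_telemetry_json <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_telemetry_json
#' @export
read_telemetry_json <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) jsonlite::fromJSON(ln, simplifyVector = FALSE))
}

#' Persist a trained alcohol controller as a JSON config
#'
#' Serialises partitions (centers, width, universe) and the induced rule
#' base; [read_controller()] restores a fully functional controller.
#'
#' @param controller An `alcohol_controller`.
#' @param path Destination file.
#' @export
write_controller <- function(controller, path) {
  parts <- lapply(controller$partitions, function(p) {
    list(attribute = p$attribute, centers = as.list(p$centers),
         width = p$width, universe = p$universe)
  })
  obj <- list(partitions = parts,
              rules = controller$rules,
              smoothing_sigma = controller$smoothing_sigma,
              grid_points = controller$grid_points,
              implication = controller$implication,
              activation_floor = controller$activation_floor,
              antecedents = controller$antecedents,
              consequent = controller$consequent)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_controller
#' @export
read_controller <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  partitions <- lapply(obj$partitions, function(p) {
    structure(list(attribute = p$attribute,
                   centers = unlist(p$centers),
                   width = p$width,
                   universe = p$universe,
                   stats = NULL),
              class = "gaussian_partition")
  })
  structure(list(partitions = partitions,
                 rules = as.data.frame(obj$rules),
                 smoothing_sigma = obj$smoothing_sigma,
                 grid_points = obj$grid_points,
                 implication = obj$implication,
                 activation_floor = obj$activation_floor,
                 antecedents = obj$antecedents,
                 consequent = obj$consequent),
            class = "alcohol_controller")
}
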