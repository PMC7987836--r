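## File I/O: trial tables (CSV), time-series / vertex-map containers
## (plain-text, full-precision), and YAML configuration.

TRIAL_GROUPS <- c("sr-familiarization", "shl-familiarization")
TRIAL_CONTEXTS <- c("_l", "_r")
TRIAL_RESPONSES <- c("S", "SH")
TRIAL_CONDITIONS <- c("Trained", "Naive")

#' Validate a behavioral trial table
#'
#' Checks column presence and category domains, and recomputes the
#' derived columns `condition` (from group and context) and `unrepaired`
#' (from context and response), verifying them against any values already
#' present.
#'
#' @param df data.frame with columns `subject_id`, `group`, `context`,
#'   `step`, `response`, and optionally `condition` and `unrepaired`.
#' @return the validated data.frame with both derived columns filled in.
#' @seealso [readTrialTable()], [assignCondition()], [codeUnrepaired()]
#' @export
validateTrialTable <- function(df) {
  required <- c("subject_id", "group", "context", "step", "response")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    df$condition <- character(0)
    df$unrepaired <- logical(0)
    return(df)
  }
  checkDomain <- function(col, domain) {
    bad <- which(!(as.character(df[[col]]) %in% domain))
    if (length(bad))
      stop(sprintf("invalid %s value '%s' in row %d (allowed: %s)",
                   col, df[[col]][bad[1]], bad[1],
                   paste(domain, collapse = ", ")), call. = FALSE)
  }
  checkDomain("group", TRIAL_GROUPS)
  checkDomain("context", TRIAL_CONTEXTS)
  checkDomain("response", TRIAL_RESPONSES)
  step <- df$step
  bad <- which(!(step %in% 1:5))
  if (length(bad))
    stop(sprintf("invalid step value '%s' in row %d (allowed: 1..5)",
                 step[bad[1]], bad[1]), call. = FALSE)
  df$step <- as.integer(step)

  cond <- assignCondition(df$group, df$context)
  if (!is.null(df$condition)) {
    bad <- which(as.character(df$condition) != cond)
    if (length(bad))
      stop(sprintf(
        "condition column disagrees with group/context in row %d (expected %s)",
        bad[1], cond[bad[1]]), call. = FALSE)
  }
  df$condition <- cond
  unrep <- codeUnrepaired(df$context, df$response)
  if (!is.null(df$unrepaired)) {
    stored <- df$unrepaired
    if (is.character(stored)) stored <- toupper(stored) %in% c("TRUE", "T", "1")
    bad <- which(as.logical(stored) != unrep)
    if (length(bad))
      stop(sprintf(
        "unrepaired column disagrees with context/response in row %d", bad[1]),
        call. = FALSE)
  }
  df$unrepaired <- unrep
  df
}

#' Read a behavioral trial table from CSV
#'
#' The file must be comma-separated UTF-8 with a header naming at least
#' `subject_id`, `group`, `context`, `step`, `response`. The derived
#' columns `condition` and `unrepaired` are recomputed and, when present
#' in the file, checked against the stored values.
#'
#' @param path path to the CSV file.
#' @return validated trial table (data.frame).
#' @export
readTrialTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateTrialTable(df)
}

#' Write a trial table to CSV
#' @param df a validated trial table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTrialTable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- plain-text matrix container -------------------------------------
## Self-describing format: '#phonoflux <kind> 1' magic line, '#key: value'
## metadata, then a TSV body. Numbers are written with %.17g so doubles
## round-trip bit-exactly and a write-read-write cycle is byte-identical.

fmtNum <- function(x) sprintf("%.17g", x)

writeMatrixContainer <- function(kind, meta, colIds, body, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#phonoflux %s 1", kind), con)
  for (nm in names(meta))
    writeLines(sprintf("#%s: %s", nm, fmtNum(meta[[nm]])), con)
  writeLines(paste(colIds, collapse = "\t"), con)
  apply(body, 1L, function(row)
    writeLines(paste(fmtNum(row), collapse = "\t"), con))
  invisible(path)
}

readMatrixContainer <- function(kind, requiredMeta, path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1] != sprintf("#phonoflux %s 1", kind))
    stop(sprintf("'%s' is not a phonoflux %s file", path, kind),
         call. = FALSE)
  i <- 2L
  meta <- list()
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#", "", lines[i])
    key <- sub(":.*$", "", kv)
    meta[[key]] <- as.numeric(sub("^[^:]*: *", "", kv))
    i <- i + 1L
  }
  missing <- setdiff(requiredMeta, names(meta))
  if (length(missing))
    stop(sprintf("%s file lacks metadata field(s): %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (i > length(lines)) stop("container has no header row", call. = FALSE)
  colIds <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  dataLines <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  body <- if (length(dataLines)) {
    do.call(rbind, lapply(strsplit(dataLines, "\t", fixed = TRUE),
                          as.numeric))
  } else matrix(numeric(0), nrow = 0L, ncol = length(colIds))
  list(meta = meta, colIds = colIds, body = body)
}

#' Write / read a MultiTimeSeries
#'
#' The container is a self-describing UTF-8 text file: a magic line, the
#' sampling rate and time origin as `#key: value` metadata, a header row
#' of channel labels, and one tab-separated row per timepoint. Values are
#' serialized with 17 significant digits, so a write-read round trip is
#' bit-exact and a write-read-write cycle is byte-identical.
#'
#' @param ts a [MultiTimeSeries-class].
#' @param path file path.
#' @return `writeTimeSeries` returns the path invisibly;
#'   `readTimeSeries` returns a [MultiTimeSeries-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeTimeSeries(multiTimeSeries(matrix(rnorm(30), nrow = 3)), f)
#' readTimeSeries(f)
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "MultiTimeSeries"))
  writeMatrixContainer("timeseries",
                       list(sampling_rate = ts@samplingRate,
                            t0_ms = ts@t0Ms),
                       ts@labels, t(ts@values), path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  rec <- readMatrixContainer("timeseries", c("sampling_rate", "t0_ms"),
                             path)
  if (nrow(rec$body) < 1L)
    stop("time-series container holds no samples", call. = FALSE)
  multiTimeSeries(t(rec$body), labels = rec$colIds,
                  samplingRate = rec$meta$sampling_rate,
                  t0Ms = rec$meta$t0_ms)
}

#' Write / read a VertexActivationMap
#'
#' Same text container as [writeTimeSeries()]; the body has one row per
#' vertex holding the three coordinates followed by the activation time
#' course, and the vertex count and timepoint count in the metadata.
#'
#' @param map a [VertexActivationMap-class].
#' @param path file path.
#' @return `writeVertexMap` returns the path invisibly; `readVertexMap`
#'   a [VertexActivationMap-class].
#' @export
writeVertexMap <- function(map, path) {
  stopifnot(is(map, "VertexActivationMap"))
  body <- cbind(map@coordsMm, map@activation)
  writeMatrixContainer("vertexmap",
                       list(sampling_rate = map@samplingRate,
                            t0_ms = map@t0Ms,
                            n_timepoints = ncol(map@activation)),
                       map@vertexIds, t(body), path)
}

#' @rdname writeVertexMap
#' @export
readVertexMap <- function(path) {
  rec <- readMatrixContainer("vertexmap",
                             c("sampling_rate", "t0_ms", "n_timepoints"),
                             path)
  body <- t(rec$body)
  nT <- as.integer(rec$meta$n_timepoints)
  if (ncol(body) != nT + 3L)
    stop("vertex-map container has inconsistent dimensions", call. = FALSE)
  vertexActivationMap(body[, 1:3, drop = FALSE],
                      body[, -(1:3), drop = FALSE],
                      vertexIds = rec$colIds,
                      samplingRate = rec$meta$sampling_rate,
                      t0Ms = rec$meta$t0_ms)
}

## ---- configuration ---------------------------------------------------

CONFIG_KEYS <- c(model_order = "modelOrder", n_bootstrap = "nBootstrap",
                 alpha = "alpha", window_ms = "windowMs",
                 centroid_percentile = "centroidPercentile",
                 exclusion_radius_mm = "exclusionRadiusMm",
                 growth_sd_factor = "growthSdFactor",
                 redundancy_sd_factor = "redundancySdFactor",
                 contiguity_radius_mm = "contiguityRadiusMm",
                 steps_included = "stepsIncluded",
                 random_seed = "randomSeed")

#' Load an analysis configuration from YAML
#'
#' Recognized keys (snake_case): `model_order`, `n_bootstrap`, `alpha`,
#' `window_ms`, `centroid_percentile`, `exclusion_radius_mm`,
#' `growth_sd_factor`, `redundancy_sd_factor`, `contiguity_radius_mm`,
#' `steps_included`, `random_seed`. Unspecified fields take the study
#' defaults of [analysisConfig()]; unknown keys produce a warning, not an
#' error. Domain violations (e.g., alpha outside (0,1)) are errors.
#'
#' @param path path to a YAML file; an empty file yields all defaults.
#' @return an [AnalysisConfig-class].
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_KEYS))
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  args <- list()
  for (key in intersect(names(raw), names(CONFIG_KEYS)))
    args[[CONFIG_KEYS[[key]]]] <- raw[[key]]
  do.call(analysisConfig, args)
}

## ---- time-axis helper ------------------------------------------------

#' Sample indices of a closed millisecond window
#'
#' Converts a closed interval in milliseconds to sample indices, rounding
#' toward the interior so that the returned samples all lie inside the
#' interval. At 1000 Hz with t0 = 0, the 100-500 ms window maps to 401
#' samples.
#'
#' @param x an object with a time base ([MultiTimeSeries-class] or
#'   [VertexActivationMap-class]).
#' @param windowMs numeric `c(lo, hi)` in milliseconds.
#' @return integer vector of sample indices.
#' @export
windowIndices <- function(x, windowMs) {
  tms <- timesMs(x)
  eps <- 1e-9
  idx <- which(tms >= windowMs[1] - eps & tms <= windowMs[2] + eps)
  if (!length(idx))
    stop(sprintf("window %g-%g ms lies outside the data span %g-%g ms",
                 windowMs[1], windowMs[2], tms[1], tms[length(tms)]),
         call. = FALSE)
  idx
}
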