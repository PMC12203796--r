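# Plain-text exchange formats.  Matrices travel as CSV with a JSON sidecar
# ("<path>.json") holding the attributes; tables are tidy CSV with a
# "# units:" comment line.  Everything round-trips losslessly (numbers are
# written with 17 significant digits).
#
# Conventions: frame indices 0-based, windows half-open [onset, offset);
# CSV is UTF-8, '.' decimal, no thousands separators.

.write_num_csv <- function(df, path) {
  # doubles go out as %.17g so every value round-trips bit-exactly
  df[] <- lapply(df, function(col) if (is.double(col)) sprintf("%.17g", col) else col)
  data.table::fwrite(df, path, sep = ",", quote = FALSE, logical01 = FALSE)
}

.sidecar <- function(path) paste0(path, ".json")

#' Write / read a sweep set
#'
#' The neutral exchange format for current-clamp recordings: a CSV with a
#' `time_ms` column and one `sweep_<current>pA` column per sweep, plus a
#' JSON sidecar (`<path>.json`) with `sampling_rate_hz`, `step_window_ms`,
#' `current_pA`, and optional free-form `metadata`.
#'
#' @param sweeps a [sweep_set()].
#' @param path CSV path (sidecar written next to it).
#' @param metadata optional list stored in the sidecar (e.g. the
#'   generating config and seed).
#' @return `write_sweepset`: `path`, invisibly. `read_sweepset`: a
#'   [sweep_set()].
#' @export
write_sweepset <- function(sweeps, path, metadata = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  df <- data.frame(time_ms = sweeps$time)
  for (i in seq_len(nrow(sweeps$voltage)))
    df[[sprintf("sweep_%03d", i)]] <- sweeps$voltage[i, ]
  .write_num_csv(df, path)
  side <- list(format = "v1phys_sweepset", version = 1L,
               sampling_rate_hz = sweeps$sampling_rate,
               step_window_ms = sweeps$step_window,
               current_pA = sweeps$current_pA)
  if (!is.null(metadata)) side$metadata <- metadata
  jsonlite::write_json(side, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweepset
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(.sidecar(path)))
    stop("schema error: missing sidecar ", .sidecar(path))
  side <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  for (field in c("sampling_rate_hz", "step_window_ms", "current_pA"))
    if (is.null(side[[field]]))
      stop("schema error: sidecar lacks required field '", field, "'")
  df <- data.table::fread(path, sep = ",", data.table = FALSE)
  if (!"time_ms" %in% names(df)) stop("schema error: missing 'time_ms' column")
  sw <- as.matrix(df[, setdiff(names(df), "time_ms"), drop = FALSE])
  if (ncol(sw) != length(side$current_pA))
    stop("schema error: ", ncol(sw), " sweep columns but ",
         length(side$current_pA), " entries in 'current_pA'")
  sweep_set(time = df$time_ms, voltage = t(sw),
            current_pA = as.numeric(side$current_pA),
            step_window = as.numeric(side$step_window_ms),
            sampling_rate = as.numeric(side$sampling_rate_hz))
}

#' Write / read a fluorescence dataset
#'
#' Wide CSV: `cell` id column then one column per frame (`f000000`, ...),
#' with a JSON sidecar carrying `frame_rate_hz`, `animal`, `genotype`,
#' `fov`, `is_dff`.
#'
#' @param dataset a [fluorescence_dataset()].
#' @param path CSV path.
#' @param metadata optional list stored in the sidecar.
#' @return `write_fluorescence`: `path`, invisibly; `read_fluorescence`: a
#'   [fluorescence_dataset()].
#' @export
write_fluorescence <- function(dataset, path, metadata = NULL) {
  stopifnot(inherits(dataset, "fluorescence_dataset"))
  df <- data.frame(cell = rownames(dataset$traces))
  m <- dataset$traces
  colnames(m) <- sprintf("f%06d", seq_len(ncol(m)) - 1L)
  df <- cbind(df, as.data.frame(m))
  .write_num_csv(df, path)
  side <- list(format = "v1phys_fluorescence", version = 1L,
               frame_rate_hz = dataset$frame_rate, animal = dataset$animal,
               genotype = dataset$genotype, fov = dataset$fov,
               is_dff = dataset$is_dff)
  if (!is.null(metadata)) side$metadata <- metadata
  jsonlite::write_json(side, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
read_fluorescence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(.sidecar(path)))
    stop("schema error: missing sidecar ", .sidecar(path))
  side <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  for (field in c("frame_rate_hz", "animal", "genotype", "is_dff"))
    if (is.null(side[[field]]))
      stop("schema error: sidecar lacks required field '", field, "'")
  df <- data.table::fread(path, sep = ",", data.table = FALSE)
  if (!"cell" %in% names(df)) stop("schema error: missing 'cell' column")
  m <- as.matrix(df[, setdiff(names(df), "cell"), drop = FALSE])
  rownames(m) <- df$cell
  fluorescence_dataset(m, frame_rate = as.numeric(side$frame_rate_hz),
                       animal = side$animal, genotype = side$genotype,
                       fov = side$fov %||% "fov1", is_dff = side$is_dff)
}

#' Write / read stimulus epochs
#'
#' CSV columns: `presentation`, `block`, `sf_cpd`, `contrast`,
#' `onset_frame`, `offset_frame`, `baseline_onset_frame` (0-based,
#' half-open), plus onset/offset seconds.  A `# units:` comment line
#' precedes the header.
#'
#' @param epochs a [generate_stimulus_schedule()] data.frame.
#' @param path CSV path.
#' @param n_frames trace length used for validation on read (optional).
#' @return `write_epochs`: `path`, invisibly; `read_epochs`: epochs
#'   data.frame of class `stimulus_schedule`.
#' @export
write_epochs <- function(epochs, path) {
  df <- data.frame(presentation = epochs$presentation, block = epochs$block,
                   sf_cpd = epochs$sf, contrast = epochs$contrast,
                   onset_s = epochs$onset_s, offset_s = epochs$offset_s,
                   onset_frame = epochs$onset_frame,
                   offset_frame = epochs$offset_frame,
                   baseline_onset_frame = epochs$baseline_onset_frame)
  con <- file(path, "w")
  writeLines("# units: sf_cpd=cycles/degree contrast=fraction frames=0-based,half-open times=s", con)
  close(con)
  data.table::fwrite(df, path, sep = ",", append = TRUE, col.names = TRUE)
  side <- list(format = "v1phys_epochs", version = 1L,
               frame_rate_hz = attr(epochs, "frame_rate"),
               lead_in_s = attr(epochs, "lead_in_s"),
               schedule_duration_s = attr(epochs, "schedule_duration_s"),
               n_frames = attr(epochs, "n_frames"))
  jsonlite::write_json(side, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, n_frames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, sep = ",", skip = "presentation", data.table = FALSE)
  need <- c("presentation", "block", "sf_cpd", "contrast", "onset_frame",
            "offset_frame", "baseline_onset_frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: epochs file lacks column(s) ",
                         paste(miss, collapse = ", "))
  names(df)[names(df) == "sf_cpd"] <- "sf"
  if (!is.null(n_frames)) {
    bad <- which(df$offset_frame > n_frames | df$baseline_onset_frame < 0)
    if (length(bad))
      stop("validation error: epoch rows beyond trace length: ",
           paste(head(bad, 10), collapse = ", "))
  }
  if (file.exists(.sidecar(path))) {
    side <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    attr(df, "frame_rate") <- side$frame_rate_hz
    attr(df, "lead_in_s") <- side$lead_in_s
    attr(df, "schedule_duration_s") <- side$schedule_duration_s
    attr(df, "n_frames") <- as.integer(side$n_frames)
  }
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' Write a tidy results table with a units comment line
#'
#' @param df data.frame.
#' @param path CSV path.
#' @param units named character vector or single string describing units.
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(df, path, units = NULL) {
  con <- file(path, "w")
  if (!is.null(units)) {
    u <- if (!is.null(names(units)))
      paste(names(units), units, sep = "=", collapse = " ") else paste(units, collapse = " ")
    writeLines(paste("# units:", u), con)
  }
  close(con)
  data.table::fwrite(df, path, sep = ",", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tidy_table
#' @export
read_tidy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  as.data.frame(data.table::fread(path, sep = ",",
                                  skip = if (startsWith(first, "#")) 1L else 0L))
}

#' Read an Axon ABF current-clamp file (optional adapter)
#'
#' Delegates to the bundled Python converter (`inst/py/abf2sweep.py`,
#' requires the `pyabf` package) which rewrites the file in the neutral
#' sweep-set exchange format; the result is then read with
#' [read_sweepset()].  Errors with guidance when Python or pyabf is not
#' available.
#'
#' @param path ABF file.
#' @param python Python interpreter to use.
#' @return a [sweep_set()].
#' @export
read_sweepset_abf <- function(path, python = Sys.which("python")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!nzchar(python))
    stop("ABF support needs a Python interpreter with the 'pyabf' package")
  script <- system.file("py", "abf2sweep.py", package = "v1phys")
  out <- tempfile(fileext = ".csv")
  status <- system2(python, c(script, shQuote(path), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("ABF conversion failed: ", paste(status, collapse = "\n"))
  read_sweepset(out)
}
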