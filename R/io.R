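#' Read and write force-extension traces
#'
#' Traces are stored as delimited text with columns `time_s`,
#' `extension_nm`, `force_pN`, one file per pull; metadata lines prefixed
#' with `#` (key: value) become attributes.  In memory the columns are
#' `time`, `extension`, `force` in s, nm, pN.
#'
#' @param path File path.
#' @param trace A trace tibble (see [simulate_fx_trace()]).
#' @param metadata Optional named list written as `# key: value` header
#'   lines.
#' @return `read_fx_trace()` returns the trace tibble (metadata in
#'   attributes); `write_fx_trace()` returns `path` invisibly.
#' @export
read_fx_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  dat <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  req <- c("time_s", "extension_nm", "force_pN")
  if (!all(req %in% names(dat)))
    abort(sprintf("Trace file must have columns %s.", paste(req, collapse = ", ")))
  out <- tibble::tibble(time = dat$time_s, extension = dat$extension_nm,
                        force = dat$force_pN)
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(kv[2]))
      attr(out, kv[1]) <- if (is.na(val)) kv[2] else val
    }
  }
  out
}

#' @rdname read_fx_trace
#' @export
write_fx_trace <- function(trace, path, metadata = NULL) {
  check_trace(trace)
  if (is.null(metadata)) {
    sr <- attr(trace, "sampling_rate")
    if (!is.null(sr)) metadata <- list(sampling_rate = sr)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  utils::write.table(
    data.frame(time_s = trace$time, extension_nm = trace$extension,
               force_pN = trace$force),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rupture-event tables
#'
#' Delimited text with columns `condition`, `loading_rate_pN_per_s`,
#' `force_pN` (and optionally `loading_rate_measured_pN_per_s`); in memory
#' the columns are `condition`, `loading_rate`, `loading_rate_measured`,
#' `force`.
#'
#' @param path File path.
#' @param data Rupture-event tibble (see [simulate_rupture_forces()]).
#' @return `read_rupture_table()` returns the tibble;
#'   `write_rupture_table()` returns `path` invisibly.
#' @export
read_rupture_table <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", comment.char = "#")
  req <- c("condition", "loading_rate_pN_per_s", "force_pN")
  if (!all(req %in% names(dat)))
    abort(sprintf("Rupture table must have columns %s.", paste(req, collapse = ", ")))
  tibble::tibble(
    condition = as.character(dat$condition),
    loading_rate = dat$loading_rate_pN_per_s,
    loading_rate_measured = dat$loading_rate_measured_pN_per_s %||%
      dat$loading_rate_pN_per_s,
    force = dat$force_pN)
}

#' @rdname read_rupture_table
#' @export
write_rupture_table <- function(data, path) {
  stopifnot(all(c("condition", "loading_rate", "force") %in% names(data)))
  out <- data.frame(
    condition = data$condition,
    loading_rate_pN_per_s = data$loading_rate,
    loading_rate_measured_pN_per_s = data$loading_rate_measured %||%
      data$loading_rate,
    force_pN = data$force)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write BLI sensorgrams
#'
#' Delimited text with columns `time_s`, `signal_nm`, `phase` and
#' optionally `role`; in memory `time`, `signal`, `phase` (`role` as an
#' attribute if present).
#'
#' @param path File path.
#' @param s Sensorgram tibble.
#' @param role Optional role string written alongside
#'   (experimental / drift_control / binding_control).
#' @return `read_sensorgram()` returns the tibble; `write_sensorgram()`
#'   returns `path` invisibly.
#' @export
read_sensorgram <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", comment.char = "#")
  req <- c("time_s", "signal_nm", "phase")
  if (!all(req %in% names(dat)))
    abort(sprintf("Sensorgram file must have columns %s.", paste(req, collapse = ", ")))
  out <- tibble::tibble(time = dat$time_s, signal = dat$signal_nm,
                        phase = as.character(dat$phase))
  if ("role" %in% names(dat)) attr(out, "role") <- as.character(dat$role[1])
  check_sensorgram(out)
  out
}

#' @rdname read_sensorgram
#' @export
write_sensorgram <- function(s, path, role = NULL) {
  check_sensorgram(s)
  out <- data.frame(time_s = s$time, signal_nm = s$signal, phase = s$phase)
  if (!is.null(role)) out$role <- role
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param report A list, e.g. the `report` element of
#'   [filter_single_tethers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a computation bitwise: the
#' command label, a hash of the configuration, the master seed, the package
#' version and the per-stage parameter record.
#'
#' @param command Command or stage label.
#' @param config A list of all parameters in effect.
#' @param seed The master seed used.
#' @param outputs Character vector of output paths.
#' @param path Optional path; when given the manifest is also written as
#'   JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(command, config, seed, outputs = character(),
                         path = NULL) {
  man <- list(command = command,
              config_hash = rlang::hash(config),
              seed = seed,
              package_version = as.character(utils::packageVersion("tiplink")),
              config = config,
              outputs = outputs,
              timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(man))
  }
  man
}
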