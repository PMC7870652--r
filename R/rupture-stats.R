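#' Detect the rupture in a force-extension trace
#'
#' A rupture is an abrupt drop to baseline: a force decrease larger than
#' five times the per-trace noise SD within at most three samples.  The
#' noise SD is estimated robustly from first differences
#' (`mad(diff(force)) / sqrt(2)`).
#'
#' @param trace A force-extension tibble with columns `time`, `extension`,
#'   `force` (s, nm, pN), as produced by [simulate_fx_trace()] or
#'   [read_fx_trace()].
#' @param drop_factor Detection threshold in units of the noise SD.
#' @return A list: `index` (last sample before the drop), `rupture_force`
#'   (pN), `noise_sd` (pN).  Errors with "no rupture detected" when no
#'   qualifying drop exists.
#' @export
detect_rupture <- function(trace, drop_factor = 5) {
  check_trace(trace)
  f <- trace$force
  n <- length(f)
  if (n < 5L) abort("no rupture detected: trace too short.")
  noise_sd <- mad(diff(f)) / sqrt(2)
  # largest drop achieved within <= 3 samples
  drop <- vapply(seq_len(n - 1L), function(i) {
    f[i] - min(f[(i + 1):min(i + 3, n)])
  }, numeric(1))
  i <- which.max(drop)
  if (!(drop[i] > drop_factor * noise_sd))
    abort("no rupture detected: no force drop exceeds the noise threshold.")
  list(index = i, rupture_force = f[i], noise_sd = noise_sd)
}

check_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time", "extension", "force") %in% names(trace)))
    abort("`trace` must have columns `time`, `extension`, `force`.")
  if (is.unsorted(trace$time, strictly = TRUE))
    abort("`trace$time` must be strictly increasing.")
  invisible(trace)
}

#' Fit an extensible worm-like chain to a pulling trace
#'
#' Detects the rupture, then least-squares fits the extensible Marko-Siggia
#' interpolation [wlc_force()] to the pre-rupture ramp, estimating contour
#' length, persistence length and stretch modulus.  The rupture force is the
#' force immediately before the detected drop.
#'
#' @inheritParams detect_rupture
#' @param min_force Ramp points below this force (pN) are excluded from the
#'   fit (the slack, noise-dominated region).
#' @param start Optional named list of starting values (`Lc`, `Lp`, `K`).
#' @return An object of class `wlc_fit` with fields `contour_length`,
#'   `persistence_length`, `stretch_modulus` (nm, nm, pN), `rupture_force`
#'   (pN), `residual` (RMS, pN), `n` and `convergence`.  Supports [tidy()]
#'   and [glance()].
#' @export
fit_wlc <- function(trace, min_force = 0.5, start = NULL) {
  det <- detect_rupture(trace)
  ramp <- trace[seq_len(det$index), ]
  ramp <- ramp[ramp$force > min_force, ]
  if (nrow(ramp) < 20L) abort("fit divergence: too few ramp points above `min_force`.")
  x_max <- max(ramp$extension)
  s <- list(Lc = x_max * 1.03, Lp = 50, K = 1500)
  if (!is.null(start)) s[names(start)] <- start
  fit <- tryCatch(
    minpack.lm::nlsLM(
      force ~ wlc_force(extension, Lc, Lp, K),
      data = ramp, start = s,
      lower = c(Lc = x_max * 1.0005, Lp = 0.5, K = 50),
      upper = c(Lc = x_max * 5, Lp = 500, K = 1e5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("fit divergence: ", conditionMessage(e))))
  est <- coef(fit)
  structure(
    list(contour_length = unname(est["Lc"]),
         persistence_length = unname(est["Lp"]),
         stretch_modulus = unname(est["K"]),
         rupture_force = det$rupture_force,
         residual = sqrt(mean(stats::residuals(fit)^2)),
         n = nrow(ramp),
         convergence = fit$convInfo$isConv %||% TRUE),
    class = "wlc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit>  Lc = %.1f nm  Lp = %.1f nm  K = %.0f pN  rupture = %.2f pN  (rms %.3g pN, n = %d)\n",
              x$contour_length, x$persistence_length, x$stretch_modulus,
              x$rupture_force, x$residual, x$n))
  invisible(x)
}

#' @export
tidy.wlc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("contour_length", "persistence_length", "stretch_modulus"),
    estimate = c(x$contour_length, x$persistence_length, x$stretch_modulus),
    unit = c("nm", "nm", "pN"))
}

#' @export
glance.wlc_fit <- function(x, ...) {
  tibble::tibble(rupture_force = x$rupture_force, residual = x$residual,
                 n = x$n, converged = isTRUE(x$convergence))
}

#' Quality-control filter for single-tether events
#'
#' Keeps only fits whose contour and persistence lengths fall inside the
#' acceptance intervals, the standard check that a pulling event involved
#' exactly one tether (double tethers halve the apparent contour length;
#' nonspecific attachments distort persistence length).  Deterministic and
#' idempotent.
#'
#' @param fits A tibble with columns `contour_length` and
#'   `persistence_length` (one row per event), e.g. rows of
#'   `tidy()`-ed [fit_wlc()] results or any event table.
#' @param contour_range,persistence_range Closed acceptance intervals, nm.
#' @return A list: `accepted` (the surviving rows) and `report` (counts of
#'   rejections by reason, JSON-serializable).
#' @export
filter_single_tethers <- function(fits, contour_range, persistence_range) {
  if (!is.data.frame(fits) || nrow(fits) == 0L) abort("`fits` must be a non-empty data frame.")
  if (!all(c("contour_length", "persistence_length") %in% names(fits)))
    abort("`fits` must have columns `contour_length` and `persistence_length`.")
  stopifnot(length(contour_range) == 2L, length(persistence_range) == 2L)
  bad_contour <- fits$contour_length < contour_range[1] |
    fits$contour_length > contour_range[2]
  bad_persistence <- fits$persistence_length < persistence_range[1] |
    fits$persistence_length > persistence_range[2]
  accepted <- fits[!bad_contour & !bad_persistence, , drop = FALSE]
  list(
    accepted = tibble::as_tibble(accepted),
    report = list(
      n_input = nrow(fits),
      n_accepted = nrow(accepted),
      n_rejected = sum(bad_contour | bad_persistence),
      rejected_contour = sum(bad_contour),
      rejected_persistence = sum(bad_persistence),
      contour_range = as.numeric(contour_range),
      persistence_range = as.numeric(persistence_range)))
}

#' Loading rate from the linear force regime of a trace
#'
#' The loading rate is the slope of a least-squares line over the final
#' contiguous near-linear window of the force ramp preceding rupture.  The
#' window starts as the last quarter of the ramp and is grown backwards
#' while the linear fit shows no lack of fit (residual SD within 25% of the
#' per-trace noise SD estimated from first differences); if the starting
#' window already shows curvature it is shrunk instead.  The lack-of-fit
#' criterion is used rather than an R^2 threshold because R^2 compares the
#' residual to the (window-dependent) signal variance and admits grossly
#' curved windows on clean traces.
#'
#' @inheritParams detect_rupture
#' @param min_samples Minimum admissible window length.
#' @return Loading rate, pN s^-1.  Errors if no admissible window of at
#'   least `min_samples` exists.
#' @export
extract_loading_rate <- function(trace, min_samples = 10) {
  det <- detect_rupture(trace)
  ramp <- trace[seq_len(det$index), ]
  n <- nrow(ramp)
  if (n < min_samples) abort("linear regime shorter than 10 samples.")
  tol <- 1.25 * max(det$noise_sd, 1e-6 * max(abs(ramp$force)))
  ok <- function(i0) {
    w <- ramp[i0:n, ]
    fit <- lm(force ~ time, data = w)
    sqrt(mean(stats::residuals(fit)^2)) <= tol
  }
  i0 <- max(1L, n - max(min_samples, ceiling(n / 4)) + 1L)
  if (ok(i0)) {
    step <- max(1L, ceiling(n / 20))
    while (i0 > 1L && ok(max(1L, i0 - step))) i0 <- max(1L, i0 - step)
  } else {
    while (n - i0 + 1L > min_samples && !ok(i0)) {
      i0 <- i0 + max(1L, ceiling((n - i0) / 10))
    }
    if (!ok(i0)) abort("linear regime shorter than 10 samples.")
  }
  unname(coef(lm(force ~ time, data = ramp[i0:n, ]))[2])
}

#' Most-probable rupture force by kernel density estimation
#'
#' Estimates the rupture-force probability density with a Gaussian kernel
#' (Silverman's rule bandwidth by default), takes the mode on a refined
#' grid with local parabolic interpolation, and reports the selected
#' bandwidth as the error of the mode -- the convention used for the
#' dynamic force spectrum points.
#'
#' @param forces Rupture forces, pN (n >= 5).
#' @param bw Kernel bandwidth, pN; default Silverman's rule ([bw.nrd0()]).
#' @param n_grid KDE evaluation grid size.
#' @return A one-row tibble: `mode_force`, `error` (the bandwidth),
#'   `n_events`.
#' @export
estimate_mode_kde <- function(forces, bw = NULL, n_grid = 2048) {
  forces <- as.numeric(forces)
  if (length(forces) < 5L) abort("`forces` must contain at least 5 events.")
  bw <- bw %||% bw.nrd0(forces)
  d <- density(forces, bw = bw, n = n_grid)
  tibble::tibble(mode_force = refine_mode(d$x, d$y), error = bw,
                 n_events = length(forces))
}

#' Dynamic-force-spectrum points from a rupture table
#'
#' Groups rupture events by condition and nominal loading rate, and reduces
#' each group to a mode point: the KDE most-probable rupture force, its
#' bandwidth error, and the mean measured loading rate (the fit abscissa).
#'
#' @param data Rupture-event tibble with columns `condition`,
#'   `loading_rate`, `force`, and optionally `loading_rate_measured`
#'   (defaults to `loading_rate`).
#' @param min_events Groups smaller than this are dropped.
#' @return A tibble with one row per group: `condition`, `loading_rate`,
#'   `mean_loading_rate`, `mode_force`, `error`, `n_events`.
#' @export
rupture_modes <- function(data, min_events = 5) {
  stopifnot(all(c("condition", "loading_rate", "force") %in% names(data)))
  if (!"loading_rate_measured" %in% names(data))
    data$loading_rate_measured <- data$loading_rate
  data |>
    dplyr::group_by(.data$condition, .data$loading_rate) |>
    dplyr::filter(dplyr::n() >= min_events) |>
    dplyr::summarise(
      mean_loading_rate = mean(.data$loading_rate_measured),
      mode = estimate_mode_kde(.data$force),
      .groups = "drop") |>
    tidyr::unpack("mode", names_sep = NULL) |>
    dplyr::select("condition", "loading_rate", "mean_loading_rate",
                  "mode_force", "error", "n_events")
}

#' Freedman-Diaconis histogram with a systematic bin-offset scan
#'
#' Bin width is the Freedman-Diaconis rule `2 * IQR * n^(-1/3)`.  The bin
#' origin is then scanned over a grid of offsets within one bin width and
#' the offset that maximizes the count in the modal bin is selected (ties
#' broken toward the smaller offset), so the histogram mode is as sharp as
#' the data allow.  A Gaussian KDE is returned alongside for overlay.
#'
#' @param forces Rupture forces, pN (n >= 5).
#' @param n_offsets Number of offsets scanned in `[0, bin_width)` (>= 20).
#' @return An object of class `fd_histogram`: list with `bins` (tibble
#'   `mid`, `count`), `bin_width`, `offset`, `density` (tibble `force`,
#'   `density`), `n`.
#' @export
fd_histogram <- function(forces, n_offsets = 21) {
  forces <- as.numeric(forces)
  if (length(forces) < 5L) abort("`forces` must contain at least 5 events.")
  iqr <- stats::IQR(forces)
  if (iqr <= 0) abort("zero IQR: all values equal; cannot bin.")
  n <- length(forces)
  width <- 2 * iqr * n^(-1 / 3)
  offsets <- seq(0, width, length.out = n_offsets + 1L)[seq_len(n_offsets)]
  best <- NULL
  for (off in offsets) {
    first <- floor((min(forces) - off) / width)
    breaks <- off + width * seq(first, ceiling((max(forces) - off) / width))
    if (max(breaks) <= max(forces)) breaks <- c(breaks, max(breaks) + width)
    counts <- as.integer(table(cut(forces, breaks, right = FALSE,
                                   include.lowest = TRUE)))
    if (is.null(best) || max(counts) > best$peak) {
      best <- list(peak = max(counts), offset = off, breaks = breaks,
                   counts = counts)
    }
  }
  d <- density(forces, bw = bw.nrd0(forces), n = 512)
  structure(
    list(bins = tibble::tibble(
           mid = utils::head(best$breaks, -1) + width / 2,
           count = best$counts),
         bin_width = width, offset = best$offset,
         density = tibble::tibble(force = d$x, density = d$y),
         n = n),
    class = "fd_histogram")
}

#' @export
print.fd_histogram <- function(x, ...) {
  cat(sprintf("<fd_histogram>  %d events, bin width %.3g pN, offset %.3g pN, modal count %d\n",
              x$n, x$bin_width, x$offset, max(x$bins$count)))
  invisible(x)
}
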