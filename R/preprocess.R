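# Pre-processing of raw binocular gaze recordings: eye averaging, blink
# NaN-extension, calibration-based normalization to % units, and usability
# flagging of epochs.

#' Average the two eyes into a cyclopean gaze trace
#'
#' Samplewise mean of the left- and right-eye channels. A NaN in either eye
#' propagates to the output, so blink stretches survive averaging.
#'
#' @param left,right Equal-length numeric traces on a common time axis.
#' @return Numeric trace of the same length.
#' @export
merge_eyes <- function(left, right) {
  if (length(left) != length(right))
    stop("input error: left and right traces differ in length")
  (left + right) / 2
}

#' Extend NaN stretches around blinks
#'
#' Every maximal run of NaN samples is widened by `pad_ms` on each side
#' (100 ms by default) to eliminate residual blink artefacts at blink edges;
#' overlapping extensions merge into a single NaN run. No other samples are
#' altered. The returned trace carries a `blinks_masked` attribute and the
#' operation is idempotent: a trace that has already been masked is returned
#' unchanged rather than widened again.
#'
#' @param x Numeric trace, uniformly sampled.
#' @param sampling_rate Hz.
#' @param pad_ms Extension on each side of every NaN run, ms.
#' @return The trace with widened NaN runs.
#' @export
mask_blinks <- function(x, sampling_rate = 1000, pad_ms = 100) {
  if (isTRUE(attr(x, "blinks_masked"))) return(x)
  isna <- is.na(x)
  if (!any(isna)) {
    attr(x, "blinks_masked") <- TRUE
    return(x)
  }
  pad <- round(pad_ms * sampling_rate / 1000)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- rep(FALSE, length(x))
  for (i in which(r$values)) {
    lo <- max(1L, starts[i] - pad)
    hi <- min(length(x), ends[i] + pad)
    bad[lo:hi] <- TRUE
  }
  x[bad] <- NaN
  attr(x, "blinks_masked") <- TRUE
  x
}

#' Build a calibration reference from a calibration recording
#'
#' For each of the seven labelled calibration positions, takes the median
#' cyclopean gaze in the 500-1000 ms window after the point's onset (allowing
#' the participant 500 ms to reach the point), then fits an affine map from
#' raw horizontal coordinates to % units by least squares against the nominal
#' positions (centre = 0%, lateral points = +/-100% at the item
#' eccentricity). The vertical axis is fitted the same way (used only by the
#' binocular 2-D detector).
#'
#' @param cal A `calibration_recording` (see [generate_calibration()]): needs
#'   `samples` (time_ms, label, lx, ly, rx, ry) and `onsets` (label,
#'   onset_ms).
#' @param window_ms Sub-window after point onset used for the medians, ms.
#' @return An object of class `calibration_reference`: list with `medians`
#'   (per-label median x/y), and affine coefficients `x_offset`, `x_scale`,
#'   `y_offset`, `y_scale` such that `pct = offset + scale * raw`.
#' @export
build_calibration_reference <- function(cal, window_ms = c(500, 1000)) {
  required <- c("left-top", "left-middle", "left-bottom",
                "right-top", "right-middle", "right-bottom", "centre")
  missing <- setdiff(required, cal$onsets$label)
  if (length(missing) > 0L)
    stop("calibration error: missing position label(s): ",
         paste(missing, collapse = ", "))
  med <- lapply(required, function(lab) {
    onset <- cal$onsets$onset_ms[cal$onsets$label == lab][1]
    sel <- cal$samples$label == lab &
      cal$samples$time_ms >= onset + window_ms[1] &
      cal$samples$time_ms <= onset + window_ms[2]
    s <- cal$samples[sel, ]
    data.frame(label = lab,
               x = stats::median(merge_eyes(s$lx, s$rx), na.rm = TRUE),
               y = stats::median(merge_eyes(s$ly, s$ry), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  med <- do.call(rbind, med)
  nominal_x <- c(-100, -100, -100, 100, 100, 100, 0)
  nominal_y <- c(100, 0, -100, 100, 0, -100, 0)
  fx <- stats::lm.fit(cbind(1, med$x), nominal_x)$coefficients
  fy <- stats::lm.fit(cbind(1, med$y), nominal_y)$coefficients
  out <- list(medians = med,
              x_offset = unname(fx[1]), x_scale = unname(fx[2]),
              y_offset = unname(fy[1]), y_scale = unname(fy[2]))
  class(out) <- "calibration_reference"
  out
}

#' Normalize a raw gaze trace to % units
#'
#' Applies the affine map of a [build_calibration_reference()] so that 0%
#' is the screen centre and +/-100% the centres of the right/left memory
#' items. NaN samples are preserved.
#'
#' @param x Raw gaze trace.
#' @param reference A `calibration_reference`.
#' @param axis `"x"` (horizontal, default) or `"y"`.
#' @return Normalized trace in % units.
#' @export
normalize_gaze <- function(x, reference, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") reference$x_offset + reference$x_scale * x
  else reference$y_offset + reference$y_scale * x
}

#' Invert the calibration normalization
#'
#' @inheritParams normalize_gaze
#' @param pct Normalized trace in % units.
#' @return Raw-coordinate trace.
#' @export
denormalize_gaze <- function(pct, reference, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") (pct - reference$x_offset) / reference$x_scale
  else (pct - reference$y_offset) / reference$y_scale
}

#' Construct a gaze epoch
#'
#' @param time_ms Strictly increasing, uniformly spaced time axis relative to
#'   cue onset, ms.
#' @param x_pct Normalized horizontal gaze, % units (NaN within blinks).
#' @param cued_side `"left"` or `"right"`.
#' @return Object of class `gaze_epoch`.
#' @export
gaze_epoch <- function(time_ms, x_pct, cued_side) {
  if (length(time_ms) != length(x_pct))
    stop("input error: time and position differ in length")
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
    stop("input error: time axis must be strictly increasing and uniform")
  structure(list(time_ms = time_ms, x_pct = x_pct,
                 cued_side = match.arg(cued_side, c("left", "right"))),
            class = "gaze_epoch")
}

#' Flag an epoch as usable
#'
#' A trial is usable only if its eye trace contains no NaN anywhere in the
#' 0-600 ms post-cue window (closed interval); NaNs here typically reflect
#' blinks or loss of the eyes.
#'
#' @param epoch A [gaze_epoch()].
#' @param window_ms Usability window, ms (default `c(0, 600)`).
#' @return `TRUE` if no NaN sample falls inside the window.
#' @export
mark_usable <- function(epoch, window_ms = c(0, 600)) {
  t <- epoch$time_ms
  if (t[1] > window_ms[1] || t[length(t)] < window_ms[2])
    stop("input error: epoch does not span the usability window")
  sel <- t >= window_ms[1] & t <= window_ms[2]
  !anyNA(epoch$x_pct[sel])
}

#' Read gaze samples from a CSV file
#'
#' Expects the documented dialect: columns `time_ms, lx, ly, rx, ry` (missing
#' samples as empty fields or NaN).
#'
#' @param path CSV file path.
#' @return Data frame with those five columns.
#' @export
read_gaze_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("time_ms", "lx", "ly", "rx", "ry")
  if (!all(need %in% names(d)))
    stop("input error: gaze CSV must have columns ",
         paste(need, collapse = ", "))
  d[need]
}

#' Parse sample lines of an EyeLink ASC export
#'
#' Minimal binocular sample parser: keeps lines that start with a numeric
#' timestamp and reads `time, xl, yl, pl, xr, yr, pr`; missing-data markers
#' (`.`) become NaN. Event lines (ESACC/EBLINK/etc.) are ignored.
#'
#' @param path ASC file path.
#' @return Data frame with columns `time_ms, lx, ly, rx, ry`.
#' @export
parse_eyelink_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^\\s*[0-9]+(\\s|\t)", lines)
  if (!any(keep))
    return(data.frame(time_ms = numeric(), lx = numeric(), ly = numeric(),
                      rx = numeric(), ry = numeric()))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  num <- function(v) suppressWarnings(ifelse(v == ".", NaN, as.numeric(v)))
  parsed <- t(vapply(fields, function(f) {
    f <- c(f, rep(".", 7L))[1:7]
    c(num(f[1]), num(f[2]), num(f[3]), num(f[5]), num(f[6]))
  }, numeric(5)))
  data.frame(time_ms = parsed[, 1], lx = parsed[, 2], ly = parsed[, 3],
             rx = parsed[, 4], ry = parsed[, 5])
}
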