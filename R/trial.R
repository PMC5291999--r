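#' Marker trial bundle
#'
#' Container for one motion-capture trial: a long-format marker table
#' (100 Hz), an optional vertical ground-reaction-force table (1500 Hz), a
#' marker-label registry mapping labels to segments, and trial metadata.
#' Coordinates are millimetres, force newtons. Frame indices are 0-based
#' and contiguous; the time of frame k is k / `rate` seconds and of force
#' sample j is j / `force_rate` seconds.
#'
#' @param markers data.frame with columns `frame`, `label`, `x`, `y`, `z`.
#'   Missing marker samples are explicit `NA`s, never dropped rows.
#' @param registry data.frame with columns `label`, `segment` (segment
#'   `"anatomical"` marks the standing-trial calibration markers).
#' @param trial_id character id.
#' @param kind one of `"walking"`, `"standing_reference"`, `"stn_standing"`.
#' @param force optional data.frame with columns `sample`, `fz`; required
#'   for walking trials.
#' @param rate,force_rate sampling rates in Hz.
#' @param meta optional list of generator ground truth / provenance.
#' @return object of class `marker_trial`.
#' @export
marker_trial <- function(markers, registry, trial_id, kind, force = NULL,
                         rate = 100, force_rate = 1500, meta = list()) {
  kind <- match.arg(kind, c("walking", "standing_reference", "stn_standing"))
  need <- c("frame", "label", "x", "y", "z")
  if (!is.data.frame(markers) || !all(need %in% names(markers))) {
    fk_stop("`markers` must have columns frame, label, x, y, z",
            "footkin_schema_error")
  }
  unknown <- setdiff(unique(markers$label), registry$label)
  if (length(unknown)) {
    fk_stop(paste0("marker labels not in registry: ",
                   paste(unknown, collapse = ", ")),
            "footkin_schema_error")
  }
  frames <- sort(unique(markers$frame))
  if (length(frames) == 0L ||
      !isTRUE(all(frames == seq(0L, length(frames) - 1L)))) {
    fk_stop("frame indices must be contiguous from 0", "footkin_schema_error")
  }
  reg <- registry[registry$label %in% markers$label, , drop = FALSE]
  segs <- setdiff(unique(reg$segment), "anatomical")
  cnt <- table(reg$segment[reg$segment != "anatomical"])
  short <- names(cnt)[cnt < 3L | (names(cnt) == "leg" & cnt < 4L)]
  if (length(short)) {
    fk_stop(paste0("segments with too few markers (need 3, leg 4): ",
                   paste(short, collapse = ", ")), "footkin_model_error")
  }
  if (kind == "walking" && is.null(force)) {
    fk_stop("walking trials require force data", "footkin_schema_error")
  }
  if (!is.null(force) &&
      (!is.data.frame(force) || !all(c("sample", "fz") %in% names(force)))) {
    fk_stop("`force` must have columns sample, fz", "footkin_schema_error")
  }
  structure(list(trial_id = as.character(trial_id), kind = kind,
                 rate = rate, force_rate = force_rate,
                 markers = markers[order(markers$frame, markers$label), ,
                                   drop = FALSE],
                 force = force, registry = reg, meta = meta),
            class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  nf <- length(unique(x$markers$frame))
  cat("<marker_trial '", x$trial_id, "'> ", x$kind, ", ", nf, " frames @ ",
      x$rate, " Hz, ", length(unique(x$markers$label)), " markers",
      if (!is.null(x$force)) sprintf(", force %d samples @ %g Hz",
                                     nrow(x$force), x$force_rate),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a [marker_trial()].
#' @return integer frame count.
#' @export
n_frames <- function(trial) length(unique(trial$markers$frame))

# markers of one frame as a labelled matrix (rows = labels)
frame_matrix <- function(trial, frame, labels = NULL) {
  mk <- trial$markers[trial$markers$frame == frame, , drop = FALSE]
  if (!is.null(labels)) mk <- mk[match(labels, mk$label), , drop = FALSE]
  m <- as.matrix(mk[, c("x", "y", "z")])
  rownames(m) <- mk$label
  m
}

# fast access: array n_frames x n_labels x 3 for the given labels
marker_array <- function(trial, labels) {
  mk <- trial$markers[trial$markers$label %in% labels, , drop = FALSE]
  nf <- max(mk$frame) + 1L
  arr <- array(NA_real_, c(nf, length(labels), 3L),
               dimnames = list(NULL, labels, c("x", "y", "z")))
  idx <- cbind(mk$frame + 1L, match(mk$label, labels))
  arr[cbind(idx, 1L)] <- mk$x
  arr[cbind(idx, 2L)] <- mk$y
  arr[cbind(idx, 3L)] <- mk$z
  arr
}
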