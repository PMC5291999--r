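#' Built-in six-segment foot and leg model
#'
#' Versioned description of the marker set used throughout the package:
#' segment chain, rigid-cluster marker offsets and the anatomical
#' calibration markers of the standing reference trial. The lab frame is
#' x mediolateral, y direction of progression (anterior), z vertical up;
#' units are millimetres. The left foot is modelled.
#'
#' The chain is leg -> calcaneus -> midfoot -> \{medial forefoot -> hallux,
#' lateral forefoot\}. Each foot segment carries a rigid triad of markers
#' roughly 50 mm across (the leg carries four); the standing reference
#' trial additionally carries anatomical markers on the medial/lateral
#' malleoli and knee joint margins from which the leg local coordinate
#' system is constructed.
#'
#' Joints are named after their distal segment: `rearfoot`
#' (calcaneus-leg), `midfoot` (midfoot-calcaneus), `medial_forefoot` and
#' `lateral_forefoot` (each vs midfoot) and `hallux` (hallux-medial
#' forefoot, the 1st MPJ).
#'
#' @return an object of class `foot_model`: a list with elements
#'   `version`, `segments` (per segment: `markers`, 3-column matrix of
#'   standing-pose marker positions; `origin`; `parent`), `anatomical`
#'   (named list of 4 points), `joints` (data.frame `joint`, `proximal`,
#'   `distal`) and `planes`.
#' @export
#' @examples
#' m <- foot_model()
#' names(m$segments)
foot_model <- function() {
  seg <- function(center, offsets, parent, origin) {
    mk <- sweep(offsets, 2, center, `+`)
    list(markers = mk, origin = origin, parent = parent)
  }
  tri <- function(a, b, c) {
    m <- rbind(a, b, c, deparse.level = 0)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  }
  segments <- list(
    leg = list(
      markers = {
        m <- rbind(c(-30, 45, 260), c(30, 45, 255), c(26, 50, 175),
                   c(-26, 48, 170))
        colnames(m) <- c("x", "y", "z")
        rownames(m) <- paste0("leg_", 1:4)
        m
      },
      origin = c(0, 0, 80), parent = NA_character_
    ),
    calcaneus = seg(c(0, -70, 40),
                    tri(c(0, -5, 33), c(28, 2, -16), c(-28, 2, -16)),
                    "leg", c(0, -55, 35)),
    midfoot = seg(c(0, 18, 45),
                  tri(c(0, 7, 32), c(29, -4, -16), c(-29, -4, -16)),
                  "calcaneus", c(0, 10, 38)),
    medial_forefoot = seg(c(28, 62, 28),
                          tri(c(0, 32, 7), c(28, -16, -4), c(-28, -16, -4)),
                          "midfoot", c(22, 40, 28)),
    lateral_forefoot = seg(c(-32, 52, 22),
                           tri(c(0, 32, 6), c(28, -16, 0), c(-28, -16, -6)),
                           "midfoot", c(-26, 34, 24)),
    hallux = seg(c(30, 104, 16),
                 tri(c(0, 34, 5), c(30, -17, 0), c(-30, -17, -3)),
                 "medial_forefoot", c(28, 85, 18))
  )
  for (s in names(segments)) {
    if (is.null(rownames(segments[[s]]$markers))) {
      rownames(segments[[s]]$markers) <-
        paste0(s, "_", seq_len(nrow(segments[[s]]$markers)))
    }
  }
  anatomical <- list(
    med_malleolus = c(40, 0, 80),
    lat_malleolus = c(-40, 0, 80),
    med_knee = c(46, 0, 470),
    lat_knee = c(-46, 0, 470)
  )
  joints <- data.frame(
    joint = c("rearfoot", "midfoot", "medial_forefoot", "lateral_forefoot",
              "hallux"),
    proximal = c("leg", "calcaneus", "midfoot", "midfoot", "medial_forefoot"),
    distal = c("calcaneus", "midfoot", "medial_forefoot", "lateral_forefoot",
               "hallux"),
    stringsAsFactors = FALSE
  )
  structure(list(version = "1.0", segments = segments,
                 anatomical = anatomical, joints = joints,
                 planes = c("sagittal", "frontal", "transverse")),
            class = "foot_model")
}

#' @export
print.foot_model <- function(x, ...) {
  cat("<foot_model v", x$version, "> ", length(x$segments),
      " segments, ", nrow(x$joints), " joints\n", sep = "")
  for (s in names(x$segments)) {
    cat("  ", s, ": ", nrow(x$segments[[s]]$markers), " markers\n", sep = "")
  }
  invisible(x)
}

#' Marker label registry for a model
#'
#' Maps every marker label of a model (cluster and anatomical) to its
#' segment; anatomical calibration markers are registered under the
#' pseudo-segment `"anatomical"`.
#'
#' @param model a [foot_model()].
#' @return data.frame with columns `label`, `segment`.
#' @export
foot_marker_registry <- function(model = foot_model()) {
  lab <- unlist(lapply(names(model$segments), function(s) {
    stats::setNames(rep(s, nrow(model$segments[[s]]$markers)),
                    rownames(model$segments[[s]]$markers))
  }))
  lab <- c(lab, stats::setNames(rep("anatomical", length(model$anatomical)),
                                names(model$anatomical)))
  data.frame(label = names(lab), segment = unname(lab),
             stringsAsFactors = FALSE)
}

joint_names <- function() {
  c("rearfoot", "midfoot", "medial_forefoot", "lateral_forefoot", "hallux")
}

plane_names <- function() c("sagittal", "frontal", "transverse")
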