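#' Default prefrontal optode montage
#'
#' A reconstructed 20-channel prefrontal montage with eight emitters and seven
#' detectors, laid out as a staggered two-row band centred on the FpZ
#' reference landmark (international 10-20 system). Optodes alternate
#' emitter/detector along each row (in-row spacing 2.8 cm, rows 2.4 cm apart
#' with a 1.4 cm stagger) so that every first-neighbour emitter-detector pair
#' forms a measurement channel with separation 2.78-2.8 cm. The published
#' montage is only available as a schematic, so the exact pairing here is a
#' plausible reconstruction with the stated optode counts and separations.
#'
#' Coordinates are in a flat 2-D head-schematic frame (cm), origin at FpZ.
#' Channels are numbered 1-20 left to right (ties: front row first).
#'
#' @return An object of class `fnirs_montage`: a list with data frames
#'   `emitters` (label, x, y), `detectors` (label, x, y) and `channels`
#'   (channel, emitter, detector, x, y midpoint, separation), plus the
#'   `reference` landmark label.
#' @examples
#' m <- default_montage()
#' nrow(m$channels)           # 20
#' range(m$channels$separation)
#' @export
default_montage <- function() {
  dx <- 2.8
  # Front row (y = +1.2): E D E D E D E D ; back row (y = -1.2): E D E D E D E
  front_x <- dx * (0:7) - 9.8
  back_x <- dx * (0:6) + 1.4 - 9.8
  front <- data.frame(
    label = c("E1", "D1", "E2", "D2", "E3", "D3", "E4", "D4"),
    x = front_x, y = 1.2,
    type = rep(c("emitter", "detector"), 4), stringsAsFactors = FALSE)
  back <- data.frame(
    label = c("E5", "D5", "E6", "D6", "E7", "D7", "E8"),
    x = back_x, y = -1.2,
    type = rep_len(c("emitter", "detector"), 7), stringsAsFactors = FALSE)
  opt <- rbind(front, back)

  emitters <- opt[opt$type == "emitter", c("label", "x", "y")]
  detectors <- opt[opt$type == "detector", c("label", "x", "y")]
  rownames(emitters) <- rownames(detectors) <- NULL

  # Channels: all emitter-detector pairs closer than 3 cm.
  pairs <- expand.grid(e = seq_len(nrow(emitters)), d = seq_len(nrow(detectors)))
  sep <- sqrt((emitters$x[pairs$e] - detectors$x[pairs$d])^2 +
                (emitters$y[pairs$e] - detectors$y[pairs$d])^2)
  keep <- sep <= 3.0
  ch <- data.frame(
    emitter = emitters$label[pairs$e[keep]],
    detector = detectors$label[pairs$d[keep]],
    x = (emitters$x[pairs$e[keep]] + detectors$x[pairs$d[keep]]) / 2,
    y = (emitters$y[pairs$e[keep]] + detectors$y[pairs$d[keep]]) / 2,
    separation = sep[keep], stringsAsFactors = FALSE)
  ch <- ch[order(ch$x, -ch$y), , drop = FALSE]
  ch <- cbind(channel = seq_len(nrow(ch)), ch)
  rownames(ch) <- NULL

  structure(list(emitters = emitters, detectors = detectors, channels = ch,
                 reference = "FpZ"),
            class = "fnirs_montage")
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf(
    "fNIRS montage: %d emitters, %d detectors, %d channels (separation %.2f-%.2f cm), reference %s\n",
    nrow(x$emitters), nrow(x$detectors), nrow(x$channels),
    min(x$channels$separation), max(x$channels$separation), x$reference))
  invisible(x)
}

#' @export
plot.fnirs_montage <- function(x, ...) {
  ch <- x$channels
  plot(ch$x, ch$y, type = "n", asp = 1, xlab = "x (cm)", ylab = "y (cm)",
       main = "fNIRS montage", ...)
  points(x$emitters$x, x$emitters$y, pch = 17, col = "red", cex = 1.4)
  points(x$detectors$x, x$detectors$y, pch = 19, col = "blue", cex = 1.4)
  text(ch$x, ch$y, labels = ch$channel, cex = 0.7)
  points(0, 0, pch = 3)
  invisible(x)
}

# Canonical channel column labels, e.g. "ch01".
channel_labels <- function(n) sprintf("ch%02d", seq_len(n))
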