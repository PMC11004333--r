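# Face cropping (deliberately without alignment) and the full-frame + tile
# decomposition feeding the spatial encoder.

#' Passthrough face detector
#'
#' A detector under the pluggable box-and-confidence contract that returns
#' the whole frame with confidence 1, for pre-cropped (e.g. synthetic)
#' input. A detector is any `function(frame)` returning a list of
#' `list(box = c(x0, y0, x1, y1), confidence = <number>)` with 1-based
#' inclusive pixel coordinates (x = column, y = row).
#'
#' @return A detector function.
#' @export
passthroughDetector <- function() {
  function(frame) {
    d <- dim(frame)
    list(list(box = c(1, 1, d[2L], d[1L]), confidence = 1))
  }
}

#' Detect and crop a face without alignment
#'
#' Takes the highest-confidence detector box, expands it to a square about
#' its centre (clamped to the frame), crops and bicubic-resizes to
#' 448 x 448. No rotation or landmark alignment is applied: head movement
#' is part of the expression signal this pipeline preserves.
#'
#' @param frame an `H x W x 3` image array (values in `[0, 1]`).
#' @param detector a detector function (see [passthroughDetector()]).
#' @param previousBox optional fallback box reused when no face is found
#'   (the per-session convention for dropped detections).
#' @param frameIndex index recorded on the output (and on the no-face
#'   error condition).
#' @return A [FaceCrop-class].
#' @export
detectAndCrop <- function(frame, detector = passthroughDetector(),
                          previousBox = NULL, frameIndex = 1L) {
  dets <- detector(frame)
  box <- if (length(dets)) {
    dets[[which.max(vapply(dets, `[[`, numeric(1), "confidence"))]]$box
  } else if (!is.null(previousBox)) {
    previousBox
  } else {
    cond <- structure(class = c("noFace", "error", "condition"),
                      list(message = sprintf("no face in frame %d", frameIndex),
                           call = sys.call(-1), frameIndex = frameIndex))
    stop(cond)
  }
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  cx <- (box[1L] + box[3L]) / 2
  cy <- (box[2L] + box[4L]) / 2
  side <- max(box[3L] - box[1L], box[4L] - box[2L]) + 1
  side <- min(side, h, w)
  x0 <- round(min(max(cx - side / 2 + 0.5, 1), w - side + 1))
  y0 <- round(min(max(cy - side / 2 + 0.5, 1), h - side + 1))
  crop <- frame[y0:(y0 + side - 1), x0:(x0 + side - 1), , drop = FALSE]
  if (side != 448) crop <- bicubicResize(crop, 448L, 448L)
  methods::new("FaceCrop", image = crop, sourceFrameIndex = as.integer(frameIndex))
}

#' Decompose a face crop into the full frame and four quadrant tiles
#'
#' The four tiles are the disjoint quadrants of the 448 x 448 crop
#' (half-open pixel ranges, origin top-left, order top-left, top-right,
#' bottom-left, bottom-right); the fifth image is the whole crop
#' bicubic-resized to 224 x 224. The quadrants reassemble the crop exactly.
#'
#' @param crop a [FaceCrop-class] or a 448 x 448 x 3 array.
#' @return A [TileSet-class].
#' @export
makeTileset <- function(crop) {
  img <- if (methods::is(crop, "FaceCrop")) crop@image else crop
  d <- dim(img)
  if (length(d) != 3L || d[1L] != 448L || d[2L] != 448L || d[3L] != 3L)
    pfStop("invalidArgument", "crop must be 448 x 448 x 3")
  tiles <- list(img[1:224, 1:224, , drop = FALSE],
                img[1:224, 225:448, , drop = FALSE],
                img[225:448, 1:224, , drop = FALSE],
                img[225:448, 225:448, , drop = FALSE])
  methods::new("TileSet", full = bicubicResize(img, 224L, 224L), tiles = tiles)
}

#' Read a directory of PNG frames
#' @param dir directory containing `frame_*.png` files (sorted by name).
#' @return List of `H x W x 3` arrays.
#' @export
readFrameDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a[, , 1:3, drop = FALSE]
  })
}
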