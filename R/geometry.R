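# 2-D geometry utilities. All coordinates are drawing points, y growing
# downward; rectangles are numeric c(xmin, ymin, xmax, ymax).

rect2d <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmin <= xmax, ymin <= ymax)
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}

rectCenter <- function(r) c((r[[1]] + r[[3]]) / 2, (r[[2]] + r[[4]]) / 2)

#' Minimal enclosing rectangle
#'
#' Computes the smallest axis-aligned rectangle enclosing every member of
#' `objects`, where a member is either a point `c(x, y)` or a rectangle
#' `c(xmin, ymin, xmax, ymax)`.
#'
#' @param objects non-empty list of points and/or rectangles.
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @examples
#' boundingBox(list(c(0, 0), c(2, 5)))
#' @export
boundingBox <- function(objects) {
  if (!is.list(objects) || length(objects) == 0) stop("no objects")
  xs <- ys <- numeric(0)
  for (o in objects) {
    o <- as.numeric(o)
    if (length(o) == 2) { xs <- c(xs, o[1]); ys <- c(ys, o[2]) }
    else if (length(o) == 4) { xs <- c(xs, o[c(1, 3)]); ys <- c(ys, o[c(2, 4)]) }
    else stop("object is neither a point nor a rectangle")
  }
  if (!all(is.finite(c(xs, ys)))) stop("non-finite coordinate")
  rect2d(min(xs), min(ys), max(xs), max(ys))
}

fragmentBbox <- function(f) {
  if (nrow(f$atoms) == 0) stop("no objects")
  rect2d(min(f$atoms$x), min(f$atoms$y), max(f$atoms$x), max(f$atoms$y))
}

textBbox <- function(t) rect2d(t$xmin, t$ymin, t$xmax, t$ymax)

#' Project a point onto an arrow's axis
#'
#' Expresses a point in arrow-local coordinates: `t` is the normalized
#' position along the tail-to-head axis (0 at the tail, 1 at the head) and
#' `d` the signed perpendicular distance in drawing units. Because y grows
#' downward, points drawn *above* the arrow have negative `d`.
#'
#' @param p point `c(x, y)`.
#' @param arrow list or one-row data frame with `tailx`, `taily`, `headx`,
#'   `heady`.
#' @return named numeric `c(t = , d = )`.
#' @examples
#' projectOnArrow(c(5, -3), list(tailx = 0, taily = 0, headx = 10, heady = 0))
#' @export
projectOnArrow <- function(p, arrow) {
  v <- c(arrow$headx - arrow$tailx, arrow$heady - arrow$taily)
  len2 <- sum(v^2)
  if (len2 == 0) stop("zero-length arrow")
  w <- c(p[[1]] - arrow$tailx, p[[2]] - arrow$taily)
  tt <- sum(v * w) / len2
  d <- (v[1] * w[2] - v[2] * w[1]) / sqrt(len2)
  c(t = tt, d = d)
}

arrowLength <- function(arrow)
  sqrt((arrow$headx - arrow$tailx)^2 + (arrow$heady - arrow$taily)^2)

# Median drawn bond length over the whole graph; scale anchor for zone
# margins and Molfile coordinate normalization. NA when nothing is bonded.
medianBondLength <- function(graph) {
  lens <- unlist(lapply(graph@fragments, function(f) {
    if (nrow(f$bonds) == 0) return(numeric(0))
    i <- match(f$bonds$begin, f$atoms$id)
    j <- match(f$bonds$end, f$atoms$id)
    sqrt((f$atoms$x[i] - f$atoms$x[j])^2 + (f$atoms$y[i] - f$atoms$y[j])^2)
  }))
  if (length(lens) == 0) NA_real_ else stats::median(lens)
}
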