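## Visual-field maps: a regular grid of intact / absolute-defect / untested
## cells in degrees of visual angle, plus parametric scotomata used both to
## synthesise fields and to define ground truth for simulated observers.
## Internally temporal is always positive x: a left-eye field is mirrored at
## load time so a single blind-spot model serves both eyes; the I/O layer
## restores natural signs.

FIELD_STATUSES <- c("intact", "defect", "untested")

#' Parametric scotoma specifications
#'
#' Constructors for the three supported scotoma shapes. `scotoma_circle()`
#' describes a circular absolute defect such as the physiological blind spot;
#' `scotoma_halfplane()` a hemianopia (all field strictly beyond a vertical
#' boundary); `scotoma_quadrant()` a quadrantanopia. `blind_spot_scotoma()`
#' is the default anatomical blind-spot model: a circle of radius 2.5 degrees
#' centred at (14.5, -1) in temporal-positive coordinates -- the midpoint of
#' the 12-17 degree eccentricity span of the optic-nerve head, one degree
#' below the horizontal meridian.
#'
#' @param center numeric length-2, circle centre in degrees.
#' @param radius circle radius in degrees, > 0.
#' @param boundary_x vertical boundary of the half-plane, degrees.
#' @param side which side of the boundary is blind: `"right"` means
#'   `x > boundary_x`, `"left"` means `x < boundary_x`.
#' @param which quadrant, one of `"upper_right"`, `"upper_left"`,
#'   `"lower_right"`, `"lower_left"` (open quadrants, axes excluded).
#' @return An object of class `scotoma`.
#' @export
scotoma_circle <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius) || radius <= 0) stop("circle radius must be > 0", call. = FALSE)
  structure(list(shape = "circle", center = as.numeric(center), radius = radius),
            class = "scotoma")
}

#' @rdname scotoma_circle
#' @export
scotoma_halfplane <- function(boundary_x, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is.numeric(boundary_x), length(boundary_x) == 1, is.finite(boundary_x))
  structure(list(shape = "halfplane", boundary_x = boundary_x, side = side),
            class = "scotoma")
}

#' @rdname scotoma_circle
#' @export
scotoma_quadrant <- function(which = c("upper_right", "upper_left",
                                       "lower_right", "lower_left")) {
  which <- match.arg(which)
  structure(list(shape = "quadrant", which = which), class = "scotoma")
}

#' @rdname scotoma_circle
#' @export
blind_spot_scotoma <- function() scotoma_circle(center = c(14.5, -1), radius = 2.5)

#' Test whether positions fall inside a scotoma
#'
#' @param spec a [scotoma_circle()]-family specification.
#' @param x,y numeric vectors of coordinates in degrees (recycled together).
#' @return Logical vector.
#' @export
scotoma_contains <- function(spec, x, y) {
  stopifnot(inherits(spec, "scotoma"))
  switch(spec$shape,
    circle = (x - spec$center[1])^2 + (y - spec$center[2])^2 <= spec$radius^2,
    halfplane = if (spec$side == "right") x > spec$boundary_x else x < spec$boundary_x,
    quadrant = switch(spec$which,
      upper_right = x > 0 & y > 0,
      upper_left  = x < 0 & y > 0,
      lower_right = x > 0 & y < 0,
      lower_left  = x < 0 & y < 0)
  )
}

#' Build a visual-field map from scotoma specifications
#'
#' Samples a square grid of pitch `pitch_deg` out to `extent_deg` on each axis
#' (cell coordinates are integer multiples of the pitch). Cells inside any of
#' the given scotomata are `"defect"`, all others `"intact"`. The default
#' pitch of 0.75 degrees matches the sampling density of the eye-tracking
#' perimeter whose output these maps emulate. Deterministic, idempotent, and
#' order-independent in `specs`.
#'
#' @param specs list of scotoma specifications (possibly empty).
#' @param pitch_deg grid spacing in degrees, > 0.
#' @param extent_deg half-width of the sampled square, >= `pitch_deg`.
#' @param eye `"right"` or `"left"`. Stored as metadata; coordinates are
#'   always temporal-positive internally.
#' @return An object of class `visual_field`: list with `eye`, `pitch_deg`,
#'   `extent_deg`, a `cells` data frame (`x_deg`, `y_deg`, `status`, sorted by
#'   x then y) and an internal status matrix for fast lookup.
#' @export
make_field <- function(specs = list(), pitch_deg = 0.75, extent_deg = 45,
                       eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (inherits(specs, "scotoma")) specs <- list(specs)
  if (!is.numeric(pitch_deg) || pitch_deg <= 0) {
    stop("pitch_deg must be > 0", call. = FALSE)
  }
  if (!is.numeric(extent_deg) || extent_deg < pitch_deg) {
    stop("extent_deg must be at least one pitch: grid would be empty", call. = FALSE)
  }
  n <- floor(extent_deg / pitch_deg + 1e-9)
  coords <- seq(-n, n) * pitch_deg
  status <- matrix("intact", nrow = length(coords), ncol = length(coords))
  if (length(specs) > 0) {
    xg <- matrix(coords, nrow = length(coords), ncol = length(coords))
    yg <- t(xg)
    for (spec in specs) {
      status[scotoma_contains(spec, xg, yg)] <- "defect"
    }
  }
  new_visual_field(eye, pitch_deg, extent_deg, coords, status)
}

new_visual_field <- function(eye, pitch_deg, extent_deg, coords, status) {
  stopifnot(all(status %in% FIELD_STATUSES))
  cells <- data.frame(
    x_deg = rep(coords, each = length(coords)),
    y_deg = rep(coords, times = length(coords)),
    status = as.vector(t(status)),  # matrix is [x, y]; cells sorted by x then y
    stringsAsFactors = FALSE
  )
  structure(
    list(eye = eye, pitch_deg = pitch_deg, extent_deg = extent_deg,
         coords = coords, status = status, cells = cells),
    class = "visual_field"
  )
}

#' @export
print.visual_field <- function(x, ...) {
  tab <- table(factor(x$status, levels = FIELD_STATUSES))
  cat(sprintf("<visual_field: %s eye, pitch %g deg, extent +/- %g deg, %d cells (%d intact, %d defect, %d untested)>\n",
              x$eye, x$pitch_deg, x$extent_deg, length(x$status),
              tab[["intact"]], tab[["defect"]], tab[["untested"]]))
  invisible(x)
}

# Nearest grid index for a coordinate, half-way ties broken toward the
# smaller coordinate: ceiling(v - 0.5) rounds halves down.
.nearest_index <- function(v, pitch) ceiling(v / pitch - 0.5)

#' Classify a point against a visual-field map
#'
#' Returns the status of the nearest grid cell (statuses are categorical, so
#' no interpolation); points half-way between cells resolve to the cell with
#' the smaller x, then smaller y. Points beyond the sampled extent are
#' `"untested"`.
#'
#' @param field a [make_field()] map.
#' @param p numeric length-2 position in degrees, or an n x 2 matrix.
#' @return Character status, one per row of `p`.
#' @export
classify_point <- function(field, p) {
  stopifnot(inherits(field, "visual_field"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  n <- (length(field$coords) - 1) / 2
  ix <- .nearest_index(p[, 1], field$pitch_deg) + n + 1
  iy <- .nearest_index(p[, 2], field$pitch_deg) + n + 1
  out <- rep("untested", nrow(p))
  ok <- ix >= 1 & ix <= length(field$coords) & iy >= 1 & iy <= length(field$coords)
  out[ok] <- field$status[cbind(ix[ok], iy[ok])]
  out
}

#' Extract the border zone between intact and defect field
#'
#' The border (transition) zone is where restitution training places its
#' stimuli. A transition cell is an intact or defect cell with at least one
#' 4-neighbour of the opposite status; the zone is that set dilated to the
#' requested width, i.e. every non-untested cell within `width - pitch`
#' (Euclidean) of a transition cell. With `width == pitch` the zone is the
#' transition cells themselves. Result is sorted by x then y; a field with no
#' defect yields an empty zone.
#'
#' @param field a [make_field()] map.
#' @param width zone width in degrees, >= the grid pitch.
#' @return Data frame with columns `x_deg`, `y_deg`.
#' @export
border_zone <- function(field, width = field$pitch_deg) {
  stopifnot(inherits(field, "visual_field"))
  if (width < field$pitch_deg - 1e-9) {
    stop("width must be at least the grid pitch", call. = FALSE)
  }
  st <- field$status
  nr <- nrow(st)
  opp <- function(a, b) (a == "intact" & b == "defect") | (a == "defect" & b == "intact")
  trans <- matrix(FALSE, nr, nr)
  trans[-1, ]  <- trans[-1, ]  | opp(st[-1, ], st[-nr, ])
  trans[-nr, ] <- trans[-nr, ] | opp(st[-nr, ], st[-1, ])
  trans[, -1]  <- trans[, -1]  | opp(st[, -1], st[, -nr])
  trans[, -nr] <- trans[, -nr] | opp(st[, -nr], st[, -1])
  if (!any(trans)) return(data.frame(x_deg = numeric(0), y_deg = numeric(0)))
  idx <- which(trans, arr.ind = TRUE)
  tx <- field$coords[idx[, 1]]
  ty <- field$coords[idx[, 2]]
  reach <- width - field$pitch_deg + 1e-9
  if (reach < field$pitch_deg / 2) {
    keep <- idx
  } else {
    cand <- which(st != "untested", arr.ind = TRUE)
    cx <- field$coords[cand[, 1]]
    cy <- field$coords[cand[, 2]]
    d2 <- outer(cx, tx, "-")^2 + outer(cy, ty, "-")^2
    keep <- cand[apply(d2, 1, min) <= reach^2, , drop = FALSE]
  }
  out <- data.frame(x_deg = field$coords[keep[, 1]], y_deg = field$coords[keep[, 2]])
  out <- unique(out)
  out[order(out$x_deg, out$y_deg), , drop = FALSE]
}

#' Stimulus sites inside a mapped blind spot
#'
#' Places `n` stimulus positions at the centroid of the field's defect region
#' (snapped to the nearest defect cell), emulating the validation protocol
#' that centres its undetectable stimuli on the previously mapped blind spot.
#' With `spread = "jitter"` each position is instead jittered uniformly
#' within one grid pitch of the centroid, rejecting draws that leave the
#' defect, for protocols that scatter stimuli within the mapped scotoma.
#'
#' @param field a [make_field()] map containing at least one defect cell.
#' @param n number of positions, >= 1.
#' @param spread `"centroid"` (default: all positions identical) or `"jitter"`.
#' @return An `n` x 2 matrix of positions, all classifying as `"defect"`.
#' @export
blind_spot_stimulus_sites <- function(field, n, spread = c("centroid", "jitter")) {
  spread <- match.arg(spread)
  stopifnot(inherits(field, "visual_field"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  def <- field$cells[field$cells$status == "defect", , drop = FALSE]
  if (nrow(def) == 0) stop("field contains no defect", call. = FALSE)
  centroid <- c(mean(def$x_deg), mean(def$y_deg))
  d2 <- (def$x_deg - centroid[1])^2 + (def$y_deg - centroid[2])^2
  best <- def[order(d2, def$x_deg, def$y_deg)[1], ]
  site <- c(best$x_deg, best$y_deg)
  if (spread == "centroid") {
    return(matrix(site, nrow = n, ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("x_deg", "y_deg"))))
  }
  out <- matrix(NA_real_, nrow = n, ncol = 2,
                dimnames = list(NULL, c("x_deg", "y_deg")))
  for (i in seq_len(n)) {
    for (try in 1:100) {
      cand <- site + stats::runif(2, -field$pitch_deg, field$pitch_deg)
      if (classify_point(field, cand) == "defect") break
    }
    out[i, ] <- cand
  }
  out
}

#' Read and write visual-field map files
#'
#' The on-disk format is a CSV with header `x_deg,y_deg,status` (status one
#' of `intact`, `defect`, `untested`), one row per grid cell, in the natural
#' coordinate signs of the tested eye. For a left eye, x is negated on read
#' so that temporal is positive internally, and negated again on write. The
#' reader validates grid regularity (constant pitch, complete square grid).
#'
#' @param field a [make_field()] map.
#' @param path file path.
#' @param eye which eye the file describes (`"right"` or `"left"`).
#' @return `read_field()` returns a `visual_field`; `write_field()` returns
#'   `path` invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "visual_field"))
  cells <- field$cells
  if (field$eye == "left") cells$x_deg <- -cells$x_deg
  cells <- cells[order(cells$x_deg, cells$y_deg), ]
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, eye = c("right", "left")) {
  eye <- match.arg(eye)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x_deg", "y_deg", "status")
  if (!all(req %in% names(cells))) {
    stop("field file must have columns x_deg,y_deg,status", call. = FALSE)
  }
  if (!all(cells$status %in% FIELD_STATUSES)) {
    stop("field file contains unknown status values", call. = FALSE)
  }
  if (eye == "left") cells$x_deg <- -cells$x_deg
  xs <- sort(unique(cells$x_deg))
  ys <- sort(unique(cells$y_deg))
  if (!isTRUE(all.equal(xs, ys)) || nrow(cells) != length(xs)^2) {
    stop("field file is not a complete square grid", call. = FALSE)
  }
  pitches <- diff(xs)
  pitch <- pitches[1]
  if (any(abs(pitches - pitch) > 1e-6)) {
    stop("field file grid pitch is not constant", call. = FALSE)
  }
  if (abs(xs[1] + xs[length(xs)]) > 1e-6) {
    stop("field file grid is not centred on fixation", call. = FALSE)
  }
  n <- (length(xs) - 1) / 2
  status <- matrix(NA_character_, length(xs), length(xs))
  ix <- round(cells$x_deg / pitch) + n + 1
  iy <- round(cells$y_deg / pitch) + n + 1
  status[cbind(ix, iy)] <- cells$status
  if (anyNA(status)) stop("field file has missing grid cells", call. = FALSE)
  new_visual_field(eye, pitch, xs[length(xs)], xs, status)
}
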