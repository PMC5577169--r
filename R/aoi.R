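#' Areas of interest for the mental-rotation display
#'
#' The display shows two Shepard-Metzler block figures side by side; the upper
#' and lower arms of each figure define four areas of interest (AOIs). Gaze
#' position is discretized to these regions before any modelling. The fixed
#' category numbering is 1 = L1 (left figure, upper arm), 2 = L2 (left, lower),
#' 3 = R1 (right, upper), 4 = R2 (right, lower).
#'
#' @param regions named list with elements `L1`, `L2`, `R1`, `R2`. Each region
#'   is either a rectangle given as `c(x0, y0, x1, y1)` (screen px, origin
#'   top-left, y increasing downwards) or a polygon given as a two-column
#'   matrix of vertices.
#' @return an object of class `aoi_layout`.
#' @details Regions must be pairwise disjoint (rectangle containment is
#'   edge-inclusive, so shared edges are not allowed). Overlap between two
#'   rectangles is checked exactly; overlap involving a polygon is checked by
#'   testing a dense grid of points of each region against the other.
#' @export
aoi_layout <- function(regions) {
  nms <- c("L1", "L2", "R1", "R2")
  if (!is.list(regions) || !setequal(names(regions), nms))
    stop("layout error: regions must be a named list with exactly L1, L2, R1, R2")
  regions <- regions[nms]
  regs <- lapply(nms, function(nm) {
    r <- regions[[nm]]
    if (is.numeric(r) && length(r) == 4L && is.null(dim(r))) {
      if (r[1] >= r[3] || r[2] >= r[4])
        stop("layout error: degenerate rectangle for ", nm)
      list(name = nm, type = "rect", rect = unname(as.numeric(r)))
    } else if (is.matrix(r) && ncol(r) == 2L && nrow(r) >= 3L) {
      list(name = nm, type = "poly", poly = unname(r))
    } else {
      stop("layout error: region ", nm,
           " must be c(x0, y0, x1, y1) or a vertex matrix")
    }
  })
  names(regs) <- nms
  layout <- structure(list(regions = regs), class = "aoi_layout")
  .check_disjoint(layout)
  layout
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat("AOI layout (4 regions, screen px, y down):\n")
  for (r in x$regions) {
    if (r$type == "rect")
      cat(sprintf("  %s: rect [%g, %g] x [%g, %g]\n", r$name,
                  r$rect[1], r$rect[3], r$rect[2], r$rect[4]))
    else
      cat(sprintf("  %s: polygon with %d vertices\n", r$name, nrow(r$poly)))
  }
  invisible(x)
}

.region_bbox <- function(r) {
  if (r$type == "rect") r$rect
  else c(min(r$poly[, 1]), min(r$poly[, 2]), max(r$poly[, 1]), max(r$poly[, 2]))
}

.point_in_region <- function(x, y, r) {
  if (r$type == "rect") {
    x >= r$rect[1] & x <= r$rect[3] & y >= r$rect[2] & y <= r$rect[4]
  } else {
    as.logical(mgcv::in.out(rbind(r$poly, r$poly[1, ]), cbind(x, y)))
  }
}

.region_grid <- function(r, m = 15L) {
  bb <- .region_bbox(r)
  g <- expand.grid(x = seq(bb[1], bb[3], length.out = m),
                   y = seq(bb[2], bb[4], length.out = m))
  keep <- .point_in_region(g$x, g$y, r)
  g[keep, , drop = FALSE]
}

.check_disjoint <- function(layout) {
  regs <- layout$regions
  for (i in 1:3) for (j in (i + 1):4) {
    a <- regs[[i]]; b <- regs[[j]]
    ba <- .region_bbox(a); bb <- .region_bbox(b)
    if (ba[1] > bb[3] || bb[1] > ba[3] || ba[2] > bb[4] || bb[2] > ba[4]) next
    if (a$type == "rect" && b$type == "rect") {
      stop("layout error: regions ", a$name, " and ", b$name, " overlap")
    }
    ga <- .region_grid(a); gb <- .region_grid(b)
    if (any(.point_in_region(ga$x, ga$y, b)) ||
        any(.point_in_region(gb$x, gb$y, a)))
      stop("layout error: regions ", a$name, " and ", b$name, " overlap")
  }
  invisible(TRUE)
}

#' Default AOI layout
#'
#' Four disjoint rectangles on a 1920 x 1080 px screen: the upper and lower
#' arms of a left-side and a right-side figure, each figure sitting inside its
#' own half of the display with a small vertical gap between the arm regions.
#'
#' @return an `aoi_layout`.
#' @export
default_aoi_layout <- function() {
  aoi_layout(list(
    L1 = c(280, 320, 680, 538),   # left figure, upper arm
    L2 = c(280, 542, 680, 760),   # left figure, lower arm
    R1 = c(1240, 320, 1640, 538), # right figure, upper arm
    R2 = c(1240, 542, 1640, 760)  # right figure, lower arm
  ))
}

#' Assign fixations to areas of interest
#'
#' @param x,y fixation coordinates in screen px (vectorized).
#' @param layout an [aoi_layout()].
#' @return integer vector: 1 = L1, 2 = L2, 3 = R1, 4 = R2, or 0 for a point
#'   outside every region (`AOI_OUTSIDE`).
#' @export
assign_aoi <- function(x, y, layout) {
  stopifnot(inherits(layout, "aoi_layout"), length(x) == length(y))
  out <- rep(AOI_OUTSIDE, length(x))
  for (k in 1:4) {
    inside <- .point_in_region(x, y, layout$regions[[k]])
    out[inside & out == AOI_OUTSIDE] <- k
  }
  out
}

#' Sentinel for fixations outside every AOI
#' @export
AOI_OUTSIDE <- 0L

#' Read / write an AOI layout as JSON
#'
#' The JSON file holds one object per region (`L1`, `L2`, `R1`, `R2`), each
#' either `{"rect": [x0, y0, x1, y1]}` or `{"poly": [[x, y], ...]}`.
#'
#' @param path file path.
#' @return `read_aoi_layout` returns an `aoi_layout`; `write_aoi_layout`
#'   returns `path` invisibly.
#' @export
read_aoi_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- lapply(j, function(r) {
    if (!is.null(r$rect)) as.numeric(r$rect)
    else if (!is.null(r$poly)) matrix(as.numeric(unlist(r$poly)),
                                      ncol = 2, byrow = is.list(r$poly))
    else stop("layout error: region must have a 'rect' or 'poly' entry")
  })
  aoi_layout(regions)
}

#' @rdname read_aoi_layout
#' @param layout an `aoi_layout` to serialize.
#' @export
write_aoi_layout <- function(layout, path) {
  stopifnot(inherits(layout, "aoi_layout"))
  j <- lapply(layout$regions, function(r) {
    if (r$type == "rect") list(rect = r$rect)
    else list(poly = apply(r$poly, 1, as.list))
  })
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
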