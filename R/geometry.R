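#' Rasterize a disc on a voxel grid
#'
#' @param shape `c(nx, ny)` grid size.
#' @param center `c(x, y)` in voxel coordinates.
#' @param radius radius in voxels.
#' @return logical matrix; TRUE inside the disc.
#' @keywords internal
disc_mask <- function(shape, center, radius) {
  xy <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]))
  m <- (xy$x - center[1])^2 + (xy$y - center[2])^2 <= radius^2
  matrix(m, nrow = shape[1], ncol = shape[2])
}

#' Rasterize a polygon on a voxel grid
#'
#' Uses `mgcv::in.out()` for the point-in-polygon test on voxel centers.
#'
#' @param shape `c(nx, ny)` grid size.
#' @param vertices two-column matrix of polygon vertices (voxel coordinates).
#' @return logical matrix; TRUE inside the polygon.
#' @keywords internal
polygon_mask <- function(shape, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("vertices must be an n x 2 matrix with n >= 3")
  }
  bnd <- rbind(vertices, vertices[1, ])
  xy <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2])))
  m <- mgcv::in.out(bnd, xy)
  matrix(m, nrow = shape[1], ncol = shape[2])
}

#' Phantom geometry: labeled regions on a 2D slice
#'
#' One axial slice per frame carries five regions mimicking the ROI layout of
#' a pancreatic perfusion exam: a circular aortic ROI, and for each tissue
#' (parenchyma, carcinoma) a polygonal whole-tissue ROI with a smaller
#' circular high-confidence ROI strictly inside it. Regions of different
#' tissues (and the aorta) are pairwise disjoint.
#'
#' The default grid is 96 x 96 voxels at a nominal 1 mm pixel pitch, which
#' puts the ROI areas on the scale of a clinical exam (circular ROIs ~80
#' voxels, polygonal carcinoma ~750, polygonal parenchyma ~2300).
#'
#' @param image_shape `c(nx, ny)` voxel grid.
#' @param aorta list `(center, radius)`.
#' @param carcinoma list `(vertices, circ_center, circ_radius)`.
#' @param parenchyma list `(vertices, circ_center, circ_radius)`.
#' @return a `phantom_geometry` object with rasterized masks in `$masks`
#'   (names `aorta`, `carcinoma_poly`, `carcinoma_circ`, `parenchyma_poly`,
#'   `parenchyma_circ`).
#' @export
phantom_geometry <- function(image_shape = c(96, 96),
                             aorta = list(center = c(18, 20), radius = 5),
                             carcinoma = list(
                               vertices = regular_polygon(c(30, 48), 16, 8),
                               circ_center = c(30, 48), circ_radius = 5
                             ),
                             parenchyma = list(
                               vertices = rbind(
                                 c(48, 30), c(70, 22), c(90, 35),
                                 c(90, 70), c(65, 78), c(48, 60)
                               ),
                               circ_center = c(70, 50), circ_radius = 5
                             )) {
  masks <- list(
    aorta = disc_mask(image_shape, aorta$center, aorta$radius),
    carcinoma_poly = polygon_mask(image_shape, carcinoma$vertices),
    carcinoma_circ = disc_mask(image_shape, carcinoma$circ_center, carcinoma$circ_radius),
    parenchyma_poly = polygon_mask(image_shape, parenchyma$vertices),
    parenchyma_circ = disc_mask(image_shape, parenchyma$circ_center, parenchyma$circ_radius)
  )
  # circular ROIs must nest strictly inside their own polygonal ROI
  if (!all(masks$carcinoma_poly[masks$carcinoma_circ])) {
    stop("carcinoma circular ROI must lie inside the carcinoma polygon")
  }
  if (!all(masks$parenchyma_poly[masks$parenchyma_circ])) {
    stop("parenchyma circular ROI must lie inside the parenchyma polygon")
  }
  # distinct tissues and the aorta must not overlap
  outer_masks <- masks[c("aorta", "carcinoma_poly", "parenchyma_poly")]
  pairs <- utils::combn(names(outer_masks), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (any(outer_masks[[a]] & outer_masks[[b]])) {
      stop(sprintf("overlapping regions: %s and %s", a, b))
    }
  }
  structure(list(image_shape = as.integer(image_shape),
                 aorta = aorta, carcinoma = carcinoma, parenchyma = parenchyma,
                 masks = masks),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  sizes <- vapply(x$masks, sum, integer(1))
  cat(sprintf("<phantom_geometry> %s grid; voxels: %s\n",
              paste(x$image_shape, collapse = "x"),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Vertices of a regular polygon
#'
#' @param center `c(x, y)`.
#' @param radius circumradius in voxels.
#' @param n number of vertices.
#' @return an `n x 2` matrix.
#' @export
regular_polygon <- function(center, radius, n = 8) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
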