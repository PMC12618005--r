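#' Average-intensity z projection
#'
#' Pixelwise arithmetic mean over the slices of a stack, the projection the
#' gut-ROS (DHE) quantification runs before drawing ROIs.
#'
#' @param stack A `height x width x slices` numeric array, a single matrix,
#'   or a list of equally sized slice matrices.
#' @return A `height x width` matrix.
#' @export
z_project_mean <- function(stack) {
  if (is.list(stack)) {
    dims <- unique(lapply(stack, dim))
    if (length(stack) == 0L || length(dims) != 1L) {
      stop("slices must be non-empty and identically shaped", call. = FALSE)
    }
    stack <- array(unlist(stack), dim = c(dims[[1L]], length(stack)))
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3L] < 1L) {
    stop("`stack` must be a height x width x slices array", call. = FALSE)
  }
  if (any(!is.finite(stack))) stop("stack values must be finite", call. = FALSE)
  rowMeans(stack, dims = 2L)
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# Pixel centers sit at integer coordinates (x = column, y = row, 1-based).
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean fluorescence over named ROI polygons
#'
#' A pixel belongs to an ROI when its center (integer coordinates; x =
#' column, y = row) falls inside the polygon under the even-odd rule, the
#' convention of common ImageJ-style ROI tools.
#'
#' @param image A numeric matrix (e.g. from [z_project_mean()]).
#' @param rois A named list of polygons; each polygon a data frame or
#'   2-column matrix of `x`, `y` vertices in pixel coordinates.
#' @return A data frame `region`, `n_pixels`, `mean_fluorescence`.
#' @export
roi_mean_fluorescence <- function(image, rois) {
  stopifnot(is.matrix(image))
  if (!is.list(rois) || is.null(names(rois)) || any(names(rois) == "") ||
      anyDuplicated(names(rois))) {
    stop("`rois` must be a list of uniquely named polygons", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  rows <- lapply(names(rois), function(nm) {
    poly <- rois[[nm]]
    poly <- if (is.data.frame(poly)) cbind(poly$x, poly$y) else as.matrix(poly)
    if (nrow(poly) < 3L) stop(sprintf("ROI '%s' has < 3 vertices", nm),
                              call. = FALSE)
    xs <- max(1L, floor(min(poly[, 1L]))):min(w, ceiling(max(poly[, 1L])))
    ys <- max(1L, floor(min(poly[, 2L]))):min(h, ceiling(max(poly[, 2L])))
    px <- rep(xs, each = length(ys))
    py <- rep(ys, times = length(xs))
    inside <- point_in_polygon(px, py, poly[, 1L], poly[, 2L])
    if (!any(inside)) {
      stop(sprintf("ROI '%s' contains no pixel centers", nm), call. = FALSE)
    }
    vals <- image[cbind(py[inside], px[inside])]
    data.frame(region = nm, n_pixels = sum(inside),
               mean_fluorescence = mean(vals))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mean fluorescence per nucleus from a label mask
#'
#' Per-label mean intensity over the label's pixels ("mean fluorescence per
#' nucleus area"). Optionally subtracts the median intensity of the
#' background (label 0) pixels first; the default reports raw means, as
#' the figure quantifications do.
#'
#' @param image Numeric matrix, aligned with `mask`.
#' @param mask Integer matrix, 0 = background, k > 0 = nucleus k.
#' @param background_policy `"none"` (default) or `"median_background"`.
#' @return A data frame `label`, `n_pixels`, `mean_fluorescence`; empty
#'   (zero rows) when the mask has no labels.
#' @export
nucleus_mean_fluorescence <- function(image, mask,
                                      background_policy = c("none",
                                                            "median_background")) {
  stopifnot(is.matrix(image), is.matrix(mask))
  if (!all(dim(image) == dim(mask))) {
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  }
  background_policy <- match.arg(background_policy)
  vals <- image
  if (background_policy == "median_background") {
    bg <- mask == 0L
    if (!any(bg)) stop("no background pixels to estimate from", call. = FALSE)
    vals <- vals - median(image[bg])
  }
  labs <- mask[mask > 0L]
  if (length(labs) == 0L) {
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      mean_fluorescence = numeric(0)))
  }
  m <- tapply(vals[mask > 0L], labs, mean)
  n <- tapply(rep(1L, length(labs)), labs, sum)
  data.frame(label = as.integer(names(m)),
             n_pixels = as.integer(n),
             mean_fluorescence = as.numeric(m),
             row.names = NULL)
}
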