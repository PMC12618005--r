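#' Parameters for the synthetic nucleus image-stack simulator
#'
#' Generates a multi-slice grayscale stack containing non-overlapping
#' uniform-intensity disk "nuclei" on a constant background, plus optional
#' Gaussian pixel noise, together with the matching integer label mask.
#' With `noise_sd = 0` the mean intensity over a nucleus's mask pixels is
#' exactly `background + per_nucleus_intensity[k]`, which makes the
#' per-nucleus quantification exactly checkable.
#'
#' @param width,height Image size in pixels.
#' @param n_slices Number of z slices.
#' @param n_nuclei Number of nuclei; 0 gives an empty mask.
#' @param nucleus_radius Disk radius, pixels.
#' @param per_nucleus_intensity Numeric vector of length `n_nuclei`
#'   (recycled if length 1), added to the background inside each disk.
#' @param background Constant background level.
#' @param noise_sd Gaussian pixel noise SD (per pixel and slice); negative
#'   values are clipped at 0 so intensities stay non-negative.
#' @param seed Integer seed.
#' @return An object of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 128, height = 128, n_slices = 5,
                             n_nuclei = 10, nucleus_radius = 6,
                             per_nucleus_intensity = 100, background = 10,
                             noise_sd = 0, seed = 1L) {
  stop_if_not_positive(width, "width")
  stop_if_not_positive(height, "height")
  stop_if_not_positive(n_slices, "n_slices")
  stop_if_not_positive(nucleus_radius, "nucleus_radius")
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0", call. = FALSE)
  per_nucleus_intensity <- rep_len(as.numeric(per_nucleus_intensity),
                                   max(n_nuclei, 1L))
  if (any(per_nucleus_intensity < 0) || background < 0) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_slices = as.integer(n_slices), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 per_nucleus_intensity = per_nucleus_intensity,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "image_sim_params")
}

#' Simulate an image stack with a matching nucleus label mask
#'
#' Nucleus centers are placed by rejection sampling so disks neither
#' overlap nor cross the frame edge; placement fails with an error after a
#' bounded number of retries when the packing is infeasible.
#'
#' @param params An [image_sim_params()] object.
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return A list: `stack` (array `height x width x n_slices`), `mask`
#'   (integer matrix, 0 = background, k = nucleus k), `centers` (data
#'   frame `label`, `x`, `y`, `intensity`).
#' @export
simulate_image_stack <- function(params, max_tries = 5000L) {
  stopifnot(inherits(params, "image_sim_params"))
  r <- params$nucleus_radius
  w <- params$width; h <- params$height
  if (params$n_nuclei > 0 && (w < 2 * r + 1 || h < 2 * r + 1)) {
    stop("nuclei do not fit in the frame", call. = FALSE)
  }
  with_seed(params$seed, {
    cx <- numeric(0); cy <- numeric(0)
    for (k in seq_len(params$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, r + 1, w - r)
        y <- runif(1, r + 1, h - r)
        if (all((x - cx)^2 + (y - cy)^2 > (2 * r + 1)^2)) {
          cx <- c(cx, x); cy <- c(cy, y)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place nucleus %d without overlap", k),
             call. = FALSE)
      }
    }
    mask <- matrix(0L, nrow = h, ncol = w)
    base <- matrix(params$background, nrow = h, ncol = w)
    px <- matrix(rep(seq_len(w), each = h), nrow = h)  # column = x
    py <- matrix(rep(seq_len(h), times = w), nrow = h) # row = y
    for (k in seq_along(cx)) {
      inside <- (px - cx[k])^2 + (py - cy[k])^2 <= r^2
      mask[inside] <- k
      base[inside] <- params$background + params$per_nucleus_intensity[k]
    }
    stack <- array(base, dim = c(h, w, params$n_slices))
    if (params$noise_sd > 0) {
      stack <- stack + array(rnorm(length(stack), 0, params$noise_sd),
                             dim = dim(stack))
      stack[stack < 0] <- 0
    }
    centers <- if (length(cx) > 0) {
      data.frame(label = seq_along(cx), x = cx, y = cy,
                 intensity = params$per_nucleus_intensity[seq_along(cx)])
    } else {
      data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                 intensity = numeric(0))
    }
    list(stack = stack, mask = mask, centers = centers)
  })
}
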