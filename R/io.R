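#' Read and write velocity-trace CSV files
#'
#' One CSV per subject with columns `time_s`, `velocity_mm_s`.
#'
#' @param trace A [velocity_trace()].
#' @param path File path.
#' @return `write_velocity_trace()` returns the path invisibly;
#'   `read_velocity_trace()` returns a `velocity_trace`.
#' @export
write_velocity_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              velocity_mm_s = trace$velocity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_trace
#' @param subject_id,frame_rate,zt0_offset Metadata for the rebuilt trace;
#'   `frame_rate = NULL` infers it from the time grid.
#' @export
read_velocity_trace <- function(path, subject_id = basename(path),
                                frame_rate = NULL, zt0_offset = 0) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "velocity_mm_s") %in% names(d))) {
    stop("trace CSV needs columns time_s, velocity_mm_s", call. = FALSE)
  }
  if (is.null(frame_rate)) {
    if (nrow(d) < 2L) stop("cannot infer frame rate from one frame", call. = FALSE)
    frame_rate <- 1 / median(diff(d$time_s))
  }
  velocity_trace(subject_id = subject_id, time = d$time_s,
                 velocity = d$velocity_mm_s, frame_rate = frame_rate,
                 zt0_offset = zt0_offset)
}

#' Write a cohort as per-subject CSVs plus a manifest TSV
#'
#' The manifest has columns `subject_id`, `group`, `population`,
#' `treatment`, `file` (relative trace paths).
#'
#' @param cohort A `locomotor_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "locomotor_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort_manifest(cohort)
  man$file <- paste0(man$subject_id, ".csv")
  for (i in seq_along(cohort)) {
    write_velocity_trace(cohort[[i]], file.path(dir, man$file[i]))
  }
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}

#' Read and write flow-cytometry event CSVs
#'
#' Columns `event_id`, `dye`, `gfp`, `fsc`, `ssc` (extra columns such as
#' simulation truth labels are preserved).
#'
#' @param events Event data frame.
#' @param path File path.
#' @export
write_flow_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  check_flow_events(utils::read.csv(path))
}

#' Read and write DEG tables as TSV
#'
#' Columns `gene`, `log2fc`, `pvalue`, `padj`.
#'
#' @param table DEG table data frame.
#' @param path File path.
#' @export
write_deg_table <- function(table, path) {
  check_deg_table(table, "table")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  check_deg_table(utils::read.delim(path), path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line", call. = FALSE)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicated set names", call. = FALSE)
  sets
}

#' Read ROI polygons from JSON
#'
#' JSON object mapping ROI names to arrays of `[x, y]` vertex pairs (or to
#' objects with `x`/`y` arrays).
#'
#' @param path JSON file path.
#' @return A named list of data frames with `x`, `y` columns, usable with
#'   [roi_mean_fluorescence()].
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(raw, function(p) {
    if (is.matrix(p)) {
      data.frame(x = p[, 1L], y = p[, 2L])
    } else {
      data.frame(x = p$x, y = p$y)
    }
  })
}

#' Read and write multi-slice grayscale TIFF stacks
#'
#' Stacks are stored as 16-bit multi-page TIFF with an explicit intensity
#' `scale` (arbitrary fluorescence units per full-scale count), so values
#' survive a round trip up to 16-bit quantization. Label masks use
#' `write_label_mask()`/`read_label_mask()`, which map integer labels
#' through the 16-bit range exactly.
#'
#' @param stack `height x width x slices` array (or matrix).
#' @param path TIFF path.
#' @param scale Value mapped to the top of the 16-bit range; defaults to
#'   the stack maximum.
#' @export
write_image_stack <- function(stack, path, scale = max(stack, 1e-12)) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  slices <- lapply(seq_len(dim(stack)[3L]),
                   function(i) pmin(stack[, , i] / scale, 1))
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(list(path = path, scale = scale))
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, scale = 1) {
  slices <- tiff::readTIFF(path, all = TRUE)
  slices <- lapply(slices, function(s) if (length(dim(s)) == 3L) s[, , 1L] else s)
  array(unlist(slices), dim = c(dim(slices[[1L]]), length(slices))) * scale
}

#' @rdname write_image_stack
#' @param mask Integer label matrix (0 = background).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
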