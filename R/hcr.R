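#' Gating configuration for the host-cell-reactivation assay
#'
#' Live cells are gated on the viability-dye channel (live iff dye intensity
#' strictly below `dye_threshold`; membrane-compromised cells take up more
#' dye). GFP positivity uses `gfp_threshold`, either supplied manually or
#' derived from an untransfected control with [derive_gfp_threshold()].
#'
#' @param dye_threshold Viability-dye cut-off, arbitrary units (> 0).
#' @param gfp_threshold GFP-positive cut-off, arbitrary units (> 0).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(dye_threshold, gfp_threshold) {
  stop_if_not_positive(dye_threshold, "dye_threshold")
  stop_if_not_positive(gfp_threshold, "gfp_threshold")
  structure(list(dye_threshold = dye_threshold, gfp_threshold = gfp_threshold),
            class = "gate_config")
}

check_flow_events <- function(events) {
  if (!is.data.frame(events) || nrow(events) == 0L) {
    stop("event table must be a data frame with >= 1 event", call. = FALSE)
  }
  for (col in c("dye", "gfp")) {
    if (!col %in% names(events)) {
      stop(sprintf("event table lacks a `%s` column", col), call. = FALSE)
    }
    if (any(!is.finite(events[[col]])) || any(events[[col]] < 0)) {
      stop(sprintf("`%s` intensities must be finite and >= 0", col),
           call. = FALSE)
    }
  }
  invisible(events)
}

#' Gate live cells on the viability-dye channel
#'
#' @param events A flow event data frame with `dye` and `gfp` columns.
#' @param dye_threshold Live iff `dye < dye_threshold`.
#' @return The live subset of `events` (possibly empty, with a warning).
#' @export
gate_live_cells <- function(events, dye_threshold) {
  check_flow_events(events)
  stop_if_not_positive(dye_threshold, "dye_threshold")
  out <- events[events$dye < dye_threshold, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no events below the dye threshold; downstream F is undefined",
            call. = FALSE)
  }
  out
}

#' Derive the GFP-positive threshold from an untransfected control
#'
#' A reproducible stand-in for the hand-drawn positivity line: the q-quantile
#' (type-7, linear interpolation between order statistics) of the live-gated
#' control sample's GFP intensities.
#'
#' @param control Event table for an untransfected control sample.
#' @param dye_threshold Live gate applied before taking the quantile.
#' @param q Quantile, default 0.999.
#' @return The threshold (arbitrary units).
#' @export
derive_gfp_threshold <- function(control, dye_threshold, q = 0.999) {
  check_flow_events(control)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be in (0, 1)", call. = FALSE)
  }
  live <- gate_live_cells(control, dye_threshold)
  if (nrow(live) == 0L) stop("no live control events", call. = FALSE)
  if (nrow(live) < 1 / (1 - q)) {
    warning(sprintf(
      "control has %d live events; the %.4g-quantile threshold is unstable",
      nrow(live), q), call. = FALSE)
  }
  unname(quantile(live$gfp, probs = q, type = 7))
}

#' Per-sample HCR summary F = N x MFI / S
#'
#' Over live-gated events: `S` live events, `N` of them GFP-positive, `MFI`
#' the mean GFP intensity of those N. `F = N * MFI / S` is the
#' expression-weighted positive fraction; when `N = 0`, `MFI` is undefined
#' and `F = 0`.
#'
#' @param events A flow event table.
#' @param cfg A [gate_config()].
#' @return A one-row data frame `S`, `N`, `MFI`, `F`.
#' @export
hcr_summary <- function(events, cfg) {
  stopifnot(inherits(cfg, "gate_config"))
  live <- gate_live_cells(events, cfg$dye_threshold)
  s <- nrow(live)
  if (s == 0L) {
    return(data.frame(S = 0L, N = 0L, MFI = NA_real_, F = NA_real_))
  }
  pos <- live$gfp >= cfg$gfp_threshold
  n <- sum(pos)
  mfi <- if (n > 0L) mean(live$gfp[pos]) else NA_real_
  data.frame(S = s, N = n, MFI = mfi,
             F = if (n > 0L) n * mfi / s else 0)
}

#' Host-cell-reactivation relative expression (%RE)
#'
#' Computes `F = N x MFI / S` for the sample transfected with UV-treated
#' plasmid and the sample transfected with undamaged plasmid under one
#' shared gate, and reports `%RE = 100 x F_t / F_u`: recovered reporter
#' expression as a percentage of the undamaged control, the assay's
#' repair-capacity readout. `%RE` is invariant under a global rescaling of
#' GFP intensities applied to both samples.
#'
#' @param treated Event table, UV-treated plasmid.
#' @param untreated Event table, undamaged plasmid.
#' @param cfg A [gate_config()] applied to both samples.
#' @return A list of class `hcr_result`: `treated` and `untreated` one-row
#'   summaries (see [hcr_summary()]) and `percent_re`. When `F_u` is 0 the
#'   ratio is undefined and `percent_re` is `NA` with a warning.
#' @examples
#' cfg <- gate_config(dye_threshold = 100, gfp_threshold = 10)
#' u <- data.frame(dye = rep(1, 100), gfp = rep(c(50, 1), c(80, 20)))
#' t <- data.frame(dye = rep(1, 100), gfp = rep(c(50, 1), c(20, 80)))
#' relative_expression(t, u, cfg)$percent_re  # 25
#' @export
relative_expression <- function(treated, untreated, cfg) {
  ft <- hcr_summary(treated, cfg)
  fu <- hcr_summary(untreated, cfg)
  pre <- if (is.na(fu$F) || fu$F == 0) {
    warning("F_u is zero or undefined; %RE is undefined", call. = FALSE)
    NA_real_
  } else {
    100 * ft$F / fu$F
  }
  structure(list(treated = ft, untreated = fu, percent_re = pre),
            class = "hcr_result")
}

#' @export
print.hcr_result <- function(x, ...) {
  cat(sprintf("treated:   S = %d, N = %d, MFI = %.4g, F = %.4g\n",
              x$treated$S, x$treated$N, x$treated$MFI, x$treated$F))
  cat(sprintf("untreated: S = %d, N = %d, MFI = %.4g, F = %.4g\n",
              x$untreated$S, x$untreated$N, x$untreated$MFI, x$untreated$F))
  cat(sprintf("%%RE = %.4g%%\n", x$percent_re))
  invisible(x)
}
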