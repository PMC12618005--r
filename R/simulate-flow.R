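#' Parameters for the flow-cytometry event simulator
#'
#' Events are a mixture of live and dead cells; live cells are GFP-positive
#' with probability `transfection_efficiency`. Dye and GFP intensities are
#' log-normal (parameters on the log scale), mimicking the bimodal
#' live/dead viability-dye and GFP+/GFP- distributions of a
#' host-cell-reactivation sample. Scatter channels are emitted as loosely
#' separated log-normals for completeness; gating here uses the dye.
#'
#' @param n_events Number of events (> 0).
#' @param live_fraction Probability an event is a live cell.
#' @param transfection_efficiency Probability a live cell is GFP-positive;
#'   in an HCR pair this is the repair-weighted effective efficiency, so the
#'   treated:untreated ratio of efficiencies sets the true %RE when the
#'   positive-intensity distributions match.
#' @param gfp_pos_meanlog,gfp_pos_sdlog Log-scale GFP parameters, positives.
#' @param gfp_neg_meanlog,gfp_neg_sdlog Log-scale GFP parameters, negatives
#'   (autofluorescence; also used for dead cells).
#' @param dye_live_meanlog,dye_dead_meanlog,dye_sdlog Log-scale viability
#'   dye parameters.
#' @param seed Integer seed.
#' @return An object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(n_events = 50000,
                            live_fraction = 0.9,
                            transfection_efficiency = 0.3,
                            gfp_pos_meanlog = log(1000), gfp_pos_sdlog = 0.5,
                            gfp_neg_meanlog = log(10), gfp_neg_sdlog = 0.5,
                            dye_live_meanlog = log(50),
                            dye_dead_meanlog = log(5000),
                            dye_sdlog = 0.4,
                            seed = 1L) {
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1) {
    stop("`n_events` must be >= 1", call. = FALSE)
  }
  stop_if_not_scalar_prob(live_fraction, "live_fraction")
  stop_if_not_scalar_prob(transfection_efficiency, "transfection_efficiency")
  for (s in c(gfp_pos_sdlog, gfp_neg_sdlog, dye_sdlog)) {
    if (s <= 0) stop("all sdlog parameters must be > 0", call. = FALSE)
  }
  structure(list(n_events = as.integer(n_events),
                 live_fraction = live_fraction,
                 transfection_efficiency = transfection_efficiency,
                 gfp_pos_meanlog = gfp_pos_meanlog,
                 gfp_pos_sdlog = gfp_pos_sdlog,
                 gfp_neg_meanlog = gfp_neg_meanlog,
                 gfp_neg_sdlog = gfp_neg_sdlog,
                 dye_live_meanlog = dye_live_meanlog,
                 dye_dead_meanlog = dye_dead_meanlog,
                 dye_sdlog = dye_sdlog, seed = as.integer(seed)),
            class = "flow_sim_params")
}

#' Simulate a flow-cytometry event table
#'
#' @param params A [flow_sim_params()] object.
#' @return A data frame with per-event columns `event_id`, `dye`, `gfp`,
#'   `fsc`, `ssc` and the ground-truth labels `true_live`, `true_gfp_pos`
#'   (kept for testing; downstream gating never reads them).
#' @examples
#' ev <- simulate_flow_events(flow_sim_params(n_events = 1000, seed = 11))
#' mean(ev$true_gfp_pos[ev$true_live])
#' @export
simulate_flow_events <- function(params) {
  stopifnot(inherits(params, "flow_sim_params"))
  n <- params$n_events
  with_seed(params$seed, {
    live <- runif(n) < params$live_fraction
    pos <- live & (runif(n) < params$transfection_efficiency)
    dye <- numeric(n)
    dye[live] <- rlnorm(sum(live), params$dye_live_meanlog, params$dye_sdlog)
    dye[!live] <- rlnorm(sum(!live), params$dye_dead_meanlog, params$dye_sdlog)
    gfp <- numeric(n)
    gfp[pos] <- rlnorm(sum(pos), params$gfp_pos_meanlog, params$gfp_pos_sdlog)
    gfp[!pos] <- rlnorm(sum(!pos), params$gfp_neg_meanlog, params$gfp_neg_sdlog)
    fsc <- rlnorm(n, ifelse(live, log(5e4), log(2e4)), 0.3)
    ssc <- rlnorm(n, ifelse(live, log(3e4), log(4e4)), 0.4)
    data.frame(event_id = seq_len(n), dye = dye, gfp = gfp,
               fsc = fsc, ssc = ssc,
               true_live = live, true_gfp_pos = pos)
  })
}
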