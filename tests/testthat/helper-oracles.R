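# Independent oracles. Each deliberately uses a different algorithm from the
# package implementation it checks.

# Run-length-encoding bout oracle: rle(), gap closure by relabelling short
# interior mobile runs, re-rle. (The package uses boundary differences and
# tapply-based merging.)
oracle_bouts <- function(flags, frame_rate, min_bout_s = 60, max_gap_s = 0) {
  flags[is.na(flags)] <- FALSE
  gap_frames <- floor(max_gap_s * frame_rate)
  r <- rle(flags)
  if (gap_frames > 0 && length(r$values) > 2) {
    interior <- which(!r$values & r$lengths <= gap_frames)
    interior <- interior[interior > 1 & interior < length(r$values)]
    r$values[interior] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / frame_rate >= min_bout_s)
  data.frame(start = (starts[keep] - 1) / frame_rate,
             end = (starts[keep] - 1 + r$lengths[keep]) / frame_rate,
             duration = r$lengths[keep] / frame_rate)
}

as_plain_bouts <- function(b) {
  data.frame(start = as.numeric(b$start), end = as.numeric(b$end),
             duration = as.numeric(b$duration))
}

# Hand-applied Benjamini-Hochberg step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj_sorted[i] <- min(running_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Brute-force GSEA running sum over every position of the ranked list.
oracle_es <- function(scores, hit, weight = 1) {
  hit <- as.logical(hit)
  if (!any(!hit)) return(1)
  w <- abs(scores)^weight * hit
  tot <- sum(w)
  p_hit <- if (tot == 0) cumsum(hit) / sum(hit) else cumsum(w) / tot
  p_miss <- cumsum(!hit) / sum(!hit)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

# Per-epoch Bernoulli chain, simulated with an explicit frame loop.
oracle_chain <- function(n_epochs, p_doze, p_wake, seed,
                         initial = "active") {
  set.seed(seed)
  s <- integer(n_epochs)
  s[1] <- if (initial == "active") 0L else 1L
  for (i in 2:n_epochs) {
    u <- runif(1)
    s[i] <- if (s[i - 1] == 0L) {
      if (u < p_doze) 1L else 0L
    } else {
      if (u < p_wake) 0L else 1L
    }
  }
  s
}
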