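#' Enrichment score of one gene set against a ranked list
#'
#' The classical weighted Kolmogorov-Smirnov running-sum statistic: walking
#' down the ranked list, the hit CDF (hits weighted by |score|^weight,
#' weight 0 giving the unweighted KS form) minus the miss CDF; the ES is
#' the signed deviation of largest magnitude. Computed from the hit
#' positions alone in O(set size): the running sum attains its extrema
#' immediately after a hit (maxima) or immediately before one (minima).
#'
#' @param scores Numeric scores sorted in decreasing order (the ranked
#'   list's scores).
#' @param hit_idx Integer positions of the set's members in the sorted
#'   list.
#' @param weight Exponent on |score| for hit weighting (default 1).
#' @return The enrichment score in \[-1, 1\]. A set covering the whole
#'   universe has no misses; its ES is 1 by convention.
#' @export
gsea_es <- function(scores, hit_idx, weight = 1) {
  n <- length(scores)
  k <- length(hit_idx)
  if (k == 0L) stop("empty hit set", call. = FALSE)
  if (n == k) return(1)
  pos <- sort(as.integer(hit_idx))
  w <- abs(scores[pos])^weight
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / k, k) else w <- w / tot
  cumw <- cumsum(w)
  miss <- (pos - seq_len(k)) / (n - k)      # miss CDF just before/at each hit
  dev_after <- cumw - miss                  # just after hit j
  dev_before <- c(0, cumw[-k]) - miss       # just before hit j
  cand <- c(dev_after, dev_before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For each set, computes the weighted running-sum enrichment score of its
#' members' positions in the ranked list, then compares it against a null
#' built by drawing the same number of positions uniformly at random
#' (gene-label permutation; phenotype labels are unavailable for preranked
#' summaries). The two-sided permutation p-value is
#' `(1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1)`, NES divides ES by the mean
#' |null ES| of matching sign, and p-values are Benjamini-Hochberg adjusted
#' across the scored sets.
#'
#' @param ranked A `ranked_genes` data frame from [rank_genes()] (or any
#'   data frame with `gene` and `score` sorted by decreasing score).
#' @param sets A named list of character vectors of member gene ids, or a
#'   list as returned by [read_gmt()].
#' @param weight Hit-weight exponent (default 1).
#' @param n_perm Number of null permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked universe; sets outside the bounds are dropped (defaults 10 and
#'   500). Sets with no members in the universe are skipped with a warning.
#' @return A data frame `set`, `size`, `es`, `nes`, `pval`, `padj`, one
#'   row per scored set.
#' @export
preranked_gsea <- function(ranked, sets, weight = 1, n_perm = 1000, seed = 1L,
                           min_size = 10, max_size = 500) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must be uniquely named", call. = FALSE)
  }
  scores <- ranked$score
  if (is.unsorted(rev(scores))) stop("`ranked` must be sorted by decreasing score",
                                     call. = FALSE)
  if (all(scores == 0)) stop("all ranking scores are zero", call. = FALSE)
  universe <- as.character(ranked$gene)
  n <- length(universe)
  rows <- list()
  with_seed(seed, {
    for (nm in names(sets)) {
      members <- unique(as.character(sets[[nm]]))
      pos <- which(universe %in% members)
      k <- length(pos)
      if (k == 0L) {
        warning(sprintf("set '%s' has no members in the ranked universe; skipped",
                        nm), call. = FALSE)
        next
      }
      if (k < min_size || k > max_size) next
      es <- gsea_es(scores, pos, weight)
      null_es <- vapply(seq_len(n_perm), function(b) {
        gsea_es(scores, sample.int(n, k), weight)
      }, numeric(1))
      pval <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign) > 0L) es / mean(abs(same_sign)) else NA_real_
      rows[[nm]] <- data.frame(set = nm, size = k, es = es, nes = nes,
                               pval = pval)
    }
  })
  if (length(rows) == 0L) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), pval = numeric(0), padj = numeric(0)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$padj <- bh_adjust(out$pval)
  out
}
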