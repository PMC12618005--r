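#' One-way analysis of variance from closed-form sums of squares
#'
#' Implements the fixed-effects one-way ANOVA directly from its definition
#' (F = MS_between / MS_within with the usual partition of sums of squares)
#' so the figure-level group comparisons are oracle-checkable.
#'
#' @param groups A named or unnamed list of numeric vectors, one per group;
#'   at least two non-empty groups, with total n greater than the number of
#'   groups.
#' @return A list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`. When the within-group variance is exactly zero and the group
#'   means differ, `F` is `Inf` and `p` is 0.
#' @examples
#' one_way_anova(list(ctrl = c(1, 2), uv = c(3, 4)))  # F = 8, df (1, 2)
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("every group must be non-empty", call. = FALSE)
  if (anyNA(unlist(groups))) stop("missing values in groups", call. = FALSE)
  k <- length(groups)
  n <- sum(n_i)
  if (n <= k) stop("total n must exceed the number of groups", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / n
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfb <- k - 1L
  dfw <- n - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    if (msb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- msb / msw
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = dfb, df_within = dfw, p = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F%d,%d = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Unpaired two-sample t test (Welch or pooled) from closed forms
#'
#' Two-sided throughout. Degenerate input with zero variance in both samples
#' and equal means returns `t = 0, p = 1`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) statistic with
#'   Satterthwaite df (default) or the pooled Student statistic.
#' @return A list of class `ttest_result`: `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(a, b, welch = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  d <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- if (se2 > 0) se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
          else na + nb - 2
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    t <- if (d == 0) 0 else Inf * sign(d)
    p <- if (d == 0) 1 else 0
  } else {
    t <- d / sqrt(se2)
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("unpaired t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Per-group mean, SEM and n
#'
#' SEM uses the sample standard deviation (n - 1 denominator) over the
#' square root of n; a single observation has undefined SEM.
#'
#' @param groups A named list of non-empty numeric vectors.
#' @return Data frame `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L) {
    stop("need a non-empty list of groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  nm <- names(groups) %||% as.character(seq_along(groups))
  data.frame(
    group = nm,
    n = lengths(groups),
    mean = vapply(groups, function(x) mean(as.numeric(x)), numeric(1)),
    sem = vapply(groups, function(x) {
      x <- as.numeric(x)
      if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
    }, numeric(1)),
    row.names = NULL)
}
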