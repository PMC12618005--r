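#' Parameters for the paired differential-expression table simulator
#'
#' Emulates the structure behind a bi-directional (surface vs cave)
#' response comparison: a shared gene universe in which some genes respond
#' to treatment in both populations, some in exactly one, and the rest are
#' null. Each population's table is generated as an independent z-test per
#' gene: the log2 fold-change estimate is normal around the planted effect
#' (or zero) with standard error `se_log2fc`, the p-value is the two-sided
#' normal tail, and `padj` is Benjamini-Hochberg. Null genes therefore have
#' exactly uniform p-values and responders' power is governed by
#' `effect_size_log2fc / se_log2fc`.
#'
#' @param n_genes Universe size.
#' @param n_shared,n_surface_only,n_cave_only Planted responder counts;
#'   their sum cannot exceed `n_genes`.
#' @param effect_size_log2fc Absolute planted log2 fold change (default 2);
#'   each responder's sign is drawn once and, for shared responders, used
#'   in both populations.
#' @param se_log2fc Standard error of the log2FC estimate (default 0.4,
#'   a typical bulk RNA-seq scale).
#' @param seed Integer seed.
#' @return An object of class `de_sim_params`.
#' @export
de_sim_params <- function(n_genes = 2000, n_shared = 0, n_surface_only = 0,
                          n_cave_only = 0, effect_size_log2fc = 2,
                          se_log2fc = 0.4, seed = 1L) {
  counts <- c(n_genes, n_shared, n_surface_only, n_cave_only)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("gene counts must be non-negative integers", call. = FALSE)
  }
  if (n_shared + n_surface_only + n_cave_only > n_genes) {
    stop("planted responder counts exceed `n_genes`", call. = FALSE)
  }
  stop_if_not_positive(se_log2fc, "se_log2fc")
  structure(list(n_genes = as.integer(n_genes), n_shared = as.integer(n_shared),
                 n_surface_only = as.integer(n_surface_only),
                 n_cave_only = as.integer(n_cave_only),
                 effect_size_log2fc = effect_size_log2fc,
                 se_log2fc = se_log2fc, seed = as.integer(seed)),
            class = "de_sim_params")
}

#' Simulate paired surface/cave differential-expression tables
#'
#' @param params A [de_sim_params()] object.
#' @return A list: `surface` and `cave` DEG tables (data frames `gene`,
#'   `log2fc`, `pvalue`, `padj`) and `truth`, a data frame with each gene's
#'   planted `category` (`shared`, `surface_specific`, `cave_specific`,
#'   `nonresponsive`) and `direction` (+1/-1/0).
#' @export
simulate_de_tables <- function(params) {
  stopifnot(inherits(params, "de_sim_params"))
  n <- params$n_genes
  with_seed(params$seed, {
    genes <- sprintf("gene_%05d", seq_len(n))
    category <- rep("nonresponsive", n)
    idx <- sample.int(n, params$n_shared + params$n_surface_only +
                        params$n_cave_only)
    category[idx] <- rep(c("shared", "surface_specific", "cave_specific"),
                         c(params$n_shared, params$n_surface_only,
                           params$n_cave_only))
    dir <- integer(n)
    dir[idx] <- sample(c(-1L, 1L), length(idx), replace = TRUE)
    one_table <- function(responds) {
      mu <- ifelse(responds, dir * params$effect_size_log2fc, 0)
      lfc <- rnorm(n, mu, params$se_log2fc)
      z <- lfc / params$se_log2fc
      p <- 2 * pnorm(-abs(z))
      data.frame(gene = genes, log2fc = lfc, pvalue = p,
                 padj = p.adjust(p, method = "BH"))
    }
    surface <- one_table(category %in% c("shared", "surface_specific"))
    cave <- one_table(category %in% c("shared", "cave_specific"))
    list(surface = surface, cave = cave,
         truth = data.frame(gene = genes, category = category,
                            direction = dir))
  })
}
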