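#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' [stats::p.adjust()]); the significance rule throughout the pipeline is
#' adjusted p < 0.05.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\]; `NA` is an error.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues)) stop("p-values must not be missing", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

check_deg_table <- function(x, name) {
  need <- c("gene", "log2fc", "pvalue", "padj")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop(sprintf("`%s` must have columns %s", name,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$gene)) {
    stop(sprintf("duplicated gene ids in `%s`", name), call. = FALSE)
  }
  invisible(x)
}

#' Classify per-population treatment responses
#'
#' A gene *responds* in a population when its adjusted p-value is below
#' `alpha` in that population's treatment contrast. Genes responding in
#' both populations are `shared`, in exactly one `surface_specific` /
#' `cave_specific`, otherwise `nonresponsive`; directions come from the
#' sign of the log2 fold change. Genes absent from one table count as
#' non-responding there.
#'
#' @param surface,cave DEG tables (`gene`, `log2fc`, `pvalue`, `padj`).
#' @param alpha Significance cut-off on `padj` (default 0.05).
#' @return A data frame, one row per gene in the union: `gene`, `category`,
#'   `surface_direction`, `cave_direction` (`"up"`, `"down"` or `"none"`),
#'   and the per-population `log2fc`/`padj` columns.
#' @export
classify_population_response <- function(surface, cave, alpha = 0.05) {
  check_deg_table(surface, "surface")
  check_deg_table(cave, "cave")
  stop_if_not_scalar_prob(alpha, "alpha")
  m <- merge(surface[, c("gene", "log2fc", "padj")],
             cave[, c("gene", "log2fc", "padj")],
             by = "gene", all = TRUE, suffixes = c("_surface", "_cave"))
  sig_s <- !is.na(m$padj_surface) & m$padj_surface < alpha
  sig_c <- !is.na(m$padj_cave) & m$padj_cave < alpha
  category <- ifelse(sig_s & sig_c, "shared",
              ifelse(sig_s, "surface_specific",
              ifelse(sig_c, "cave_specific", "nonresponsive")))
  dir_of <- function(sig, lfc) {
    ifelse(!sig | is.na(lfc), "none", ifelse(lfc > 0, "up", "down"))
  }
  data.frame(gene = m$gene, category = category,
             surface_direction = dir_of(sig_s, m$log2fc_surface),
             cave_direction = dir_of(sig_c, m$log2fc_cave),
             surface_log2fc = m$log2fc_surface, surface_padj = m$padj_surface,
             cave_log2fc = m$log2fc_cave, cave_padj = m$padj_cave)
}

#' Count differentially expressed genes per table
#'
#' @param tables Either a named list of DEG tables, or a named list of
#'   named lists of DEG tables (e.g. tissue -> population -> table).
#' @param alpha Cut-off on `padj` (default 0.05).
#' @return A data frame of counts: `table`/`n_deg` for a flat list, or
#'   `tissue`/`population`/`n_deg` for a nested one.
#' @export
count_degs <- function(tables, alpha = 0.05) {
  stop_if_not_scalar_prob(alpha, "alpha")
  n_sig <- function(tab, nm) {
    check_deg_table(tab, nm)
    sum(!is.na(tab$padj) & tab$padj < alpha)
  }
  if (all(vapply(tables, is.data.frame, logical(1)))) {
    return(data.frame(table = names(tables),
                      n_deg = vapply(names(tables), function(nm)
                        n_sig(tables[[nm]], nm), integer(1)),
                      row.names = NULL))
  }
  rows <- lapply(names(tables), function(ti) {
    inner <- tables[[ti]]
    data.frame(tissue = ti, population = names(inner),
               n_deg = vapply(names(inner), function(pi)
                 n_sig(inner[[pi]], paste(ti, pi, sep = "/")), integer(1)),
               row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Signed -log10(p) gene ranking
#'
#' Ranks genes by both magnitude and direction of response: score =
#' -log10(pvalue) x sign(log2fc). p-values of exactly zero are clamped to
#' the smallest positive p in the table (floor 1e-300) so scores stay
#' finite; a log2 fold change of exactly zero gives score 0, the only
#' direction-free value. The list is sorted by decreasing score with ties
#' broken lexicographically by gene id, giving a deterministic total order.
#'
#' @param table A DEG table (`gene`, `log2fc`, `pvalue`, ...).
#' @return A data frame `gene`, `score`, sorted for use as a preranked
#'   GSEA input.
#' @export
rank_genes <- function(table) {
  need <- c("gene", "log2fc", "pvalue")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("`table` must have columns gene, log2fc, pvalue", call. = FALSE)
  }
  if (anyDuplicated(table$gene)) stop("duplicated gene ids", call. = FALSE)
  if (anyNA(table$log2fc)) stop("missing log2fc", call. = FALSE)
  p <- table$pvalue
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing", call. = FALSE)
  }
  floor_p <- if (any(p > 0)) max(min(p[p > 0]), 1e-300) else 1e-300
  score <- -log10(pmax(p, floor_p)) * sign(table$log2fc)
  ord <- order(-score, as.character(table$gene))
  out <- data.frame(gene = as.character(table$gene)[ord], score = score[ord])
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Fold changes by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale per sample and gene;
#' per sample, dCt = Ct(target) - Ct(housekeeping); per gene and
#' condition, ddCt = mean dCt(condition) - mean dCt(reference) and the
#' fold change is `2^(-ddCt)`. The reference condition's fold change is
#' exactly 1 by construction.
#'
#' @param ct Long-format data frame with columns `sample`, `condition`,
#'   `gene`, `ct`; one or more replicate wells per combination.
#' @param housekeeping_gene Normalization gene (e.g. `"rpl13a"`); must be
#'   measured in every sample.
#' @param reference_condition Condition whose mean dCt anchors ddCt.
#' @return A list: `delta_ct` (per sample x target gene) and
#'   `fold_changes` (per target gene x condition: `delta_delta_ct`,
#'   `fold_change`).
#' @examples
#' ct <- expand.grid(sample = c("s1", "s2"), gene = c("per1", "rpl13a"),
#'                   stringsAsFactors = FALSE)
#' ct$condition <- ifelse(ct$sample == "s1", "control", "treated")
#' ct$ct <- c(22, 20, 15, 15)
#' delta_delta_ct(ct, "rpl13a", "control")$fold_changes
#' @export
delta_delta_ct <- function(ct, housekeeping_gene, reference_condition) {
  need <- c("sample", "condition", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("`ct` must have columns sample, condition, gene, ct", call. = FALSE)
  }
  if (!reference_condition %in% ct$condition) {
    stop("reference condition not present", call. = FALSE)
  }
  agg <- aggregate(ct ~ sample + condition + gene, data = ct, FUN = mean)
  hk <- agg[agg$gene == housekeeping_gene, c("sample", "ct")]
  names(hk)[2L] <- "ct_hk"
  targets <- agg[agg$gene != housekeeping_gene, , drop = FALSE]
  missing_hk <- setdiff(unique(targets$sample), hk$sample)
  if (length(missing_hk) > 0L) {
    stop(sprintf("no %s measurement for sample(s): %s", housekeeping_gene,
                 paste(missing_hk, collapse = ", ")), call. = FALSE)
  }
  d <- merge(targets, hk, by = "sample")
  d$delta_ct <- d$ct - d$ct_hk
  cond_means <- aggregate(delta_ct ~ gene + condition, data = d, FUN = mean)
  ref <- cond_means[cond_means$condition == reference_condition,
                    c("gene", "delta_ct")]
  names(ref)[2L] <- "delta_ct_ref"
  fc <- merge(cond_means, ref, by = "gene")
  fc$delta_delta_ct <- fc$delta_ct - fc$delta_ct_ref
  fc$fold_change <- 2^(-fc$delta_delta_ct)
  list(delta_ct = d[, c("sample", "condition", "gene", "delta_ct")],
       fold_changes = fc[order(fc$gene, fc$condition),
                         c("gene", "condition", "delta_delta_ct",
                           "fold_change")])
}
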