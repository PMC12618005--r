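test_that("BH adjustment equals the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(51)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, NA)), "missing")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("population response classification applies the padj rule", {
  tab <- function(padj, lfc = rep(1, length(padj))) {
    data.frame(gene = paste0("g", seq_along(padj)), log2fc = lfc,
               pvalue = padj / 2, padj = padj)
  }
  cl <- classify_population_response(tab(c(0.01, 0.01, 0.20, 0.20),
                                          c(1, -2, 1, 1)),
                                     tab(c(0.01, 0.20, 0.01, 0.20)))
  expect_equal(cl$category,
               c("shared", "surface_specific", "cave_specific",
                 "nonresponsive"))
  expect_equal(cl$surface_direction, c("up", "down", "none", "none"))
  expect_equal(cl$cave_direction, c("up", "none", "up", "none"))
  # genes absent from one table count as non-responding there
  cl2 <- classify_population_response(tab(c(0.01, 0.01)),
                                      tab(0.01)[1, , drop = FALSE])
  expect_equal(cl2$category, c("shared", "surface_specific"))
  dup <- rbind(tab(0.01), tab(0.01))
  expect_error(classify_population_response(dup, tab(0.01)), "duplicated")
})

test_that("DEG counts respect the alpha cut-off monotonically", {
  tab <- data.frame(gene = paste0("g", 1:100), log2fc = 1,
                    pvalue = seq(0.0005, 0.05, length.out = 100),
                    padj = seq(0.001, 0.1, length.out = 100))
  expect_equal(count_degs(list(none = within(tab, padj <- padj + 0.9)))$n_deg, 0L)
  counts <- vapply(c(0.1, 0.05, 0.01),
                   function(a) count_degs(list(t = tab), alpha = a)$n_deg,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # nested tissue -> population layout
  nested <- count_degs(list(brain = list(surface = tab, cave = tab),
                            fin = list(surface = tab, cave = tab)))
  expect_equal(dim(nested), c(4L, 3L))
  expect_equal(nested$n_deg, rep(sum(tab$padj < 0.05), 4))
  # in the separation limit every planted responder is counted (a handful
  # of null genes may ride along at the nominal FDR)
  sim <- simulate_de_tables(de_sim_params(n_genes = 1000, n_shared = 100,
                                          effect_size_log2fc = 8, seed = 12))
  planted <- sim$truth$gene[sim$truth$category == "shared"]
  expect_true(all(sim$surface$padj[match(planted, sim$surface$gene)] < 0.05))
  n_called <- count_degs(list(s = sim$surface))$n_deg
  expect_gte(n_called, 100L)
  expect_lte(n_called - 100L, 15L)
})

test_that("gene ranking scores are signed -log10 p with deterministic ties", {
  tab <- data.frame(gene = c("b", "a", "c", "d"),
                    log2fc = c(2, -2, 1, 0),
                    pvalue = c(0.01, 0.01, 1, 0.001))
  r <- rank_genes(tab)
  expect_equal(r$score[r$gene == "b"], 2)
  expect_equal(r$score[r$gene == "a"], -2)
  expect_equal(r$score[r$gene == "c"], 0)
  expect_equal(r$score[r$gene == "d"], 0)   # sign(0) gives the neutral score
  expect_true(!is.unsorted(rev(r$score)))
  expect_equal(r$gene[r$score == 0], c("c", "d"))  # lexicographic ties
  # p = 0 is clamped to the smallest positive p in the table
  tab0 <- data.frame(gene = c("x", "y"), log2fc = c(1, 1),
                     pvalue = c(0, 1e-20))
  r0 <- rank_genes(tab0)
  expect_true(all(is.finite(r0$score)))
  expect_equal(r0$score, c(20, 20))
  expect_error(rank_genes(data.frame(gene = "g", log2fc = NA, pvalue = 0.1)),
               "log2fc")
})

test_that("delta-delta-Ct reproduces its defining arithmetic", {
  ct <- data.frame(
    sample = rep(c("r1", "r2", "t1", "t2"), each = 2),
    condition = rep(c("control", "treated"), each = 4),
    gene = rep(c("per1", "rpl13a"), 4),
    ct = c(27, 20, 27, 20, 25, 20, 25, 20))
  res <- delta_delta_ct(ct, "rpl13a", "control")
  fc <- res$fold_changes
  expect_equal(fc$fold_change[fc$condition == "control"], 1)  # exactly
  expect_equal(fc$delta_delta_ct[fc$condition == "treated"], -2)
  expect_equal(fc$fold_change[fc$condition == "treated"], 4)
  # swapping the reference inverts the fold change
  swapped <- delta_delta_ct(ct, "rpl13a", "treated")$fold_changes
  expect_equal(swapped$fold_change[swapped$condition == "control"], 0.25)
  # identical Cts everywhere: fold change 1 throughout
  flat <- ct
  flat$ct <- rep(c(24, 20), 4)
  expect_true(all(delta_delta_ct(flat, "rpl13a",
                                 "control")$fold_changes$fold_change == 1))
  # replicates are averaged on the Ct scale before differencing
  reps <- rbind(ct, within(ct[ct$gene == "per1", ], ct <- ct + 1))
  res_reps <- delta_delta_ct(reps, "rpl13a", "control")
  expect_equal(res_reps$fold_changes$delta_delta_ct[
    res_reps$fold_changes$condition == "treated"], -2)
  # a sample without the housekeeping gene is named in the error
  broken <- ct[!(ct$sample == "t2" & ct$gene == "rpl13a"), ]
  expect_error(delta_delta_ct(broken, "rpl13a", "control"), "t2")
})
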