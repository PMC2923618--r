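mkm <- function(v) {
  dimnames(v) <- list(paste0("g", seq_len(nrow(v))), paste0("s", seq_len(ncol(v))))
  expr_matrix(v, value_scale = "intensity")
}

test_that("probe correlations recover self, negation and rank agreement", {
  q <- c(s1 = 0.2, s2 = 0.5, s3 = 0.7, s4 = 0.9)
  m <- mkm(rbind(c(0.2, 0.5, 0.7, 0.9),   # equals the quantifier
                 -c(0.2, 0.5, 0.7, 0.9),  # its negation
                 c(1, 4, 9, 16),          # monotone but curved
                 c(3, 3, 3, 3)))          # zero variance
  ct <- probe_correlations(m, q, quantifier_name = "H")
  expect_equal(ct$pearson[1], 1, tolerance = 1e-12)
  expect_equal(ct$spearman[1], 1, tolerance = 1e-12)
  expect_equal(ct$pearson[2], -1, tolerance = 1e-12)
  expect_equal(ct$spearman[2], -1, tolerance = 1e-12)
  expect_equal(ct$spearman[3], 1, tolerance = 1e-12)
  expect_lt(ct$pearson[3], 1)
  expect_true(is.na(ct$pearson[4]) && is.na(ct$spearman[4]))
  expect_equal(ct$n_used, rep(4L, 4))
  expect_error(probe_correlations(m, c(a = 1, b = 2, c = 3, d = 4)), "match")
})

test_that("pairwise-complete handling and the <3-pairs rule", {
  q <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  v <- rbind(c(1, 2, NA, 4), c(NA, NA, 1, 2))
  ct <- probe_correlations(mkm(v), q)
  expect_equal(ct$n_used, c(3L, 2L))
  expect_equal(ct$pearson[1], 1, tolerance = 1e-12)  # on the 3 complete pairs
  expect_true(is.na(ct$pearson[2]))                  # too few pairs -> undefined
})

test_that("difference ranking sorts by the declared key with stable ties", {
  tA <- structure(data.frame(probe_id = c("TP63", "pA", "pB", "pC"),
                             spearman = c(-0.63632, 0.5, -0.5, NA),
                             n_used = 10L),
                  class = c("correlation_table", "data.frame"))
  tB <- structure(data.frame(probe_id = c("pB", "pC", "TP63", "pA"),
                             spearman = c(0, 0.2, 0.62138, 0),
                             n_used = 10L),
                  class = c("correlation_table", "data.frame"))
  r <- rank_by_difference(tA, tB, "abs_desc")
  expect_identical(r$probe_id[1], "TP63")
  expect_equal(r$diff[1], -1.2577, tolerance = 1e-9)
  expect_false("pC" %in% r$probe_id)        # undefined correlation excluded
  expect_identical(r$rank, seq_len(nrow(r)))
  # abs mode ties +0.5 / -0.5 and breaks by probe ID; signed orders + first
  expect_identical(r$probe_id[2:3], c("pA", "pB"))
  rs <- rank_by_difference(tA, tB, "signed_desc")
  expect_identical(rs$probe_id, c("pA", "pB", "TP63"))
  # all-equal correlations rank in probe-ID order
  same <- rank_by_difference(tA, tA, "abs_desc")
  expect_identical(same$probe_id, sort(same$probe_id))
  # swap symmetry: abs key invariant, signed key negates
  expect_equal(rank_by_difference(tB, tA, "abs_desc")$diff[1], 1.2577,
               tolerance = 1e-9)
  bad <- tB; bad$probe_id[1] <- "other"
  expect_error(rank_by_difference(tA, bad), "different probe sets")
})

test_that("sign-reversal flagging needs opposite signs at sufficient magnitude", {
  tb <- function(ids, r) structure(data.frame(probe_id = ids, spearman = r),
                                   class = c("correlation_table", "data.frame"))
  tA <- tb(c("rev", "same", "weak"), c(-0.64, -0.9, -0.6))
  tB <- tb(c("rev", "same", "weak"), c(0.62, -0.8, 0.1))
  out <- flag_sign_reversals(tA, tB, threshold = 0.5)
  expect_identical(out$probe_id, "rev")
  expect_identical(nrow(flag_sign_reversals(tA, tB, threshold = 0.7)), 0L)
})

test_that("group panels aggregate per sample then per group", {
  m <- mkm(rbind(c(1, 3, 5, 7), c(3, 1, 5, 7)))
  ann <- tiny_annotation(paste0("s", 1:4), c("a", "a", "b", "b"))
  gp <- group_panel(m, c("g1", "g2"), ann, stat = "mean")
  expect_equal(sort(gp$per_sample$value[gp$per_sample$group == "a"]), c(2, 2))
  expect_equal(gp$per_group$value[gp$per_group$group == "b"], 6)
  gp1 <- group_panel(m, "g1", ann, stat = "mean")
  expect_equal(sort(gp1$per_sample$value), sort(unname(m$values[1, ])))
  expect_error(group_panel(m, "missing_probe", ann), "missing_probe")
})

test_that("a planted declining panel yields strictly decreasing group aggregates", {
  spec <- synthetic_spec(n_probes = 300, n_markers_up = 0, n_markers_down = 15,
                         groups = c(normal = 10, primary = 10, metastasis = 10),
                         alpha = c(50, 5, 0.5), marker_effect = 50)
  sim <- simulate_expression(spec, seed = 3)
  gp <- group_panel(sim$matrix, sim$truth$marker_down, sim$annotation, "mean")
  v <- setNames(gp$per_group$value, gp$per_group$group)
  expect_true(v["normal"] > v["primary"] && v["primary"] > v["metastasis"])
})

test_that("Spearman is invariant to monotone transforms of expression", {
  set.seed(9)
  q <- setNames(runif(12), paste0("s", 1:12))
  v <- matrix(rnorm(5 * 12), 5, 12)
  m <- mkm(v)
  mt <- mkm(exp(2 * v) + 1)   # strictly increasing transform
  c1 <- probe_correlations(m, q, "spearman")
  c2 <- probe_correlations(mt, q, "spearman")
  expect_equal(c1$spearman, c2$spearman, tolerance = 1e-12)
  # rank-valued, tie-free variables: Pearson equals Spearman exactly
  rv <- mkm(matrix(as.numeric(replicate(3, sample(1:12))), ncol = 12, byrow = TRUE))
  qr <- setNames(as.numeric(sample(1:12)), paste0("s", 1:12))
  cb <- probe_correlations(rv, qr, "both")
  expect_equal(cb$pearson, cb$spearman, tolerance = 1e-12)
})
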