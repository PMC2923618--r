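test_that("surprisal follows -ln p with its boundary cases", {
  expect_equal(surprisal(1), 0)
  expect_equal(surprisal(1 / exp(1)), 1)
  expect_equal(surprisal(0.5), log(2))
  expect_error(surprisal(0))
  expect_error(surprisal(-0.1))
})

test_that("profile construction normalizes under each transform", {
  expect_equal(as.numeric(build_profile(c(2, 2, 2, 2, 2))), rep(0.2, 5))
  p1 <- build_profile(c(4, 3, 2, 1, 0.1))
  expect_equal(as.numeric(p1), c(4, 3, 2, 1, 0.1) / 10.1, tolerance = 1e-12)
  expect_equal(round(as.numeric(p1), 5), c(0.39604, 0.29703, 0.19802, 0.09901, 0.00990))
  # exp2 undoes a log2 ratio
  expect_equal(as.numeric(build_profile(c(0, 1), transform = "exp2")), c(1, 2) / 3)
  # shift makes the minimum eps
  ps <- build_profile(c(-1, 0, 1), transform = "shift", eps = 0.5)
  expect_equal(as.numeric(ps), c(0.5, 1.5, 2.5) / 4.5)
  # clip floors non-positives; zero eps with negatives is an error
  expect_equal(sum(build_profile(c(0, 1), transform = "identity_clip", eps = 1e-6)), 1)
  expect_error(build_profile(c(-1, 1), transform = "identity_clip", eps = 0),
               "positive")
  expect_error(build_profile(c(1)), "at least 2")
  expect_error(build_profile(c(1, NA)), "missing")
})

test_that("entropy hits its bounds and the worked-example value", {
  expect_equal(shannon_entropy(uniform_profile(5)), log(5))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  p3 <- build_profile(c(5, 2, 5, 1, 3))
  expect_equal(shannon_entropy(p3), 1.47406, tolerance = 5e-6)
  expect_equal(normalized_entropy(uniform_profile(7)), 1)
  expect_equal(normalized_entropy(c(0, 1, 0)), 0)
  expect_equal(round(normalized_entropy(build_profile(c(4, 3, 2, 1, 0.1))), 2), 0.82)
  expect_equal(round(normalized_entropy(p3), 2), 0.92)
})

test_that("JS divergence is symmetric, bounded and zero only at equality", {
  v <- worked_example_values()
  P <- apply(v, 2, build_profile)
  expect_equal(jensen_shannon(P[, 1], P[, 1]), 0)
  expect_equal(round(jensen_shannon(P[, 1], P[, 2]), 6), 0.286636)
  expect_equal(round(jensen_shannon(P[, 3], P[, 4]), 6), 0.035851)
  expect_error(jensen_shannon(P[, 1], uniform_profile(3)), "support")
  set.seed(1)
  for (i in 1:50) {
    N <- sample(2:20, 1)
    a <- random_profile(N); b <- random_profile(N)
    js <- jensen_shannon(a, b)
    expect_gte(js, 0)
    expect_lte(js, log(2) + 1e-12)
    expect_equal(js, jensen_shannon(b, a), tolerance = 1e-14)
  }
  # disjoint supports approach the ln 2 bound
  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
})

test_that("reference averaging honours both modes and their coincidence case", {
  v <- worked_example_values()
  P <- apply(v, 2, build_profile)
  same <- average_profile(cbind(a = P[, 1], b = P[, 1]))
  expect_equal(same$p, as.numeric(P[, 1]))
  expect_equal(average_profile(cbind(c(1, 0), c(0, 1)))$p, c(0.5, 0.5))
  # samples 1 and 2 have equal raw sums, so the two averaging modes agree
  m1 <- average_profile(P[, 1:2], mode = "mean_of_pdfs")
  m2 <- average_profile(mode = "pdf_of_mean", x = v[, 1:2])
  expect_equal(m1$p, m2$p, tolerance = 1e-12)
  # unequal sums: modes genuinely differ
  x <- cbind(c(10, 1), c(1, 1))
  d1 <- average_profile(apply(x, 2, build_profile), mode = "mean_of_pdfs")
  d2 <- average_profile(mode = "pdf_of_mean", x = x)
  expect_gt(max(abs(d1$p - d2$p)), 1e-3)
  expect_error(average_profile(matrix(numeric(0), 2, 0)), "no profiles")
})

test_that("Q0 matches the uniform closed form and normalizes the delta extremum", {
  closed <- function(N) 1 / (log(2 * N) - ((N + 1) / (2 * N)) * log(N + 1) - 0.5 * log(N))
  for (N in c(2, 5, 17)) {
    expect_equal(q0(uniform_profile(N)), closed(N), tolerance = 1e-12)
    # brute force over all N delta profiles
    brute <- max(vapply(seq_len(N), function(k) {
      d <- rep(0, N); d[k] <- 1
      jensen_shannon(d, uniform_profile(N))
    }, 0))
    expect_equal(q0(uniform_profile(N)), 1 / brute, tolerance = 1e-12)
  }
  set.seed(2)
  for (i in 1:20) {
    ref <- random_profile(sample(2:15, 1))
    brute <- max(vapply(seq_along(ref), function(k) {
      d <- rep(0, length(ref)); d[k] <- 1
      jensen_shannon(d, ref)
    }, 0))
    expect_equal(q0(ref) * brute, 1, tolerance = 1e-12)
  }
})

test_that("complexities vanish at order and disorder and stay in [0, 1]", {
  expect_equal(mpr_complexity(uniform_profile(9)), 0)
  expect_equal(mpr_complexity(c(1, 0, 0, 0)), 0)
  p1 <- build_profile(c(4, 3, 2, 1, 0.1))
  expect_equal(mpr_complexity(p1),
               q0(uniform_profile(5)) * jensen_shannon(p1, uniform_profile(5)) *
                 normalized_entropy(p1), tolerance = 1e-14)
  ref <- average_profile(cbind(a = as.numeric(p1)))
  expect_equal(m_complexity(p1, ref), 0)
  expect_equal(m_complexity(p1, uniform_profile(5)), mpr_complexity(p1))
  expect_error(m_complexity(p1, uniform_profile(4)), "support")
})

test_that("peaked metastasis-like samples score higher M-complexity vs a normal reference", {
  spec <- synthetic_spec(n_probes = 300, groups = c(normal = 12, metastasis = 12),
                         alpha = c(30, 0.8), n_markers_up = 0, n_markers_down = 0)
  hits <- 0L
  for (seed in 1:10) {
    sim <- simulate_expression(spec, seed)
    ref <- reference_profile(sim$matrix, sim$annotation, "normal")
    qt <- quantify_samples(sim$matrix, refs = list(ref), ann = sim$annotation)
    cm <- tapply(qt$`C_M_M-normal`, qt$group, mean)
    hits <- hits + (cm["metastasis"] > cm["normal"])
  }
  expect_gte(hits, 9L)
})

test_that("quantify_samples composes the table the worked example prints", {
  m <- worked_example()
  qt <- quantify_samples(m)
  expect_s3_class(qt, "quantifier_table")
  expect_equal(round(qt$H, 2), c(0.82, 0.82, 0.92, 1.00))
  expect_equal(qt$S, qt$H * log(5), tolerance = 1e-12)
  # a uniform reference reproduces the MPR columns
  uni <- average_profile(cbind(u = uniform_profile(5)), name = "uniform")
  qt2 <- quantify_samples(m, refs = list(uni))
  expect_equal(qt2$C_M_uniform, qt2$C_MPR, tolerance = 1e-12)
  expect_equal(qt2$js_uniform[4], 0, tolerance = 1e-12)
  # single-sample matrix still yields one row
  one <- expr_matrix(m$values[, 1, drop = FALSE], value_scale = "intensity")
  expect_equal(nrow(quantify_samples(one)), 1L)
  # mismatched reference support is an error
  bad <- average_profile(cbind(u = uniform_profile(4)), name = "bad")
  expect_error(quantify_samples(m, refs = list(bad)), "different probe set")
  # missing cells must be handled upstream
  v <- m$values; v[1, 1] <- NA
  expect_error(quantify_samples(expr_matrix(v)), "preprocess")
  # plane extraction selects coordinate columns
  pc <- plane_coordinates(qt, "H", "C_MPR")
  expect_identical(names(pc), c("sample_id", "H", "C_MPR"))
  expect_error(plane_coordinates(qt, "H", "nope"), "nope")
})
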