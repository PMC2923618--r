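# Independent oracles and fixture builders used across the suite.

# Term-by-term entropy accumulation (no vectorized identity shared with
# the implementation's -sum(p*log(p)) route beyond log itself).
oracle_entropy <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

# JS via its Kullback-Leibler decomposition, a different identity from the
# implementation's mixture-entropy form:
# JS(p, q) = KL(p || m)/2 + KL(q || m)/2, m = (p + q)/2.
oracle_js <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i])
    s
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

# Random rational profile: integer weights over a small support.
random_rational_profile <- function(N, max_w = 20L) {
  w <- sample.int(max_w, N, replace = TRUE)
  w / sum(w)
}

# Random real profile via normalized uniforms.
random_profile <- function(N) {
  w <- stats::runif(N)
  w / sum(w)
}

# The worked-example matrix as a plain matrix (probes x samples), matching
# the bundled fixture.
worked_example_values <- function() {
  v <- cbind(Sample1 = c(4, 3, 2, 1, 0.1),
             Sample2 = c(0.1, 1, 2, 3, 4),
             Sample3 = c(5, 2, 5, 1, 3),
             Sample4 = c(2, 2, 2, 2, 2))
  rownames(v) <- paste0("Gene", 1:5)
  v
}

# Write an expr_matrix-shaped TSV from raw character cells (for parser
# edge cases: missing tokens, ragged rows, duplicates).
write_raw_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

tiny_annotation <- function(ids, groups, exclude = FALSE) {
  data.frame(sample_id = ids, group = groups,
             exclude = rep_len(exclude, length(ids)), stringsAsFactors = FALSE)
}
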