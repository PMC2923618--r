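## Core information-theory quantifiers. Natural logarithms throughout:
## the worked-example JS values (0.286636, 0.035851, ...) are only
## reproduced in nats; normalized entropy is base-invariant.

.xlogx <- function(p) {
  out <- p * log(p)
  out[p == 0] <- 0  # 0 * ln 0 = 0 by convention
  out
}

.check_profile <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 2L)
    stop("'", arg, "' must be a numeric probability vector of length >= 2")
  if (anyNA(p) || any(p < 0))
    stop("'", arg, "' has negative or missing components")
  if (abs(sum(p) - 1) > 1e-9)
    stop("'", arg, "' does not sum to 1 (sum = ", format(sum(p)), ")")
  invisible(p)
}

#' Shannon information content of a single event
#'
#' @param p event probability, in (0, 1].
#' @return surprisal \eqn{-\ln p} in nats.
#' @export
surprisal <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("probabilities must lie in (0, 1]")
  -log(p)
}

#' Transform raw expression values into positives
#'
#' Probability profiles require strictly positive weights, but microarray
#' matrices may hold zeros or negative log2-ratios. Three transforms are
#' offered: `identity_clip` keeps values as they are but raises anything
#' below `eps` to `eps` (for intensity data); `shift` adds a constant so
#' the minimum becomes `eps`; `exp2` maps x to 2^x (undoes a log2 ratio).
#'
#' @param x numeric vector of raw expression values.
#' @param transform `"identity_clip"`, `"shift"` or `"exp2"`.
#' @param eps positivity floor for `identity_clip` / `shift`.
#' @return positive numeric vector, same length.
#' @export
transform_expression <- function(x, transform = c("identity_clip", "shift", "exp2"),
                                 eps = 1e-12) {
  transform <- match.arg(transform)
  if (anyNA(x)) stop("expression vector has missing values; preprocess first")
  t <- switch(transform,
              identity_clip = pmax(x, eps),
              shift = x + (eps - min(x)),
              exp2 = 2^x)
  if (any(t <= 0) || !all(is.finite(t)))
    stop("values not strictly positive/finite after '", transform, "' transform")
  t
}

.default_transform <- function(value_scale) {
  if (identical(value_scale, "log_ratio")) "exp2" else "identity_clip"
}

#' Build a probability profile from an expression vector
#'
#' Normalizes the (transformed) expression of one sample over its N probes
#' into a discrete probability distribution: \eqn{p_i = t(x_i) / \sum_k
#' t(x_k)}. This profile is the object all quantifiers operate on.
#'
#' @inheritParams transform_expression
#' @param source_sample optional sample ID recorded on the profile.
#' @return numeric probability vector of class `probability_profile`.
#' @export
build_profile <- function(x, transform = c("identity_clip", "shift", "exp2"),
                          eps = 1e-12, source_sample = NULL) {
  if (length(x) < 2L) stop("a profile needs at least 2 probes")
  t <- transform_expression(x, transform, eps)
  s <- sum(t)
  if (!is.finite(s) || s <= 0) stop("transformed values sum to zero")
  structure(t / s, class = "probability_profile",
            source_sample = source_sample, names = names(x))
}

#' The uniform (equiprobable) profile on N probes
#' @param N support size (>= 2).
#' @return probability vector with all components 1/N.
#' @export
uniform_profile <- function(N) {
  stopifnot(N >= 2)
  structure(rep(1 / N, N), class = "probability_profile")
}

#' Shannon entropy of a probability profile
#'
#' \eqn{S[P] = -\sum_i p_i \ln p_i} in nats, with the convention
#' \eqn{0 \ln 0 = 0}; bounded by \eqn{0 \le S \le \ln N}.
#'
#' @param p probability vector (components >= 0 summing to 1).
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  .check_profile(p)
  -sum(.xlogx(p))
}

#' Normalized Shannon entropy (Shannon evenness)
#'
#' \eqn{H[P] = S[P] / \ln N}, dimensionless in \eqn{[0, 1]}: 1 for the
#' uniform profile, 0 for a point mass. Because it is a ratio of
#' entropies, H does not depend on the logarithm base.
#'
#' @inheritParams shannon_entropy
#' @return H in \eqn{[0, 1]}.
#' @export
normalized_entropy <- function(p) shannon_entropy(p) / log(length(p))

#' Jensen-Shannon divergence between two profiles
#'
#' \eqn{JS(P_1, P_2) = S[(P_1 + P_2)/2] - S[P_1]/2 - S[P_2]/2}: symmetric,
#' bounded by \eqn{\ln 2} nats, zero iff the profiles are identical. Unlike
#' the entropy, it distinguishes profiles that are permutations of each
#' other, which is what makes it useful as a distance to a reference state.
#'
#' @param p1,p2 probability vectors on the same support.
#' @return divergence in nats, in \eqn{[0, \ln 2]}.
#' @export
jensen_shannon <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("profiles have different support sizes (", length(p1), " vs ", length(p2), ")")
  .check_profile(p1, "p1"); .check_profile(p2, "p2")
  shannon_entropy((p1 + p2) / 2) - shannon_entropy(p1) / 2 - shannon_entropy(p2) / 2
}

#' Average a set of profiles into a reference profile
#'
#' Two averaging conventions exist for building a group reference. The
#' profile-space mean (`mean_of_pdfs`) averages the per-sample probability
#' profiles componentwise. The expression-space route (`pdf_of_mean`)
#' averages the raw expression vectors first and normalizes the mean
#' vector. The two coincide exactly when all member samples have equal
#' transformed totals, and differ otherwise; the mode used is recorded on
#' the result.
#'
#' @param profiles numeric matrix with one profile per column (probes in
#'   rows), or a list of probability vectors. Required for `mean_of_pdfs`.
#' @param mode `"mean_of_pdfs"` or `"pdf_of_mean"`.
#' @param x for `pdf_of_mean`, the matrix of raw expression vectors
#'   (probes x member samples).
#' @param transform,eps passed to [build_profile()] for `pdf_of_mean`.
#' @param name reference name (e.g. `"M-Normal"`, `"M-Gleason3"`).
#' @return an object of class `reference_profile`: list with `p` (the
#'   profile), `name`, `mode` and `member_samples`.
#' @export
average_profile <- function(profiles = NULL, mode = c("mean_of_pdfs", "pdf_of_mean"),
                            x = NULL, transform = "identity_clip", eps = 1e-12,
                            name = "reference") {
  mode <- match.arg(mode)
  if (mode == "mean_of_pdfs") {
    if (is.list(profiles)) profiles <- do.call(cbind, profiles)
    if (is.null(profiles) || ncol(profiles) == 0L) stop("no profiles to average")
    apply(profiles, 2L, .check_profile)
    p <- rowMeans(profiles)
    members <- colnames(profiles)
  } else {
    if (is.null(x) || ncol(x) == 0L)
      stop("pdf_of_mean requires the raw expression matrix 'x'")
    p <- build_profile(rowMeans(x), transform = transform, eps = eps)
    members <- colnames(x)
  }
  if (is.null(members)) members <- paste0("member", seq_len(max(1L, length(members))))
  structure(list(p = as.numeric(p), name = name, mode = mode,
                 member_samples = members),
            class = "reference_profile")
}

#' Build a group reference profile from an expression matrix
#'
#' Convenience wrapper: selects the samples of one annotation group and
#' averages them with [average_profile()].
#'
#' @param m an [expr_matrix()] without missing values.
#' @param ann annotation data.frame ([read_sample_annotation()]).
#' @param group group label whose samples define the reference.
#' @param mode,transform,eps see [average_profile()].
#' @param name reference name; default `"M-<group>"`.
#' @return a `reference_profile`.
#' @export
reference_profile <- function(m, ann, group, mode = c("mean_of_pdfs", "pdf_of_mean"),
                              transform = NULL, eps = 1e-12, name = NULL) {
  mode <- match.arg(mode)
  if (is.null(transform)) transform <- .default_transform(m$value_scale)
  members <- intersect(sample_ids(m), ann$sample_id[ann$group == group & !ann$exclude])
  if (length(members) == 0L) stop("no samples in matrix for group '", group, "'")
  x <- m$values[, members, drop = FALSE]
  if (anyNA(x)) stop("matrix has missing values; preprocess first")
  if (is.null(name)) name <- paste0("M-", group)
  if (mode == "mean_of_pdfs") {
    prof <- vapply(members, function(s) build_profile(x[, s], transform, eps),
                   numeric(nrow(x)))
    average_profile(prof, mode = "mean_of_pdfs", name = name)
  } else {
    average_profile(mode = "pdf_of_mean", x = x, transform = transform,
                    eps = eps, name = name)
  }
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile '%s': N = %d, mode = %s, %d member sample(s)\n",
              x$name, length(x$p), x$mode, length(x$member_samples)))
  invisible(x)
}

.ref_p <- function(ref) if (inherits(ref, "reference_profile")) ref$p else ref

#' Complexity normalization factor Q0
#'
#' The statistical complexities scale the Jensen-Shannon divergence to a
#' reference by \eqn{Q_0 = 1 / \max_k JS(\delta_k, P_{ref})}, the
#' reciprocal of the largest divergence any profile can attain to that
#' reference — attained at a point-mass (delta) profile. This guarantees
#' \eqn{Q_0 \, JS(P, P_{ref}) \in [0, 1]} for every profile P. For the
#' uniform reference it reduces to the closed form
#' \eqn{1 / [\ln(2N) - \frac{N+1}{2N}\ln(N+1) - \frac12 \ln N]}.
#'
#' The maximization is evaluated in closed form per delta component in
#' O(N), not by constructing N delta profiles.
#'
#' @param ref a `reference_profile` or probability vector.
#' @return the scalar Q0 (dimensionless).
#' @export
q0 <- function(ref) {
  p <- .ref_p(ref)
  .check_profile(p, "ref")
  1 / max(.js_to_deltas(p))
}

# JS(delta_k, p) for every k at once:
# JS(delta_k, p) = ln(2)/2 + (p_k/2) ln(p_k/2) - ((p_k+1)/2) ln((p_k+1)/2)
.js_to_deltas <- function(p) {
  log(2) / 2 + .xlogx(p / 2) - .xlogx((p + 1) / 2)
}

#' MPR statistical complexity
#'
#' \eqn{C_{MPR}[P] = Q_0 \, JS(P, P_e) \, H[P]} with \eqn{P_e} the uniform
#' profile: the product of disorder (H) and disequilibrium (normalized JS
#' to uniformity). It vanishes both for the fully ordered profile (a
#' delta, H = 0) and the fully disordered one (uniform, JS = 0), peaking
#' in between — the y-axis of the complexity-entropy plane.
#'
#' @param p probability vector.
#' @return complexity in \eqn{[0, 1]}.
#' @export
mpr_complexity <- function(p) {
  m_complexity(p, uniform_profile(length(p)))
}

#' M statistical complexity relative to a reference
#'
#' Same functional form as [mpr_complexity()] with an arbitrary reference
#' profile replacing the uniform one: \eqn{C_M[P] = Q_0(ref) \, JS(P,
#' P_{ref}) \, H[P]}. With a group-average reference (e.g. the normal
#' tissue profile) it measures how far a sample has moved from that state,
#' weighted by its residual diversity. The MPR complexity is the special
#' case ref = uniform.
#'
#' @param p probability vector.
#' @param ref a `reference_profile` or probability vector on the same
#'   support.
#' @return complexity in \eqn{[0, 1]}.
#' @export
m_complexity <- function(p, ref) {
  r <- .ref_p(ref)
  if (length(p) != length(r))
    stop("profile and reference have different support sizes")
  q0(r) * jensen_shannon(p, r) * normalized_entropy(p)
}
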