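#' Parameters for fuzzy approximate entropy features
#'
#' Bundles the tunable constants of the MFAREn feature. The defaults are the
#' settings used throughout this package: embedding dimension `m = 2`, three
#' scale factors, tolerance coefficient `k = 0.2` and smoothing term
#' `epsilon = 1e-6`.
#'
#' @param m base embedding dimension (template length at scale 1).
#' @param scales integer vector of scale factors; scale `s` evaluates the
#'   entropy at embedding dimension `m * s`.
#' @param k tolerance coefficient; the membership tolerance is
#'   `r = k * sd(x)` of the analyzed window.
#' @param epsilon smoothing term added inside the logarithm of the
#'   multi-scale aggregate, guarding against log-of-zero.
#' @param delay template delay (samples between successive template
#'   coordinates).
#' @param r_floor lower bound on the tolerance `r`, used when a window is
#'   (numerically) constant so that `sd(x) = 0`; with all distances zero the
#'   memberships are 1 and the entropy of a constant window is exactly 0.
#' @param exclude_self if `TRUE`, self-matches (`j == i`) are excluded from
#'   the similarity sums; the default keeps them, matching the plain form of
#'   the defining sums.
#' @param literal if `TRUE`, the multi-scale aggregate uses the degenerate
#'   ratio `(EY + eps)/(EY + eps)` (identically zero aggregate) instead of
#'   the divergence between the two embedding constructions; kept only for
#'   auditability. See [mfapen()].
#' @return list of class `entropy_params`.
#' @seealso [fapen()], [mfapen()], [mfaren_value()], [mfaren_features()]
#' @export
entropy_params <- function(m = 2L, scales = 1:3, k = 0.2, epsilon = 1e-6,
                           delay = 1L, r_floor = 1e-12,
                           exclude_self = FALSE, literal = FALSE) {
  m <- as.integer(m)
  scales <- sort(unique(as.integer(scales)))
  stopifnot(m >= 1L, length(scales) >= 1L, all(scales >= 1L),
            k > 0, epsilon > 0, delay >= 1L, r_floor > 0)
  structure(list(m = m, scales = scales, k = k, epsilon = epsilon,
                 delay = as.integer(delay), r_floor = r_floor,
                 exclude_self = isTRUE(exclude_self),
                 literal = isTRUE(literal)),
            class = "entropy_params")
}

as_entropy_params <- function(p) {
  if (inherits(p, "entropy_params")) return(p)
  do.call(entropy_params, as.list(p))
}

#' Baseline-removed template vectors
#'
#' Builds the template (embedding) vectors used by fuzzy approximate
#' entropy: `X_i = (u(i), u(i + d), ..., u(i + (m-1) d)) - mean(...)`, i.e.
#' each raw window minus its own mean. Removing the per-template baseline
#' makes the comparison insensitive to local offsets.
#'
#' @param x numeric series.
#' @param dim template length.
#' @param delay delay between template coordinates.
#' @return matrix with one template per row (`N - (dim - 1) * delay` rows).
#' @export
embed_templates <- function(x, dim, delay = 1L) {
  x <- as.numeric(x)
  dim <- as.integer(dim); delay <- as.integer(delay)
  n <- length(x) - (dim - 1L) * delay
  if (dim < 1L) stop("dim must be >= 1")
  if (n < 1L) stop("series length ", length(x), " < template span for dim ", dim)
  idx <- outer(seq_len(n), (seq_len(dim) - 1L) * delay, "+")
  tm <- matrix(x[idx], nrow = n)
  tm - rowMeans(tm)
}

#' Chebyshev distance between template vectors
#'
#' @param v,w numeric vectors of equal length.
#' @return largest coordinate-wise absolute difference.
#' @export
cheb_dist <- function(v, w) {
  if (length(v) != length(w)) stop("vectors differ in length")
  max(abs(v - w))
}

#' Gaussian fuzzy membership
#'
#' Similarity of two templates at distance `d` under tolerance `r`:
#' `exp(-d^2 / (2 r^2))`.
#'
#' @param d nonnegative distance(s).
#' @param r tolerance, must be positive.
#' @return membership value(s) in (0, 1].
#' @export
fuzzy_membership <- function(d, r) {
  if (any(r <= 0)) stop("tolerance r must be > 0")
  exp(-d^2 / (2 * r^2))
}

#' Mean log similarity of templates (phi)
#'
#' `phi^m(r)` is the mean over template vectors of the log of the mean
#' Gaussian membership to all templates (self-matches included by default).
#' Since every mean membership lies in (0, 1], `phi <= 0` always.
#'
#' @inheritParams embed_templates
#' @param r tolerance.
#' @param exclude_self drop `j == i` terms from the similarity mean.
#' @return scalar `phi^dim(r)`.
#' @export
phi_m <- function(x, dim, r, delay = 1L, exclude_self = FALSE) {
  cpp_phi(as.numeric(x), as.integer(dim), r, as.integer(delay),
          isTRUE(exclude_self))
}

#' Fuzzy approximate entropy
#'
#' `fApEn(m, r, x) = phi^m(r) - phi^{m+1}(r)` with a shared tolerance
#' `r = k * sd(x)`. Because both the templates (baseline-removed) and the
#' tolerance scale with the signal, fApEn is invariant to affine maps
#' `x -> a x + b` with `a > 0`. A constant series has fApEn exactly 0.
#'
#' @param x numeric series, length at least `m + 2`.
#' @param m embedding dimension.
#' @param params an [entropy_params()] object supplying `k`, `delay`,
#'   `r_floor` and `exclude_self`; `m` defaults to `params$m` when missing.
#' @return scalar entropy value.
#' @export
fapen <- function(x, m = params$m, params = entropy_params()) {
  params <- as_entropy_params(params)
  cpp_fapen(as.numeric(x), as.integer(m), params$k, params$delay,
            params$r_floor, params$exclude_self)
}

#' Per-scale entropies of the two embedding constructions
#'
#' For each scale `s` the entropy is evaluated at an enlarged embedding
#' dimension: `EX[s]` uses template length `m * s` and `EY[s]` the
#' lengthened construction `m * s + 1`. All scales share the tolerance
#' `r = k * sd(x)` computed once from the analyzed window.
#'
#' @inheritParams fapen
#' @return list with numeric vectors `EX`, `EY` (one entry per scale) and
#'   the shared tolerance `r`.
#' @export
scale_entropies <- function(x, params = entropy_params()) {
  params <- as_entropy_params(params)
  cpp_scale_entropies(as.numeric(x), params$m, params$scales, params$k,
                      params$delay, params$r_floor, params$exclude_self)
}

#' Multi-scale fuzzy approximate entropy aggregate
#'
#' Aggregates the per-scale entropies with a Kullback-Leibler-style
#' divergence between the two embedding constructions:
#' \deqn{MfApEn = -\frac{1}{|S|} \sum_{s \in S} E_Y[s]
#'   \log\frac{E_Y[s] + \epsilon}{E_X[s] + \epsilon}.}
#' The aggregate is exactly 0 when `EX == EY` at every scale, and 0 for a
#' constant series (all entropies vanish). With `params$literal = TRUE` the
#' denominator is `EY[s] + eps` as well, which makes every term — and hence
#' the aggregate — identically zero; that degenerate variant is retained
#' only so the two readings can be compared.
#'
#' @inheritParams scale_entropies
#' @return scalar aggregate.
#' @export
mfapen <- function(x, params = entropy_params()) {
  params <- as_entropy_params(params)
  cpp_mfapen(as.numeric(x), params$m, params$scales, params$k,
             params$epsilon, params$delay, params$r_floor,
             params$exclude_self, params$literal)
}

#' Root mean square amplitude
#'
#' @param x numeric series (nonempty).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("empty series")
  sqrt(mean(as.numeric(x)^2))
}

#' MFAREn: multi-scale fuzzy approximate root mean entropy
#'
#' The fused per-window feature: `MFAREn(x) = MfApEn(x) + RMS(x)`. The
#' entropy term captures the irregularity (complexity) of the window and is
#' amplitude-invariant; the RMS term carries the contraction intensity, so
#' the fusion separates resting from active muscle states.
#'
#' @inheritParams scale_entropies
#' @return scalar feature value.
#' @export
mfaren_value <- function(x, params = entropy_params()) {
  mfapen(x, params) + rms(x)
}

#' Windowed MFAREn feature extraction
#'
#' Slides an inner window of `inner_window` samples (stride `stride`) across
#' each channel of a segment and emits one MFAREn value per position, giving
#' `F = floor((L - w)/stride) + 1` values per channel. For the default
#' 100-sample (100 ms at 1000 Hz) segment with `w = 10`, `stride = 1` this
#' is `F = 91`, i.e. the `1 x 12 x 91` classifier input.
#'
#' @param x either a numeric matrix (channels x L) for one segment, or a
#'   `windowed_samples` batch from [segment_windows()].
#' @param params an [entropy_params()] object.
#' @param inner_window inner window length in samples.
#' @param stride inner window stride in samples.
#' @return for a single matrix: a `feature_matrix` (channels x F matrix with
#'   attribute `label` when present). For a batch: a `feature_set`, a list
#'   with `features` (array `n x channels x F`), `labels`, `mode`,
#'   `subject_id`.
#' @export
mfaren_features <- function(x, params = entropy_params(),
                            inner_window = 10L, stride = 1L) {
  params <- as_entropy_params(params)
  inner_window <- as.integer(inner_window)
  stride <- as.integer(stride)
  one <- function(seg) {
    cpp_mfaren_features(seg, inner_window, stride, params$m, params$scales,
                        params$k, params$epsilon, params$delay,
                        params$r_floor, params$exclude_self, params$literal)
  }
  if (is.matrix(x)) {
    out <- one(x)
    rownames(out) <- rownames(x)
    class(out) <- c("feature_matrix", class(out))
    return(out)
  }
  if (inherits(x, "windowed_samples")) {
    n <- dim(x$segments)[3L]
    L <- dim(x$segments)[2L]
    nch <- dim(x$segments)[1L]
    Fn <- (L - inner_window) %/% stride + 1L
    feats <- array(NA_real_, c(n, nch, Fn))
    for (i in seq_len(n)) feats[i, , ] <- one(x$segments[, , i])
    out <- list(features = feats, labels = x$labels, mode = x$mode,
                subject_id = x$subject_id)
    class(out) <- "feature_set"
    return(out)
  }
  stop("x must be a channels-by-samples matrix or a windowed_samples batch")
}

#' @export
print.feature_set <- function(x, ...) {
  d <- dim(x$features)
  cat("<feature_set> ", d[1L], " samples x ", d[2L], " channels x ", d[3L],
      " features\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Combine feature sets
#'
#' @param ... `feature_set` objects with matching channel/feature dims.
#' @return a single `feature_set` with rows stacked.
#' @export
bind_feature_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "feature_set"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  dims <- vapply(sets, function(s) dim(s$features)[2:3], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("feature sets have mismatching dimensions")
  n <- sum(vapply(sets, function(s) dim(s$features)[1L], numeric(1)))
  feats <- array(NA_real_, unname(c(n, dims[1, 1], dims[2, 1])))
  labs <- character(0); mode <- character(0); subj <- character(0)
  at <- 0L
  for (s in sets) {
    ni <- dim(s$features)[1L]
    if (ni > 0L) feats[at + seq_len(ni), , ] <- s$features
    labs <- c(labs, as.character(s$labels))
    mode <- c(mode, rep(if (is.null(s$mode)) NA_character_ else s$mode, ni))
    subj <- c(subj, rep(if (is.null(s$subject_id)) NA_character_
                        else s$subject_id, ni))
    at <- at + ni
  }
  out <- list(features = feats, labels = phase_factor(labs),
              mode = mode, subject_id = subj)
  class(out) <- "feature_set"
  out
}
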