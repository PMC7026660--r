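#' Align two fits on their common valid bins
#'
#' Cells differ in which bins survive filtering (e.g. centromeric
#' gaps), so their eigenvectors live on different locus sets. This
#' intersects the original-bin validity masks, restricts each fit's
#' eigenvectors to the shared bins, and renormalizes every mode shape
#' to unit length on the intersection. Required before any mode-level
#' comparison when masks differ.
#'
#' @param a,b [gnm()] fits over the same original bin table.
#' @return list of the two adjusted fits.
#' @export
align_fits <- function(a, b) {
  stopifnot(inherits(a, "gnm"), inherits(b, "gnm"))
  if (length(a$valid_mask) != length(b$valid_mask))
    stop("fits come from different original bin tables")
  common <- a$valid_mask & b$valid_mask
  restrict <- function(f) {
    keep <- common[f$valid_mask]
    U <- f$vectors[keep, , drop = FALSE]
    nrm <- sqrt(colSums(U^2))
    if (any(nrm == 0))
      stop("a mode shape vanishes on the common bins; cannot align")
    f$vectors <- sweep(U, 2L, nrm, "/")
    f$msf <- f$msf[keep]
    f$valid_mask <- common
    f$n <- sum(keep)
    f
  }
  list(restrict(a), restrict(b))
}

.check_aligned <- function(a, b) {
  if (nrow(a$vectors) != nrow(b$vectors) ||
      !identical(a$valid_mask, b$valid_mask))
    stop("fits are not aligned on the same bins; use align_fits()")
}

#' Mode-mode overlap map between two cells
#'
#' The overlap between mode `k` of cell A and mode `l` of cell B is
#' the absolute correlation cosine `|v_k^A . v_l^B|`, in [0, 1] (the
#' direction of fluctuation along a mode is immaterial).
#'
#' @param a,b [gnm()] fits, aligned on the same bins.
#' @param m_a,m_b number of modes of each cell to include (default
#'   all retained).
#' @return `m_a x m_b` matrix of overlaps, class `overlap_matrix`.
#' @export
mode_overlap <- function(a, b, m_a = NULL, m_b = NULL) {
  .check_aligned(a, b)
  if (is.null(m_a)) m_a <- ncol(a$vectors)
  if (is.null(m_b)) m_b <- ncol(b$vectors)
  S <- abs(crossprod(a$vectors[, seq_len(m_a), drop = FALSE],
                     b$vectors[, seq_len(m_b), drop = FALSE]))
  S[S > 1] <- 1  # guard FP excess from renormalized vectors
  structure(S, cells = c(a$label, b$label), class = "overlap_matrix")
}

#' Match equivalent modes between two cells
#'
#' Pairwise comparison of mode spectra requires identifying the
#' *equivalent* (best matching) modes, cast as a linear assignment
#' problem: the cost of pairing reference mode `k` with candidate mode
#' `l` is `1 - S_kl`, and the globally cost-minimal injective
#' assignment of the reference's first `m` modes into the candidate's
#' first `window_factor * m` modes is found by the Hungarian method.
#'
#' @param ref,cand [gnm()] fits, aligned; `ref` supplies the mode
#'   numbering.
#' @param m number of reference modes to match.
#' @param window_factor candidates are drawn from the first
#'   `window_factor * m` modes of `cand` (capped at its retained
#'   count); the default 4 matches the top modes against up to 4x as
#'   many original modes.
#' @return a `mode_matching`: list with `assignment` (candidate index
#'   for each reference mode), `overlaps`, `total_cost`, `m`,
#'   `window`, cell labels.
#' @export
match_modes <- function(ref, cand, m = NULL, window_factor = 4) {
  .check_aligned(ref, cand)
  if (is.null(m)) m <- min(ncol(ref$vectors), ncol(cand$vectors))
  if (m > ncol(ref$vectors))
    stop("m exceeds the reference's retained modes")
  M <- min(as.integer(ceiling(window_factor * m)), ncol(cand$vectors))
  if (M < m)
    stop("candidate window (", M, " modes) is smaller than m = ", m)
  S <- mode_overlap(ref, cand, m_a = m, m_b = M)
  a <- solve_assignment(1 - unclass(S))
  structure(list(assignment = as.integer(a),
                 overlaps = S[cbind(seq_len(m), a)],
                 total_cost = attr(a, "cost"),
                 m = m, window = M,
                 reference = ref$label, candidate = cand$label),
            class = "mode_matching")
}

#' @export
print.mode_matching <- function(x, ...) {
  cat("Mode matching: ", x$reference, " (reference, ", x$m,
      " modes) vs ", x$candidate, " (window ", x$window, ")\n", sep = "")
  cat("  mean matched overlap:", format(mean(x$overlaps)),
      " displaced modes:", sum(x$assignment != seq_len(x$m)), "\n")
  invisible(x)
}

#' Fraction of modes replaced by out-of-range equivalents
#'
#' Summarizes how much a cell's mode population changes when
#' equivalent modes are included: by default, the fraction of the
#' reference's first `m` modes whose matched candidate mode was *not*
#' among the candidate's own first `m` (its index exceeds `m`).
#' `kind = "displaced"` instead reports the fraction of matches whose
#' candidate index differs from the reference index at all.
#'
#' @param matching a [match_modes()] result.
#' @param m mode-population size (defaults to the matching's `m`).
#' @param kind `"beyond_m"` (default) or `"displaced"`.
#' @return scalar in [0, 1].
#' @export
replacement_fraction <- function(matching, m = matching$m,
                                 kind = c("beyond_m", "displaced")) {
  kind <- match.arg(kind)
  a <- matching$assignment[seq_len(m)]
  if (kind == "beyond_m") mean(a > m) else mean(a != seq_len(m))
}

#' Mode conservation profile across a cohort of cells
#'
#' The conservation of mode `k` is the mean of the diagonal overlap
#' `[S(A,B)]_kk` over all N(N-1)/2 unordered cell pairs. With
#' `matchings` supplied (one [match_modes()] per cell against a common
#' reference), each cell's modes are first reindexed to the
#' reference's numbering, so the profile reflects *equivalent* modes.
#'
#' @param fits list of aligned [gnm()] fits (>= 2).
#' @param m number of modes to profile.
#' @param matchings optional list parallel to `fits` (entries may be
#'   `NULL` for the reference itself) of matchings to one reference.
#' @return numeric vector `<S>_k`, length `m`, values in [0, 1].
#' @export
conservation_profile <- function(fits, m = NULL, matchings = NULL) {
  N <- length(fits)
  if (N < 2) stop("need at least 2 cells")
  if (is.null(m)) m <- min(vapply(fits, function(f) ncol(f$vectors), 1L))
  V <- lapply(seq_len(N), function(i) {
    f <- fits[[i]]
    idx <- seq_len(m)
    if (!is.null(matchings) && !is.null(matchings[[i]]))
      idx <- matchings[[i]]$assignment[seq_len(m)]
    f$vectors[, idx, drop = FALSE]
  })
  acc <- numeric(m)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    .check_aligned(fits[[i]], fits[[j]])
    acc <- acc + abs(colSums(V[[i]] * V[[j]]))
  }
  pmin(acc / (N * (N - 1L) / 2L), 1)
}

#' Normalized statistical weights of the modes
#'
#' The variance of mode `k` is `1/lambda_k`; because different cells'
#' maps have different total read counts, variances are normalized to
#' weights `w_k = (1/lambda_k) / sum_l (1/lambda_l)`, which sum to 1
#' and act as a prior probability over modes.
#'
#' @param fit a [gnm()] fit (or anything with `$values`).
#' @param m number of modes (default all retained).
#' @return numeric weights summing to 1.
#' @export
mode_weights <- function(fit, m = NULL) {
  lam <- fit$values
  if (!is.null(m)) lam <- lam[seq_len(m)]
  w <- 1 / lam
  w / sum(w)
}

#' Covariance overlap between two cells
#'
#' A [0, 1] similarity between two covariance matrices built from the
#' mode variances and the squared eigenvector dot products:
#' `L = 1 - sqrt( (sum_i (w_i^A + w_i^B)
#'   - 2 sum_ij sqrt(w_i^A w_j^B) (v_i^A . v_j^B)^2)
#'   / sum_i (w_i^A + w_i^B) )`.
#' `L = 1` for identical covariances and 0 for fully orthogonal mode
#' subspaces. Weights must be normalized ([mode_weights()]).
#'
#' @param a,b aligned [gnm()] fits.
#' @param m number of modes to use from each (default all shared).
#' @param w_a,w_b optional weight overrides (must each sum to 1
#'   within 1e-6).
#' @return scalar `L` in [0, 1].
#' @export
covariance_overlap <- function(a, b, m = NULL, w_a = NULL, w_b = NULL) {
  .check_aligned(a, b)
  if (is.null(m)) m <- min(ncol(a$vectors), ncol(b$vectors))
  if (is.null(w_a)) w_a <- mode_weights(a, m)
  if (is.null(w_b)) w_b <- mode_weights(b, m)
  if (abs(sum(w_a) - 1) > 1e-6 || abs(sum(w_b) - 1) > 1e-6)
    stop("mode weights must be normalized to sum 1")
  VA <- a$vectors[, seq_len(m), drop = FALSE]
  VB <- b$vectors[, seq_len(m), drop = FALSE]
  G2 <- crossprod(VA, VB)^2
  tot <- sum(w_a) + sum(w_b)
  num <- tot - 2 * sum(sqrt(outer(w_a, w_b)) * G2)
  frac <- num / tot
  ## the outer square root amplifies FP residue (sqrt(1e-16) = 1e-8),
  ## so identical inputs must see an exactly zero bracket
  if (abs(frac) < 1e-12) frac <- 0
  if (frac < 0) {
    if (frac < -1e-9) stop("covariance-overlap bracket below 0 beyond tolerance")
    frac <- 0
  }
  if (frac > 1) {
    if (frac > 1 + 1e-9) stop("covariance-overlap bracket above 1 beyond tolerance")
    frac <- 1
  }
  1 - sqrt(frac)
}

#' Arc distance between covariance matrices
#'
#' Converts a covariance overlap `L` in [0, 1] to the arc distance
#' `d_cov = arccos(L)`, in [0, pi/2]; the cell-cell distance used to
#' build dendrograms.
#'
#' @param L covariance overlap(s).
#' @return arc distance(s).
#' @export
covariance_distance <- function(L) {
  if (any(L < -1e-9 | L > 1 + 1e-9))
    stop("covariance overlap outside [0, 1]")
  acos(pmin(pmax(L, 0), 1))
}

#' Pearson correlation between two mobility profiles
#'
#' Computed on the intersection of the two profiles' valid bins, so
#' cells with different filtered regions remain comparable.
#'
#' @param p,q `mobility_profile`s (from [fluctuations()]) or bare
#'   numeric vectors of equal length.
#' @return Pearson r.
#' @export
profile_correlation <- function(p, q) {
  mp <- attr(p, "mask"); mq <- attr(q, "mask")
  if (!is.null(mp) && !is.null(mq)) {
    if (length(mp) != length(mq))
      stop("profiles come from different original bin tables")
    common <- mp & mq
    x <- as.numeric(p)[common[mp]]
    y <- as.numeric(q)[common[mq]]
  } else {
    if (length(p) != length(q)) stop("profiles differ in length")
    x <- as.numeric(p); y <- as.numeric(q)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant mobility profile; correlation undefined")
  stats::cor(x, y)
}

#' Mobility profile restricted to equivalent modes
#'
#' Recomputes a cell's MSF profile using only the modes matched to a
#' reference's first `m` modes, in the reference's ordering. By
#' default each matched mode keeps the candidate's own eigenvalue
#' weight; `reference_weights = TRUE` substitutes the reference fit's
#' weights instead.
#'
#' @param fit the candidate [gnm()] fit.
#' @param matching a [match_modes()] result with `fit` as candidate.
#' @param reference_weights use the reference's eigenvalues.
#' @param ref the reference fit (required if `reference_weights`).
#' @return a `mobility_profile`.
#' @export
matched_mobility <- function(fit, matching, reference_weights = FALSE,
                             ref = NULL) {
  idx <- matching$assignment
  U <- fit$vectors[, idx, drop = FALSE]
  lam <- if (reference_weights) {
    if (is.null(ref)) stop("reference_weights = TRUE needs ref")
    ref$values[seq_along(idx)]
  } else fit$values[idx]
  msf <- as.numeric((U^2) %*% (1 / lam))
  structure(msf, mask = fit$valid_mask, cell = fit$label,
            normalized = FALSE, class = "mobility_profile")
}
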