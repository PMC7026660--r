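#' Kirchhoff (connectivity) matrix of a contact map
#'
#' Builds the graph-Laplacian spring matrix of the elastic network:
#' `Gamma_ij = -M_ij` for `i != j` and `Gamma_ii = sum_{j != i} M_ij`.
#' Self-contacts on the diagonal of `M` carry no spring meaning and are
#' ignored.
#'
#' @param map a filtered, connected [contact_map()].
#' @return an object of class `kirchhoff` with elements `matrix` and
#'   `source` (the input map).
#' @export
build_kirchhoff <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  M <- map$matrix
  diag(M) <- 0
  G <- -M
  diag(G) <- rowSums(M)
  structure(list(matrix = G, source = map), class = "kirchhoff")
}

#' @export
print.kirchhoff <- function(x, ...) {
  cat("Kirchhoff matrix:", nrow(x$matrix), "loci, trace",
      format(sum(diag(x$matrix))), "\n")
  invisible(x)
}

## deterministic eigenvector sign: largest-|component| entry positive
.fix_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

## within near-degenerate eigenvalue clusters (relative gap < 1e-9),
## order modes by the index of their largest component, for determinism
.order_degenerate <- function(values, U) {
  m <- length(values)
  if (m < 2L) return(seq_len(m))
  ord <- seq_len(m)
  start <- 1L
  peak <- apply(abs(U), 2L, which.max)
  for (k in 2L:(m + 1L)) {
    closes <- k > m ||
      (values[k] - values[k - 1L]) > 1e-9 * max(values[k], 1e-300)
    if (closes) {
      if (k - start > 1L) {
        idx <- start:(k - 1L)
        ord[idx] <- idx[order(peak[idx])]
      }
      start <- k
    }
  }
  ord
}

#' Normal mode decomposition of a Kirchhoff matrix
#'
#' Solves for the `m` lowest-frequency nonzero normal modes of the
#' elastic network: eigenvalues in ascending order (each scaling with a
#' mode frequency; `1/lambda_k` is the statistical weight of mode `k`)
#' and orthonormal eigenvectors (mode shapes). The zero mode(s) of the
#' Laplacian are detected (`lambda < 1e-10 * lambda_max`) and removed;
#' a connected contact graph has exactly one. Large networks are solved
#' by sparse shift-invert partial eigendecomposition, small ones
#' densely.
#'
#' @param g a [build_kirchhoff()] result, or a bare symmetric matrix.
#' @param m number of modes to retain (clamped to `n - n_zero` with a
#'   warning when larger).
#' @param allow_disconnected if `FALSE` (default), more than one zero
#'   mode is an error (the caller should [filter_bins()] first).
#' @param dense_below use dense `eigen()` for `n` below this size.
#' @return list with class `mode_set`: `values` (ascending, positive),
#'   `vectors` (n x m, orthonormal columns, deterministic signs),
#'   `n_zero`, `n`.
#' @export
decompose <- function(g, m = 500L, allow_disconnected = FALSE,
                      dense_below = 2000L) {
  G <- if (inherits(g, "kirchhoff")) g$matrix else as.matrix(g)
  n <- nrow(G)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  use_dense <- n < dense_below || (m + 8L) > n / 4
  if (use_dense) {
    e <- eigen(G, symmetric = TRUE)
    values <- rev(e$values)
    vectors <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  } else {
    k <- min(n - 1L, m + 8L)
    e <- RSpectra::eigs_sym(G, k = k, sigma = -1e-8)
    ord <- order(e$values)
    values <- e$values[ord]
    vectors <- e$vectors[, ord, drop = FALSE]
  }
  lam_max <- if (use_dense) max(values) else max(abs(diag(G))) * 2
  n_zero <- sum(values < 1e-10 * lam_max)
  if (n_zero > 1L && !allow_disconnected)
    stop("contact graph is disconnected (", n_zero,
         " zero modes); run filter_bins() first")
  if (n_zero < 1L) n_zero <- 1L  # Laplacian always has >= 1 zero mode
  avail <- length(values) - n_zero
  if (m > n - n_zero) {
    warning("m = ", m, " clamped to ", n - n_zero, " available modes")
    m <- n - n_zero
  }
  m <- min(m, avail)
  idx <- n_zero + seq_len(m)
  values <- values[idx]
  vectors <- vectors[, idx, drop = FALSE]
  ord <- .order_degenerate(values, vectors)
  values <- values[ord]
  vectors <- .fix_signs(vectors[, ord, drop = FALSE])
  structure(list(values = values, vectors = vectors,
                 n_zero = n_zero, n = n),
            class = "mode_set")
}

#' Fit a Gaussian network model to a Hi-C contact map
#'
#' The central estimator of the package. The contact map is filtered
#' (empty bins dropped, largest connected component kept), converted to
#' a Kirchhoff matrix, and decomposed into its `n_modes`
#' lowest-frequency normal modes. The resulting `gnm` object carries
#' the mode spectrum and the per-locus mean-square fluctuations (MSF),
#' and supports the usual model methods: [coef()] (eigenvalues),
#' [vcov()] (locus covariance), [fluctuations()], [cross_correlation()],
#' [collectivity()], [plot()], [simulate()].
#'
#' @param map a [contact_map()].
#' @param n_modes modes to retain (default 500, a subset large enough
#'   to represent the collective dynamics at 50 kb resolution).
#' @param scope `"genome"` fits one network over all retained bins,
#'   including inter-chromosomal contacts; use [chromosome_gnms()] for
#'   per-chromosome fits.
#' @param label cell-type label attached to the fit.
#' @param filter set `FALSE` if `map` is already filtered and connected.
#' @return an object of class `gnm`.
#' @examples
#' M <- matrix(0, 3, 3); M[1, 2] <- M[2, 1] <- 1; M[2, 3] <- M[3, 2] <- 1
#' fit <- gnm(contact_map(M), n_modes = 2)
#' coef(fit)          # Laplacian spectrum of the 3-bin path: 1, 3
#' fluctuations(fit)  # MSF = diag of the pseudoinverse: 5/9, 2/9, 5/9
#' @export
gnm <- function(map, n_modes = 500L, scope = "genome", label = NULL,
                filter = TRUE) {
  stopifnot(inherits(map, "contact_map"))
  if (filter) map <- filter_bins(map, scope = "genome")
  kir <- build_kirchhoff(map)
  modes <- decompose(kir, m = n_modes)
  msf <- as.numeric((modes$vectors^2) %*% (1 / modes$values))
  structure(list(values = modes$values, vectors = modes$vectors,
                 n_zero = modes$n_zero, n = modes$n,
                 msf = msf, bins = map$bins, bin_size = map$bin_size,
                 valid_mask = map$valid_mask, scope = scope,
                 label = if (is.null(label)) map$provenance else label,
                 call = match.call()),
            class = "gnm")
}

#' Per-chromosome GNM fits
#'
#' Splits a genome-wide map into its chromosomes (discarding trans
#' contacts) and fits a [gnm()] to each, as used for per-chromosome
#' directional cross-correlations and covariance-overlap distances.
#'
#' @inheritParams gnm
#' @return named list of `gnm` fits, one per chromosome.
#' @export
chromosome_gnms <- function(map, n_modes = 500L, label = NULL) {
  stopifnot(inherits(map, "contact_map"))
  chroms <- unique(map$bins$chrom)
  fits <- lapply(chroms, function(ch) {
    on_ch <- map$bins$chrom == ch
    sub <- contact_map(map$matrix[on_ch, on_ch, drop = FALSE],
                       bins = map$bins[on_ch, , drop = FALSE],
                       bin_size = map$bin_size,
                       provenance = paste0(map$provenance, " | ", ch))
    gnm(sub, n_modes = n_modes, scope = "chromosome", label = label)
  })
  names(fits) <- chroms
  fits
}

#' @export
print.gnm <- function(x, ...) {
  cat("Gaussian network model fit", if (!is.null(x$label))
    paste0("(", x$label, ")"), "\n")
  cat("  loci:", x$n, "  modes retained:", length(x$values),
      "  zero modes removed:", x$n_zero, "\n")
  cat("  eigenvalue range: [", format(min(x$values)), ",",
      format(max(x$values)), "]\n")
  invisible(x)
}

#' @export
summary.gnm <- function(object, ...) {
  kap <- collectivity(object)
  out <- list(n = object$n, m = length(object$values),
              n_zero = object$n_zero, label = object$label,
              eigenvalues = object$values,
              msf = object$msf, collectivity = kap)
  class(out) <- "summary.gnm"
  out
}

#' @export
print.summary.gnm <- function(x, ...) {
  cat("GNM fit", if (!is.null(x$label)) paste0("(", x$label, ")"),
      ": ", x$n, " loci, ", x$m, " modes\n", sep = "")
  cat("Eigenvalues (frequency scale):\n")
  print(summary(x$eigenvalues))
  cat("Mean-square fluctuations:\n")
  print(summary(x$msf))
  cat("Collectivity of the 5 slowest modes:",
      paste(format(utils::head(x$collectivity, 5), digits = 3),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.gnm <- function(object, ...) object$values

#' Covariance matrix of locus fluctuations
#'
#' `vcov` on a GNM fit returns the covariance matrix
#' `C = sum_k (1/lambda_k) u_k u_k^T` over the retained modes; with the
#' full spectrum this equals the Moore-Penrose pseudoinverse of the
#' Kirchhoff matrix. Its diagonal is the MSF profile.
#'
#' @param object a [gnm()] fit.
#' @param ... unused.
#' @export
vcov.gnm <- function(object, ...) {
  U <- object$vectors
  U %*% (t(U) / object$values)
}

#' Mean-square fluctuation (mobility) profile of a fit
#'
#' @param object a [gnm()] fit.
#' @param normalized scale the profile to mean 1, which leaves Pearson
#'   correlations between profiles unchanged.
#' @return a `mobility_profile`: numeric per-locus MSF with the
#'   original-bin validity mask attached.
#' @export
fluctuations <- function(object, normalized = FALSE) {
  stopifnot(inherits(object, "gnm"))
  p <- structure(object$msf, mask = object$valid_mask,
                 cell = object$label, normalized = FALSE,
                 class = "mobility_profile")
  if (normalized) normalize_profile(p) else p
}

#' @export
print.mobility_profile <- function(x, ...) {
  cat("Mobility profile", if (!is.null(attr(x, "cell")))
    paste0("(", attr(x, "cell"), ")"),
    ": ", length(x), " loci, mean ", format(mean(x)),
    if (isTRUE(attr(x, "normalized"))) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Scale a mobility profile to mean 1
#'
#' @param p a `mobility_profile` (or bare numeric vector).
#' @return the profile scaled to mean 1, `normalized` flag set.
#' @export
normalize_profile <- function(p) {
  mu <- mean(p)
  if (!is.finite(mu) || mu == 0)
    stop("cannot normalize an all-zero mobility profile")
  out <- p / mu
  mostattributes(out) <- attributes(p)
  attr(out, "normalized") <- TRUE
  class(out) <- "mobility_profile"
  out
}

#' Directional cross-correlations between loci
#'
#' Correlation cosines `D_ij = C_ij / sqrt(C_ii * C_jj)`, in [-1, 1]:
#' +1 fully correlated, -1 fully anticorrelated (concerted motion in
#' opposite senses), 0 uncorrelated. Conventionally evaluated per
#' chromosome.
#'
#' @param object a [gnm()] fit or a covariance matrix.
#' @return n x n matrix `D` with unit diagonal.
#' @export
cross_correlation <- function(object) {
  C <- if (inherits(object, "gnm")) vcov(object) else as.matrix(object)
  v <- diag(C)
  if (any(v <= 0))
    stop("zero-variance locus at index ", which(v <= 0)[1L],
         "; cannot form correlation cosines")
  D <- C / sqrt(outer(v, v))
  over <- abs(D) > 1
  if (any(abs(D[over]) > 1 + 1e-9))
    stop("correlation cosine outside [-1, 1] beyond tolerance")
  D[over] <- sign(D[over])
  diag(D) <- 1
  D
}

#' Degree of collectivity of each mode
#'
#' Exponential-entropy measure of how delocalized a mode shape is:
#' `kappa_k = (1/n) exp(-sum_i u_ki^2 log u_ki^2)`, in (0, 1]. A mode
#' moving all loci equally has collectivity 1; a single-locus spike has
#' `1/n`.
#'
#' @param object a [gnm()] fit or a `mode_set`.
#' @return numeric vector, one value per retained mode.
#' @export
collectivity <- function(object) {
  U <- object$vectors
  n <- nrow(U)
  P <- U^2
  H <- apply(P, 2L, function(p) -sum(ifelse(p > 0, p * log(p), 0)))
  exp(H) / n
}

#' @export
plot.gnm <- function(x, type = c("msf", "cross_correlation"), ...) {
  type <- match.arg(type)
  if (type == "msf") {
    graphics::plot(seq_len(x$n), x$msf, type = "l",
                   xlab = "locus index", ylab = "MSF",
                   main = paste("Mobility profile", x$label), ...)
  } else {
    D <- cross_correlation(x)
    graphics::image(seq_len(x$n), seq_len(x$n), D, zlim = c(-1, 1),
                    xlab = "locus", ylab = "locus",
                    main = "Directional cross-correlations", ...)
  }
  invisible(x)
}

#' Simulate locus displacement snapshots from a fit
#'
#' Draws isotropic Gaussian locus displacements with covariance equal
#' to the fit's mode-restricted covariance matrix.
#'
#' @param object a [gnm()] fit.
#' @param nsim number of snapshots.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return nsim x n matrix of displacements.
#' @export
simulate.gnm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  U <- object$vectors
  m <- ncol(U)
  Z <- matrix(stats::rnorm(nsim * m), nsim, m)
  Z %*% (t(U) * (1 / sqrt(object$values)))
}

#' @export
residuals.gnm <- function(object, ...) {
  ## deviation of each locus MSF from the fit-wide mean mobility
  object$msf - mean(object$msf)
}
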