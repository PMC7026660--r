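#' Specification for a synthetic Hi-C contact map
#'
#' Describes a block/TAD-structured, distance-decaying, symmetric
#' contact map: expected cis contact between bins at genomic lag `s`
#' falls off as `s^-decay_exponent`, pairs inside the same TAD are
#' boosted by `intra_tad_boost`, chromosomes exchange a weak uniform
#' trans contact, and multiplicative noise with coefficient of
#' variation `noise_level` is applied.
#'
#' @param n_loci total number of bins.
#' @param bin_size bin width in bp (default 50 kb).
#' @param n_chromosomes number of equal-sized chromosomes.
#' @param tad_boundaries strictly increasing bin indices (0-based,
#'   within `[0, n_loci]`) cutting the genome into TAD blocks.
#' @param decay_exponent power-law exponent `alpha` of the contact
#'   decay, `contact ~ lag^-alpha`.
#' @param intra_tad_boost multiplicative contact enrichment (>= 1)
#'   for pairs sharing a TAD.
#' @param noise_level coefficient of variation of the multiplicative
#'   count noise (>= 0; 0 gives the exact expected map).
#' @param trans_level trans contact as a fraction of the cis baseline.
#' @param scale overall count scale of the nearest-neighbour contact.
#' @param seed integer RNG seed.
#' @return a validated `synth_spec` list.
#' @export
synth_spec <- function(n_loci, bin_size = 50000L, n_chromosomes = 1L,
                       tad_boundaries = integer(), decay_exponent = 1,
                       intra_tad_boost = 3, noise_level = 0.1,
                       trans_level = 0.01, scale = 100, seed = 1L) {
  if (n_loci < 3L * n_chromosomes)
    stop("need at least 3 loci per chromosome")
  tb <- as.integer(tad_boundaries)
  if (length(tb) && (any(diff(tb) <= 0) || any(tb < 0) || any(tb > n_loci)))
    stop("tad_boundaries must be strictly increasing within [0, n_loci]")
  for (x in c(decay_exponent, intra_tad_boost, scale))
    if (!is.finite(x) || x <= 0) stop("factors must be finite and positive")
  if (intra_tad_boost < 1) stop("intra_tad_boost must be >= 1")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(list(n_loci = as.integer(n_loci), bin_size = bin_size,
                 n_chromosomes = as.integer(n_chromosomes),
                 tad_boundaries = tb, decay_exponent = decay_exponent,
                 intra_tad_boost = intra_tad_boost,
                 noise_level = noise_level, trans_level = trans_level,
                 scale = scale, seed = as.integer(seed)),
            class = "synth_spec")
}

## equal-sized chromosome assignment for n loci
.chrom_of <- function(n, n_chrom) {
  sizes <- rep(n %/% n_chrom, n_chrom)
  if (n %% n_chrom) sizes[seq_len(n %% n_chrom)] <-
      sizes[seq_len(n %% n_chrom)] + 1L
  rep(seq_len(n_chrom), sizes)
}

#' Generate a synthetic contact map
#'
#' Builds the expected map of a [synth_spec()] (power-law cis decay,
#' TAD-block boost, uniform weak trans contact) and applies
#' multiplicative gamma noise with the requested coefficient of
#' variation. Deterministic under the spec's seed; with
#' `noise_level = 0` the output is the exact expectation.
#'
#' @param spec a [synth_spec()].
#' @return a [contact_map()], connected within each chromosome.
#' @export
generate_contact_map <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_loci
  chrom <- .chrom_of(n, spec$n_chromosomes)
  tad <- findInterval(seq_len(n) - 1L, spec$tad_boundaries)
  lag <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(spec$trans_level * spec$scale, n, n)
  cis <- outer(chrom, chrom, "==")
  E[cis] <- spec$scale * lag[cis]^(-spec$decay_exponent)
  same_tad <- outer(tad, tad, "==") & cis
  E[same_tad] <- E[same_tad] * spec$intra_tad_boost
  diag(E) <- 0
  M <- E
  if (spec$noise_level > 0) {
    set.seed(spec$seed)
    shape <- 1 / spec$noise_level^2
    up <- upper.tri(M)
    M[up] <- M[up] * stats::rgamma(sum(up), shape = shape,
                                   rate = shape)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
  }
  bins <- data.frame(chrom = paste0("chr", chrom),
                     start = as.numeric(seq_len(n) - 1) * spec$bin_size,
                     end = as.numeric(seq_len(n)) * spec$bin_size,
                     stringsAsFactors = FALSE)
  contact_map(M, bins = bins, bin_size = spec$bin_size,
              provenance = sprintf("synthetic(seed=%d)", spec$seed))
}

#' Planted perturbation of a base cell
#'
#' Encodes a synthetic "cell type": a permutation of the first K mode
#' frequencies (the mode shapes are kept, their eigenvalues are
#' reshuffled), a set of loci planted as highly mobile, and a label.
#'
#' @param mode_permutation integer vector, a bijection on `1..K`.
#' @param hm_loci integer bin indices (1-based) to be made highly
#'   mobile by contact weakening.
#' @param cell_label text label of the synthetic cell.
#' @return a `planted_perturbation`.
#' @export
planted_perturbation <- function(mode_permutation = integer(),
                                 hm_loci = integer(),
                                 cell_label = "cell") {
  p <- as.integer(mode_permutation)
  if (length(p) && !identical(sort(p), seq_along(p)))
    stop("mode_permutation must be a bijection on 1..K")
  structure(list(mode_permutation = p,
                 hm_loci = as.integer(hm_loci),
                 cell_label = cell_label),
            class = "planted_perturbation")
}

#' Generate a family of cell types sharing mode shapes
#'
#' Emulates the regime where related cell types share pre-existing
#' mode shapes but differ in mode frequencies. For each perturbation,
#' the base map's Kirchhoff matrix is re-assembled with mode shape
#' `u_k` carrying eigenvalue `lambda_{pi(k)}` over the first K modes
#' (the residual spectrum is untouched), after perturbing each shape
#' by a random rotation of magnitude `strength` (0 = shapes identical
#' to the base). The spring matrix is converted back to a contact map
#' with nonnegativity repair: a uniform background contact is added to
#' every pair, which makes all entries nonnegative while shifting the
#' nonzero eigenvalues uniformly and leaving mode shapes and their
#' ordering exactly unchanged. Contacts of any planted highly mobile
#' loci are then weakened so their mean-square fluctuations rise.
#'
#' @param base a connected [contact_map()].
#' @param perturbations list of [planted_perturbation()]s.
#' @param strength eigenvector perturbation magnitude in [0, 1];
#'   matched shapes overlap > 0.9 for strength <= 0.3.
#' @param seed integer seed.
#' @param hm_weaken multiplicative contact weakening applied to
#'   planted highly mobile loci (< 1).
#' @return named list of [contact_map()]s, one per perturbation.
#' @export
generate_cell_family <- function(base, perturbations, strength = 0.2,
                                 seed = 1L, hm_weaken = 0.5) {
  stopifnot(inherits(base, "contact_map"))
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  K <- max(1L, vapply(perturbations, function(p)
    length(p$mode_permutation), 1L))
  G <- build_kirchhoff(base)$matrix
  n <- nrow(G)
  ## decompose a low-frequency subspace wider than K so that shape
  ## perturbations stay confined to slow modes; mixing into the
  ## high-frequency residual would distort the planted spectrum
  L <- min(n - 1L, 2L * K + 10L)
  modes <- decompose(G, m = L)
  V <- modes$vectors
  lamL <- modes$values
  U <- V[, seq_len(K), drop = FALSE]
  set.seed(seed)
  out <- lapply(perturbations, function(p) {
    pi_k <- p$mode_permutation
    if (!length(pi_k)) pi_k <- seq_len(K)
    if (length(pi_k) < K) pi_k <- c(pi_k, (length(pi_k) + 1L):K)
    if (strength > 0 && L > K) {
      extra <- V[, (K + 1L):L, drop = FALSE]
      Z <- matrix(stats::rnorm((L - K) * K), L - K, K)
      Z <- sweep(Z, 2L, sqrt(colSums(Z^2)), "/")
      Ut <- qr.Q(qr(U + strength * extra %*% Z))
      ## qr may flip signs; realign with the base shapes
      flip <- colSums(Ut * U) < 0
      Ut[, flip] <- -Ut[, flip]
    } else Ut <- U
    ## orthonormal complement of Ut within span(V) takes over the
    ## unpermuted part of the low-frequency spectrum
    B <- qr.Q(qr(cbind(Ut, V)))[, seq_len(L), drop = FALSE]
    W <- B[, (K + 1L):L, drop = FALSE]
    Gp <- G - V %*% (lamL * t(V)) + Ut %*% (lamL[pi_k] * t(Ut)) +
      W %*% (lamL[(K + 1L):L] * t(W))
    Mp <- -Gp
    diag(Mp) <- 0
    ## nonnegativity repair: a uniform background contact added to all
    ## pairs shifts every nonzero eigenvalue by c*n and leaves mode
    ## shapes and their ordering exactly intact (complete-graph
    ## Laplacian shift), unlike clipping, which scrambles the planted
    ## spectrum
    cmin <- min(Mp[upper.tri(Mp)])
    if (cmin < 0) {
      Mp <- Mp - cmin
      diag(Mp) <- 0
    }
    Mp[Mp < 0] <- 0  # FP residue only
    Mp <- (Mp + t(Mp)) / 2
    if (length(p$hm_loci)) {
      h <- p$hm_loci
      Mp[h, ] <- Mp[h, , drop = FALSE] * hm_weaken
      Mp[, h] <- Mp[, h, drop = FALSE] * hm_weaken
    }
    contact_map(Mp, bins = base$bins, bin_size = base$bin_size,
                provenance = p$cell_label)
  })
  names(out) <- vapply(perturbations, `[[`, "", "cell_label")
  out
}

#' Generate a gene annotation tiling the bins
#'
#' Places `genes_per_bin` genes in every bin, at deterministic
#' seed-driven positions inside the bin (BED convention: 0-based,
#' half-open).
#'
#' @param n_loci number of bins.
#' @param bin_size bin width in bp.
#' @param genes_per_bin genes per bin (>= 1).
#' @param seed integer seed.
#' @param bins optional bin table; synthesized single-chromosome
#'   table if `NULL`.
#' @return annotation data.frame (`gene`, `chrom`, `start`, `end`).
#' @export
generate_gene_annotation <- function(n_loci, bin_size = 50000L,
                                     genes_per_bin = 1L, seed = 1L,
                                     bins = NULL) {
  if (genes_per_bin < 1) stop("genes_per_bin must be >= 1")
  if (is.null(bins))
    bins <- data.frame(chrom = rep("chr1", n_loci),
                       start = as.numeric(seq_len(n_loci) - 1) * bin_size,
                       end = as.numeric(seq_len(n_loci)) * bin_size,
                       stringsAsFactors = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(n_loci), function(i) {
    w <- bins$end[i] - bins$start[i]
    s <- bins$start[i] + floor(stats::runif(genes_per_bin, 0, w * 0.5))
    e <- s + pmax(1, floor(stats::runif(genes_per_bin, w * 0.1, w * 0.5)))
    data.frame(gene = sprintf("G%05d", (i - 1L) * genes_per_bin +
                                seq_len(genes_per_bin)),
               chrom = bins$chrom[i], start = s,
               end = pmin(e, bins$end[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic highly-expressed-gene collection
#'
#' Emulates an expression gene-set library keyed by cell type: each
#' true cell contributes a set sharing `1 - contamination` of its
#' highly mobile genes (the rest replaced by random fill from the
#' gene universe), plus `n_decoy_sets` decoy sets of random genes.
#'
#' @param true_hmgs named list, cell label -> character vector of
#'   highly mobile genes.
#' @param universe character vector of all gene ids.
#' @param n_decoy_sets number of random decoy sets.
#' @param contamination fraction of each true set replaced by random
#'   genes, in [0, 0.5).
#' @param seed integer seed.
#' @return named list of gene sets (GMT-serializable with
#'   [write_gmt()]).
#' @export
generate_heg_collection <- function(true_hmgs, universe,
                                    n_decoy_sets = 30L,
                                    contamination = 0.2, seed = 1L) {
  if (contamination < 0 || contamination >= 0.5)
    stop("contamination must be in [0, 0.5)")
  set.seed(seed)
  sets <- lapply(true_hmgs, function(g) {
    keep <- sample(g, round((1 - contamination) * length(g)))
    fill <- sample(setdiff(universe, keep), length(g) - length(keep))
    sort(c(keep, fill))
  })
  size <- if (length(true_hmgs))
    max(1L, round(mean(lengths(true_hmgs)))) else 10L
  decoys <- lapply(seq_len(n_decoy_sets), function(i)
    sort(sample(universe, min(size, length(universe)))))
  names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoy_sets))
  c(sets, decoys)
}

#' Embed a contact map as a 3D structure
#'
#' Distance-geometry embedding consistent with a target contact map
#' under the cube-law contact/distance relation: target distances are
#' taken as `d_ij = k / M_ij^(1/3)` (absent contacts are placed at
#' twice the largest finite distance) and embedded in 3D by classical
#' multidimensional scaling. The embedding is validated by the
#' Spearman correlation between the back-calculated contacts and the
#' target on its nonzero entries.
#'
#' @param target a connected [contact_map()].
#' @param k_const distance constant of the cube law.
#' @param seed integer seed (the embedding itself is deterministic).
#' @param min_rho embedding is rejected below this Spearman
#'   correlation.
#' @return a [structure_3d()].
#' @export
generate_structure <- function(target, k_const = 1, seed = 1L,
                               min_rho = 0.8) {
  stopifnot(inherits(target, "contact_map"))
  M <- target$matrix
  n <- nrow(M)
  D <- matrix(0, n, n)
  nz <- M > 0
  D[nz] <- k_const / M[nz]^(1 / 3)
  far <- 2 * max(D[nz])
  D[!nz] <- far
  diag(D) <- 0
  set.seed(seed)
  X <- stats::cmdscale(stats::as.dist(D), k = min(3L, n - 1L))
  if (ncol(X) < 3)  # degenerate planar/linear configurations
    X <- cbind(X, matrix(0, n, 3 - ncol(X)))
  s <- structure_3d(X, bins = target$bins, k_const = k_const,
                    bin_size = target$bin_size)
  back <- structure_to_contacts(s)$matrix
  up <- upper.tri(M) & nz
  rho <- suppressWarnings(stats::cor(back[up], M[up],
                                     method = "spearman"))
  if (is.na(rho)) return(s)  # constant contacts: exact by symmetry
  if (rho < min_rho)
    stop("embedding failed: back-calculated contacts correlate at ",
         "Spearman rho = ", format(rho), " < ", min_rho)
  s
}
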