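#' Single-cell 3D genome structure
#'
#' Per-locus (x, y, z) coordinates of a resolved 3D genome model, in
#' arbitrary length units, with the bin table of the loci. Used to
#' obtain contact frequencies by reverse calculation when raw
#' single-cell Hi-C is too sparse to yield a connected contact graph.
#'
#' @param coords numeric n x 3 matrix of coordinates.
#' @param bins bin table as in [contact_map()]; synthesized if `NULL`.
#' @param k_const the distance constant `k` relating contact frequency
#'   to Euclidean distance via `n = (k/d)^3`.
#' @param bin_size bin width in bp.
#' @return an object of class `structure_3d`.
#' @export
structure_3d <- function(coords, bins = NULL, k_const = 1,
                         bin_size = 50000L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (is.null(bins))
    bins <- data.frame(chrom = rep("chr1", n),
                       start = as.numeric(seq_len(n) - 1) * bin_size,
                       end   = as.numeric(seq_len(n)) * bin_size,
                       stringsAsFactors = FALSE)
  structure(list(coords = coords, bins = bins, k_const = k_const,
                 bin_size = bin_size),
            class = "structure_3d")
}

#' @export
print.structure_3d <- function(x, ...) {
  cat("3D genome structure:", nrow(x$coords), "loci, k =", x$k_const, "\n")
  invisible(x)
}

#' Convert a 3D structure to a contact map
#'
#' Contact frequencies are obtained by reverse calculation from the
#' model, without any normalization, as `M_ij = (k / d_ij)^3` where
#' `d_ij` is the Euclidean distance between loci `i` and `j`. The
#' diagonal is zero. Because the cube law diverges as `d -> 0`,
#' coincident loci are an error unless a finite `cap` is configured;
#' resolved 3D models have excluded volume, so the default is no cap.
#'
#' @param s a [structure_3d()].
#' @param cap optional maximum contact value; entries above it
#'   (including divergent ones) are truncated.
#' @return a [contact_map()].
#' @export
structure_to_contacts <- function(s, cap = NULL) {
  stopifnot(inherits(s, "structure_3d"))
  d <- as.matrix(stats::dist(s$coords))
  off <- d[upper.tri(d)]
  if (any(off == 0) && is.null(cap))
    stop("coincident loci (d = 0) produce divergent contacts; set a cap")
  M <- (s$k_const / d)^3
  diag(M) <- 0
  if (!is.null(cap)) M[M > cap | !is.finite(M)] <- cap
  contact_map(M, bins = s$bins, bin_size = s$bin_size,
              provenance = sprintf("structure (k = %g)", s$k_const))
}

#' Read / write locus coordinate tables
#'
#' TSV with columns `locus`, `x`, `y`, `z` (plus optional `chrom`,
#' `start`, `end`).
#'
#' @param path file path.
#' @param k_const,bin_size passed to [structure_3d()].
#' @return `read_structure` a [structure_3d()]; `write_structure`
#'   invisibly `path`.
#' @export
read_structure <- function(path, k_const = 1, bin_size = 50000L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  bins <- if (all(c("chrom", "start", "end") %in% names(tab)))
    tab[, c("chrom", "start", "end")] else NULL
  structure_3d(as.matrix(tab[, c("x", "y", "z")]), bins = bins,
               k_const = k_const, bin_size = bin_size)
}

#' @rdname read_structure
#' @param s a [structure_3d()].
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_3d"))
  tab <- data.frame(locus = seq_len(nrow(s$coords)) - 1L,
                    s$bins,
                    x = s$coords[, 1L], y = s$coords[, 2L],
                    z = s$coords[, 3L])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
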