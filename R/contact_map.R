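#' Hi-C contact map container
#'
#' A `contact_map` holds a symmetric, nonnegative loci-by-loci contact
#' matrix `M` together with its bin table (chromosome, start, end, in bp,
#' 0-based half-open intervals) and a validity mask over the *original*
#' bins, so that results computed on filtered maps can always be
#' re-indexed to original genomic coordinates. `M[i, j]` is the number
#' (or strength) of contacts between loci `i` and `j`; it is the sole
#' experimental input to the Gaussian network model.
#'
#' @param matrix numeric n x n matrix, symmetric and nonnegative.
#' @param bins data.frame with columns `chrom`, `start`, `end` (bp),
#'   one row per matrix row, sorted by (chrom, start). If `NULL`, a
#'   single-chromosome table at `bin_size` resolution is synthesized.
#' @param bin_size bin width in bp (default 50000, i.e. 50 kb per locus).
#' @param valid_mask logical vector over the original bins; `FALSE`
#'   marks bins dropped by filtering (e.g. centromeric bins with no
#'   contacts). Defaults to all `TRUE`.
#' @param provenance free-text description of where the map came from.
#' @return an object of class `contact_map`.
#' @seealso [read_contact_map()], [filter_bins()], [combine_maps()],
#'   [gnm()]
#' @export
contact_map <- function(matrix, bins = NULL, bin_size = 50000L,
                        valid_mask = NULL, provenance = "in-memory") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  if (n != ncol(matrix))
    stop("contact matrix must be square, got ", n, " x ", ncol(matrix))
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-9)
    stop("contact matrix is asymmetric beyond tolerance (max |M - t(M)| = ",
         format(asym), ")")
  matrix <- (matrix + t(matrix)) / 2
  if (any(matrix < 0))
    stop("contact matrix has negative entries")
  if (is.null(bins)) {
    bins <- data.frame(chrom = rep("chr1", n),
                       start = as.numeric(seq_len(n) - 1) * bin_size,
                       end   = as.numeric(seq_len(n)) * bin_size,
                       stringsAsFactors = FALSE)
  }
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(bins)))
    stop("bins must have columns chrom, start, end")
  if (nrow(bins) != n)
    stop("bin table has ", nrow(bins), " rows but matrix has ", n)
  ord <- order(bins$chrom, bins$start)
  if (!all(ord == seq_len(n)))
    stop("bins must be sorted by (chromosome, start)")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, bins = bins, bin_size = bin_size,
                 valid_mask = valid_mask, provenance = provenance),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  cat("Hi-C contact map: ", n, " bins (",
      length(unique(x$bins$chrom)), " chromosome(s), ",
      x$bin_size, " bp/bin)\n", sep = "")
  cat("  nonzero contacts:", sum(x$matrix[upper.tri(x$matrix)] > 0),
      " total count:", format(sum(x$matrix) / 2), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$matrix)

## adjacency components of M > 0 within a set of rows; returns membership
.components <- function(M) {
  n <- nrow(M)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(M[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Read a contact map from disk
#'
#' Two plain-text dialects are supported. The canonical interchange
#' format is *sparse triplet + bin table*: a TSV of `bin1 bin2 count`
#' records (0-based bin indices, either triangle) next to a bin-table
#' TSV of `chrom start end`. A small *dense* TSV matrix is also
#' accepted.
#'
#' @param path path to the triplet TSV (`format = "triplet"`) or the
#'   dense matrix TSV (`format = "dense"`).
#' @param format one of `"triplet"`, `"dense"`.
#' @param bins_path bin-table TSV; required for `"triplet"`, optional
#'   for `"dense"`.
#' @param bin_size bin width in bp used when a bin table must be
#'   synthesized.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, format = c("triplet", "dense"),
                             bins_path = NULL, bin_size = 50000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "triplet") {
    if (is.null(bins_path))
      stop("triplet format requires a bin-table file (bins_path)")
    bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    n <- nrow(bins)
    tr <- utils::read.table(path, header = TRUE, sep = "\t")
    if (!all(c("bin1", "bin2", "count") %in% names(tr)))
      stop("triplet file must have columns bin1, bin2, count")
    if (any(tr$count < 0)) stop("negative counts in triplet file")
    if (any(tr$bin1 < 0 | tr$bin2 < 0 | tr$bin1 >= n | tr$bin2 >= n))
      stop("triplet references a bin outside the ", n, "-bin table")
    M <- matrix(0, n, n)
    ## mirror whichever triangle was given
    M[cbind(tr$bin1 + 1L, tr$bin2 + 1L)] <- tr$count
    M2 <- t(M)
    keep <- M == 0
    M[keep] <- M2[keep]
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    contact_map(M, bins = bins, bin_size = bin_size,
                provenance = paste0("triplet:", path))
  } else {
    M <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    if (max(abs(M - t(M))) > 1e-9)
      stop("dense matrix is asymmetric beyond tolerance")
    if (any(M < 0)) stop("negative counts in dense matrix")
    bins <- NULL
    if (!is.null(bins_path))
      bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    contact_map(M, bins = bins, bin_size = bin_size,
                provenance = paste0("dense:", path))
  }
}

#' Write a contact map as sparse triplets plus a bin table
#'
#' @param map a [contact_map()].
#' @param path output triplet TSV (columns `bin1 bin2 count`, upper
#'   triangle incl. diagonal, 0-based).
#' @param bins_path output bin-table TSV (`chrom start end`).
#' @return invisibly, `path`.
#' @export
write_contact_map <- function(map, path, bins_path) {
  stopifnot(inherits(map, "contact_map"))
  M <- map$matrix
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  tr <- data.frame(bin1 = idx[, 1L] - 1L, bin2 = idx[, 2L] - 1L,
                   count = M[idx])
  tr <- tr[order(tr$bin1, tr$bin2), ]
  utils::write.table(tr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(map$bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop empty bins and keep the largest connected component
#'
#' Bins with zero total contacts are removed; then, within the analysis
#' scope, only the largest connected component of the contact graph is
#' retained (ties broken toward the component containing the
#' lowest-index bin). The validity mask tracks the surviving bins
#' relative to the *original* bin table, so downstream profiles can be
#' re-indexed to genomic coordinates. Idempotent.
#'
#' @param map a [contact_map()].
#' @param scope `"genome"`: one component across all bins (trans
#'   contacts count); `"chromosome"`: the largest component within each
#'   chromosome is kept.
#' @return a filtered [contact_map()].
#' @export
filter_bins <- function(map, scope = c("genome", "chromosome")) {
  stopifnot(inherits(map, "contact_map"))
  scope <- match.arg(scope)
  M <- map$matrix
  n <- nrow(M)
  keep <- rowSums(M) - diag(M) > 0
  if (scope == "genome") {
    sub <- which(keep)
    comp <- .components(M[sub, sub, drop = FALSE])
    sizes <- tabulate(comp)
    keep_sub <- comp == which.max(sizes)
    keep <- rep(FALSE, n)
    keep[sub[keep_sub]] <- TRUE
  } else {
    for (ch in unique(map$bins$chrom)) {
      on_ch <- which(map$bins$chrom == ch & keep)
      if (!length(on_ch)) next
      comp <- .components(M[on_ch, on_ch, drop = FALSE])
      sizes <- tabulate(comp)
      keep[on_ch[comp != which.max(sizes)]] <- FALSE
    }
  }
  if (sum(keep) < 3)
    stop("fewer than 3 bins survive filtering; map is degenerate")
  mask <- map$valid_mask
  mask[mask] <- keep  # compose with any earlier filtering
  contact_map(M[keep, keep, drop = FALSE],
              bins = map$bins[keep, , drop = FALSE],
              bin_size = map$bin_size, valid_mask = mask,
              provenance = paste0(map$provenance, " | filtered(", scope, ")"))
}

#' Sum contact maps element-wise
#'
#' Combines maps over identical bin tables by element-wise summation,
#' e.g. to pool sparse single-cell contact maps into "combined
#' single-cell data" before model fitting.
#'
#' @param maps list of [contact_map()]s over the same bin table.
#' @return the combined [contact_map()].
#' @export
combine_maps <- function(maps) {
  stopifnot(length(maps) >= 1, all(vapply(maps, inherits, TRUE, "contact_map")))
  ref <- maps[[1L]]$bins
  for (m in maps[-1L])
    if (!identical(dim(m$matrix), dim(maps[[1L]]$matrix)) ||
        !isTRUE(all.equal(m$bins, ref, check.attributes = FALSE)))
      stop("maps have mismatched bin tables and cannot be combined")
  M <- Reduce(`+`, lapply(maps, `[[`, "matrix"))
  contact_map(M, bins = ref, bin_size = maps[[1L]]$bin_size,
              provenance = paste0("combined(",
                                  paste(vapply(maps, `[[`, "", "provenance"),
                                        collapse = " + "), ")"))
}
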