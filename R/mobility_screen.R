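#' Relative mobility profiles across a cell cohort
#'
#' For each cell `q`, subtracts from its MSF profile the mean MSF over
#' all cells in the cohort at each locus; the resulting per-cell
#' deviations sum to the zero vector across the cohort. Profiles are
#' first restricted to the bins valid in every cell. Profiles should
#' be normalized ([normalize_profile()]) before comparison across
#' cells with different sequencing depths.
#'
#' @param profiles named list of `mobility_profile`s (>= 2 cells).
#' @return named list of `relative_mobility` profiles: per-locus
#'   deviations with the common mask attached.
#' @export
relative_mobility <- function(profiles) {
  Q <- length(profiles)
  if (Q < 2) stop("relative mobility needs at least 2 cells")
  masks <- lapply(profiles, attr, "mask")
  if (any(vapply(masks, is.null, TRUE))) {
    len <- unique(vapply(profiles, length, 1L))
    if (length(len) != 1) stop("profiles differ in length and carry no masks")
    common <- rep(TRUE, len)
    masks <- rep(list(common), Q)
  } else {
    common <- Reduce(`&`, masks)
  }
  X <- vapply(seq_len(Q), function(i)
    as.numeric(profiles[[i]])[common[masks[[i]]]],
    numeric(sum(common)))
  mu <- rowMeans(X)
  out <- lapply(seq_len(Q), function(i)
    structure(X[, i] - mu, mask = common,
              cell = attr(profiles[[i]], "cell"),
              cohort_size = Q, class = "relative_mobility"))
  names(out) <- names(profiles)
  out
}

#' Call highly mobile loci
#'
#' Loci with the highest relative mobility (top 10% by default) are
#' considered highly mobile. Exactly `ceiling(fraction * n)` loci are
#' returned; ties at the threshold are broken toward the lower bin
#' index. Indices refer to the profile's own (masked) bins; use the
#' attached mask to map back to original bins.
#'
#' @param rel a `relative_mobility` profile (or numeric vector).
#' @param fraction top fraction to call, in (0, 1); default 0.10.
#' @return integer vector of selected locus indices (ascending).
#' @export
call_hm_loci <- function(rel, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(rel)
  k <- ceiling(fraction * n)
  ord <- order(-as.numeric(rel), seq_len(n))
  sort(ord[seq_len(k)])
}

#' Map selected loci to genes
#'
#' A gene is included iff its interval overlaps any selected bin by at
#' least 1 bp (half-open interval intersection, BED convention).
#'
#' @param loci integer indices into `bins` (rows of the bin table the
#'   profile was computed on).
#' @param annotation data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (bp, 0-based half-open); see [read_bed()].
#' @param bins bin table (`chrom`, `start`, `end`) aligned with the
#'   profile that produced `loci`.
#' @return character vector of gene ids (a gene set).
#' @export
loci_to_genes <- function(loci, annotation, bins) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  known <- annotation$chrom %in% unique(bins$chrom)
  if (!all(known)) {
    warning(sum(!known), " gene(s) on chromosomes absent from the bin ",
            "table were skipped")
    annotation <- annotation[known, , drop = FALSE]
  }
  sel <- bins[loci, , drop = FALSE]
  hits <- vapply(seq_len(nrow(annotation)), function(g) {
    on_ch <- sel$chrom == annotation$chrom[g]
    any(on_ch &
          annotation$start[g] < sel$end &
          annotation$end[g] > sel$start)
  }, TRUE)
  unique(annotation$gene[hits])
}

#' Jaccard index between two gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`; defined as 0 when both
#' sets are empty so that rankings remain total.
#'
#' @param a,b character vectors of gene ids.
#' @return scalar in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Screen a gene set against a gene-set collection
#'
#' Scores the query (e.g. a cell's highly mobile genes) against every
#' set in a collection (e.g. highly-expressed-gene sets of known cell
#' types) by Jaccard index and ranks candidates from highest to lowest
#' overlap; ties are broken alphabetically by label. If the
#' collection contains a set named after `query_label`, its rank is
#' reported as the self-match rank.
#'
#' @param query character vector of gene ids (non-empty).
#' @param collection named list of character vectors (a GMT
#'   collection; see [read_gmt()]).
#' @param query_label optional label of the querying cell.
#' @return a `screening_result`: data.frame `ranking` (label,
#'   jaccard, rank) plus `self_rank` (NA if absent).
#' @export
screen <- function(query, collection, query_label = NULL) {
  if (!length(query)) stop("query gene set is empty")
  if (!length(collection)) stop("gene-set collection is empty")
  J <- vapply(collection, jaccard, 0, a = query)
  ord <- order(-J, names(collection))
  ranking <- data.frame(label = names(collection)[ord],
                        jaccard = as.numeric(J[ord]),
                        rank = seq_along(J),
                        stringsAsFactors = FALSE)
  self_rank <- if (!is.null(query_label) &&
                   query_label %in% ranking$label)
    ranking$rank[ranking$label == query_label] else NA_integer_
  structure(list(query = query_label, ranking = ranking,
                 self_rank = self_rank),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Gene-set screening", if (!is.null(x$query))
    paste0("for ", x$query), "\n")
  print(utils::head(x$ranking, 5))
  if (!is.na(x$self_rank)) cat("self-match rank:", x$self_rank, "\n")
  invisible(x)
}

#' Read / write BED gene annotations
#'
#' Minimal 4-column BED (`chrom start end name`), 0-based half-open.
#'
#' @param path file path.
#' @return `read_bed`: data.frame with columns `gene`, `chrom`,
#'   `start`, `end`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED file needs >= 4 columns")
  data.frame(gene = tab[[4L]], chrom = tab[[1L]],
             start = tab[[2L]], end = tab[[3L]],
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param annotation data.frame as returned by `read_bed`.
#' @export
write_bed <- function(annotation, path) {
  utils::write.table(annotation[, c("chrom", "start", "end", "gene")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections (GMT)
#'
#' Tab-separated GMT: set name, description, then member genes.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
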