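#' Aggregate per-chromosome distances into a cell-cell distance graph
#'
#' Each chromosome contributes a pairwise arc-distance matrix between
#' cells; a single complete distance graph is formed by aggregating
#' across chromosomes for each cell pair. The default aggregation is
#' the maximum distance (equivalently, the minimum covariance overlap)
#' across chromosomes.
#'
#' @param per_chromosome named list of symmetric zero-diagonal
#'   matrices, one per chromosome, all with the same cell labels as
#'   dimnames (a single matrix is also accepted).
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return a `distance_graph`: symmetric matrix with cell labels and
#'   the aggregation rule recorded.
#' @export
build_distance_graph <- function(per_chromosome,
                                 aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(per_chromosome))
    per_chromosome <- list(per_chromosome)
  ref <- rownames(per_chromosome[[1L]])
  if (is.null(ref))
    stop("distance matrices must carry cell labels as dimnames")
  for (D in per_chromosome) {
    if (!identical(rownames(D), ref) || !identical(colnames(D), ref))
      stop("inconsistent cell sets across chromosomes")
    if (max(abs(D - t(D))) > 1e-9 || any(diag(D) != 0))
      stop("each distance matrix must be symmetric with zero diagonal")
  }
  A <- array(unlist(per_chromosome),
             dim = c(length(ref), length(ref), length(per_chromosome)))
  G <- apply(A, c(1L, 2L), if (aggregate == "max") max else mean)
  dimnames(G) <- list(ref, ref)
  structure(G, aggregate = aggregate, class = "distance_graph")
}

#' Minimum spanning tree of a cell distance graph (Prim)
#'
#' Grows the tree from the lexicographically first cell; at every step
#' the cheapest edge crossing the cut is added, ties broken by the
#' sorted (in-tree label, out-of-tree label) pair so the result is
#' deterministic. Cells at intermediate differentiation stages appear
#' as internal (high-degree) vertices.
#'
#' @param g a [build_distance_graph()] result or a labeled symmetric
#'   matrix.
#' @return a `cell_tree` of kind `"mst"`: edge table `edges`
#'   (`from`, `to`, `weight`), `labels`, `total_weight`.
#' @export
minimum_spanning_tree <- function(g) {
  D <- unclass(g)
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2) stop("need at least 2 cells")
  ord <- order(labels)
  in_tree <- rep(FALSE, n)
  in_tree[ord[1L]] <- TRUE
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  for (step in seq_len(n - 1L)) {
    ins <- which(in_tree); outs <- which(!in_tree)
    cand <- expand.grid(i = ins, j = outs)
    cand$w <- D[cbind(cand$i, cand$j)]
    cand <- cand[order(cand$w, labels[cand$i], labels[cand$j]), ]
    best <- cand[1L, ]
    edges <- rbind(edges, data.frame(from = labels[best$i],
                                     to = labels[best$j],
                                     weight = best$w,
                                     stringsAsFactors = FALSE))
    in_tree[best$j] <- TRUE
  }
  structure(list(kind = "mst", edges = edges, labels = labels,
                 total_weight = sum(edges$weight)),
            class = "cell_tree")
}

#' Neighbor-joining dendrogram of a cell distance graph
#'
#' Standard Saitou-Nei agglomeration over the aggregated arc
#' distances; every cell is a terminal node (leaf) of the resulting
#' unrooted binary tree. Negative intermediate branch lengths, which
#' NJ can produce on non-additive distances, are clamped to zero with
#' the deficit shifted onto the sister branch so path lengths between
#' leaves are preserved.
#'
#' @param g a [build_distance_graph()] result or labeled symmetric
#'   matrix, >= 3 cells.
#' @return a `cell_tree` of kind `"nj"` wrapping an [ape::nj()]
#'   `phylo` object (`$phylo`).
#' @export
neighbor_joining <- function(g) {
  D <- unclass(g)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 cells")
  phy <- ape::nj(stats::as.dist(D))
  ## clamp-and-shift negative branch lengths
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1L]
    sibs <- setdiff(which(phy$edge[, 1L] == parent), e)
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    if (length(sibs))
      phy$edge.length[sibs[1L]] <- phy$edge.length[sibs[1L]] + deficit
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  structure(list(kind = "nj", phylo = phy, labels = rownames(D)),
            class = "cell_tree")
}

#' @export
print.cell_tree <- function(x, ...) {
  if (x$kind == "mst") {
    cat("Minimum spanning tree over", length(x$labels),
        "cells, total weight", format(x$total_weight), "\n")
    print(x$edges)
  } else {
    cat("Neighbor-joining tree over", length(x$labels), "cells\n")
    print(x$phylo)
  }
  invisible(x)
}

#' Leaf bipartitions induced by a cell tree
#'
#' For every edge of the tree, the set of cells on one side of that
#' edge (the smaller side, by label-sorted convention). Used to test
#' whether a planted grouping is recovered.
#'
#' @param tree a `cell_tree`.
#' @return list of character vectors of cell labels.
#' @export
tree_splits <- function(tree) {
  if (tree$kind == "mst") {
    labs <- tree$labels
    adj <- lapply(labs, function(l) character())
    names(adj) <- labs
    for (r in seq_len(nrow(tree$edges))) {
      a <- tree$edges$from[r]; b <- tree$edges$to[r]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    splits <- lapply(seq_len(nrow(tree$edges)), function(r) {
      a <- tree$edges$from[r]; b <- tree$edges$to[r]
      seen <- b; queue <- b   # component containing b with edge removed
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- adj[[v]]
        if (v == b) nb <- setdiff(nb, a)
        nb <- nb[!(nb %in% seen)]
        seen <- c(seen, nb); queue <- c(queue, nb)
      }
      sort(seen)
    })
  } else {
    phy <- tree$phylo
    n_tip <- length(phy$tip.label)
    desc <- function(node) {
      if (node <= n_tip) return(phy$tip.label[node])
      kids <- phy$edge[phy$edge[, 1L] == node, 2L]
      unlist(lapply(kids, desc))
    }
    splits <- lapply(seq_len(nrow(phy$edge)), function(e)
      sort(desc(phy$edge[e, 2L])))
  }
  all_labs <- sort(tree$labels)
  lapply(splits, function(s)
    if (length(s) > length(all_labs) / 2) setdiff(all_labs, s) else s)
}

#' Serialize a cell tree to Newick
#'
#' NJ trees are written via [ape::write.tree()]; MST trees are written
#' with cells as labeled (possibly internal) nodes, rooted at the
#' lexicographically first cell, with branch lengths equal to the arc
#' distances.
#'
#' @param tree a `cell_tree`.
#' @param path optional file; if missing the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (tree$kind == "nj") {
    s <- ape::write.tree(tree$phylo)
  } else {
    labs <- tree$labels
    adj <- list()
    for (r in seq_len(nrow(tree$edges))) {
      a <- tree$edges$from[r]; b <- tree$edges$to[r]
      w <- tree$edges$weight[r]
      adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w))
      adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w))
    }
    rec <- function(node, parent) {
      kids <- adj[[node]]
      if (!is.na(parent))
        kids <- kids[kids$to != parent, , drop = FALSE]
      if (is.null(kids) || !nrow(kids)) return(node)
      inner <- paste(vapply(seq_len(nrow(kids)), function(i)
        paste0(rec(kids$to[i], node), ":", format(kids$w[i])), ""),
        collapse = ",")
      paste0("(", inner, ")", node)
    }
    root <- sort(labs)[1L]
    s <- paste0(rec(root, NA_character_), ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
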