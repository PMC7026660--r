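## shared fixtures: tiny contact maps and random generators

## 3-bin path: the canonical hand-checkable network
path3_map <- function() {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 1
  M[2, 3] <- M[3, 2] <- 1
  contact_map(M)
}

## random connected symmetric nonnegative map: a weighted chain
## guarantees connectivity, plus random extra contacts
random_connected_map <- function(n, seed, density = 0.3) {
  set.seed(seed)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) M[i, i + 1L] <- M[i + 1L, i] <- runif(1, 0.5, 2)
  extra <- which(upper.tri(M) & M == 0)
  pick <- sample(extra, round(density * length(extra)))
  M[pick] <- runif(length(pick), 0.1, 1)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  contact_map(M)
}

## minimal gnm-like object from explicit eigenpairs (unit-norm columns)
manual_fit <- function(vectors, values, label = "manual") {
  vectors <- as.matrix(vectors)
  structure(list(values = values, vectors = vectors,
                 n_zero = 1L, n = nrow(vectors),
                 msf = as.numeric((vectors^2) %*% (1 / values)),
                 valid_mask = rep(TRUE, nrow(vectors)),
                 label = label),
            class = "gnm")
}

## exhaustive minimum assignment cost over all permutations (m <= 7)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best) { best <- cst; best_p <- p }
  }
  list(cost = best, assignment = best_p)
}

## all spanning trees of a complete graph via Pruefer sequences
spanning_tree_weights <- function(D) {
  n <- nrow(D)
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2L))
  apply(seqs, 1L, function(pr) {
    pr <- as.integer(pr)
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- rep(TRUE, n)
    for (v in pr) {
      leaf <- which(avail & degree == 1L)[1L]
      w <- w + D[leaf, v]
      degree[leaf] <- 0L; avail[leaf] <- FALSE
      degree[v] <- degree[v] - 1L
    }
    last <- which(avail & degree >= 1L)
    w + D[last[1L], last[2L]]
  })
}
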