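#' Minimum-cost rectangular assignment
#'
#' Jonker-Volgenant shortest-augmenting-path solver for the linear
#' assignment problem with `nrow(cost) <= ncol(cost)`. Each row is
#' assigned a distinct column so that the total cost is globally
#' minimal. Ties between equally cheap columns are broken toward the
#' smaller column index, so the result is deterministic.
#'
#' @param cost numeric cost matrix, rows <= columns, finite entries.
#' @return integer vector `a` with `a[i]` the column assigned to row
#'   `i`; `attr(, "cost")` holds the total cost.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n > m)
    stop("assignment needs nrow <= ncol (", n, " > ", m, ")")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n)          # row potentials
  v <- numeric(m + 1L)     # column potentials, slot 1 = virtual column
  p <- integer(m + 1L)     # p[j + 1] = row matched to column j (0 free)
  way <- integer(m + 1L)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[cols + 1L])
      red <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- red < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- red[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]   # ties -> smallest column
      delta <- minv[j1]
      usedj <- which(used)                # includes virtual column
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {                               # unwind the alternating path
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in cols) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  structure(a, cost = sum(cost[cbind(seq_len(n), a)]))
}
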