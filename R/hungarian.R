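#' Minimum-cost perfect matching (Hungarian algorithm)
#'
#' Solves the linear sum assignment problem on a square cost matrix using the
#' shortest-augmenting-path formulation with dual potentials (O(n^3)). This
#' is the assignment engine behind both tracker stages: matching previous-frame
#' flies to (duplicated) blob nodes, and re-assigning identities after merged
#' blobs are split.
#'
#' @param cost square numeric matrix; `cost[i, j]` is the cost of assigning
#'   row `i` to column `j`. All entries must be finite.
#' @return list with `assignment` (integer vector: column matched to each
#'   row) and `cost` (total cost of the optimal matching).
#' @export
#' @examples
#' solve_assignment(matrix(c(1, 2, 3, 1), 2, 2))
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  if (!all(is.finite(cost)))
    abort("assignment costs must be finite", class = "flynet_bad_cost")
  n <- nrow(cost)
  if (n == 0L) return(list(assignment = integer(), cost = 0))
  INF <- .Machine$double.xmax / 4
  # columns are 1..n; index n+1 is the virtual unmatched column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j]: row currently matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(INF, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      jrel <- which.min(minv[free])
      delta <- minv[free][jrel]
      j1 <- free[jrel]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used[seq_len(n)]] <- minv[!used[seq_len(n)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == n + 1L) i else p[j1]
      if (j1 == n + 1L) break
      j0 <- j1
    }
  }
  assignment <- integer(n)
  assignment[p[seq_len(n)]] <- seq_len(n)
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
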