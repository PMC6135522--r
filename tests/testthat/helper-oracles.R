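# Brute-force oracles used across the suite. Deliberately naive: direct
# definitional loops and exhaustive enumeration, independent of the package
# implementation paths they check.

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exhaustive minimum assignment cost
brute_assignment <- function(cost) {
  n <- nrow(cost)
  pm <- all_perms(n)
  costs <- apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(cost = min(costs), perm = pm[which.min(costs), ])
}

# exhaustive QAP: minimize ||W1 - W2[p, p]||_F over all permutations
brute_qap <- function(W1, W2) {
  n <- nrow(W1)
  pm <- all_perms(n)
  vals <- apply(pm, 1, function(p) norm(W1 - W2[p, p, drop = FALSE], "F"))
  list(objective = min(vals), perm = pm[which.min(vals), ])
}

# random weighted digraph weights (max-normalized, zero diagonal)
random_weights <- function(n, density = 0.5) {
  W <- matrix(round(runif(n * n) * 9) * (runif(n * n) < density), n, n)
  diag(W) <- 0
  if (max(W) > 0) W <- W / max(W)
  W
}

random_counts <- function(n, density = 0.5, max_count = 9) {
  C <- matrix(sample(0:max_count, n * n, replace = TRUE) *
                (runif(n * n) < density), n, n)
  diag(C) <- 0
  C
}

# --- definitional network parameter loops -------------------------------

oracle_degrees <- function(counts) {
  n <- nrow(counts)
  A <- counts > 0
  out <- matrix(0, n, 6,
                dimnames = list(NULL, c("in", "out", "deg", "win", "wout", "wdeg")))
  W <- if (max(counts) > 0) counts / max(counts) else counts * 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (A[j, i]) out[i, "in"] <- out[i, "in"] + 1
      if (A[i, j]) out[i, "out"] <- out[i, "out"] + 1
      out[i, "win"] <- out[i, "win"] + W[j, i]
      out[i, "wout"] <- out[i, "wout"] + W[i, j]
    }
    out[i, "deg"] <- out[i, "in"] + out[i, "out"]
    out[i, "wdeg"] <- out[i, "win"] + out[i, "wout"]
  }
  out
}

# Fagiolo weighted directed clustering by explicit triangle loops
oracle_clustering <- function(W) {
  n <- nrow(W)
  A <- (W > 0) * 1
  Wh <- W^(1 / 3)
  sapply(seq_len(n), function(i) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i) next
      tri <- tri + (Wh[i, j] + Wh[j, i]) * (Wh[j, k] + Wh[k, j]) *
        (Wh[k, i] + Wh[i, k])
    }
    # note j == k terms contribute the reciprocated-pair correction implicitly
    dtot <- sum(A[i, -i]) + sum(A[-i, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (den > 0) tri / den else 0
  })
}

# all simple paths i -> j (lists of vertices), for exhaustive betweenness
enum_paths <- function(adj_ok, from, to, n) {
  out <- list()
  recur <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (nx in seq_len(n)) {
      if (nx %in% path) next
      if (adj_ok[last, nx]) recur(c(path, nx))
    }
  }
  recur(from)
  out
}

# betweenness by full path enumeration: fraction of shortest paths through v
oracle_betweenness <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  ok <- is.finite(L)
  b <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- enum_paths(ok, s, t, n)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) {
      sum(L[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    mn <- min(lens)
    short <- paths[lens <= mn + 1e-12]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(p) v %in% p[-c(1, length(p))],
                            logical(1)))
      b[v] <- b[v] + through / length(short)
    }
  }
  b / ((n - 1) * (n - 2))
}

oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  ok <- is.finite(L)
  tot <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- enum_paths(ok, s, t, n)
    d <- if (length(paths)) {
      min(vapply(paths, function(p) sum(L[cbind(p[-length(p)], p[-1])]),
                 numeric(1)))
    } else Inf
    tot <- tot + 1 / d
  }
  tot / (n * (n - 1))
}

oracle_transitivity <- function(counts) {
  A <- (counts > 0) * 1
  n <- nrow(A)
  open <- 0; closed <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (A[i, j] && A[j, k]) {
      open <- open + 1
      if (A[i, k]) closed <- closed + 1
    }
  }
  if (open > 0) closed / open else NA_real_
}

oracle_assortativity <- function(counts) {
  A <- counts > 0
  n <- nrow(A)
  dtot <- rowSums(A) + colSums(A)
  ds <- c(); dt <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j]) { ds <- c(ds, dtot[i]); dt <- c(dt, dtot[j]) }
  }
  if (length(ds) < 2 || sd(ds) == 0 || sd(dt) == 0) return(NA_real_)
  cor(ds, dt)
}

# run-length oracle for interaction extraction: simulate the boolean series
oracle_interactions <- function(true_frames, horizon, min_run, min_gap) {
  x <- rep(FALSE, horizon + 1L)
  x[true_frames + 1L] <- TRUE
  # merge gaps < min_gap
  r <- rle(x)
  idx <- which(!r$values & r$lengths < min_gap)
  idx <- setdiff(idx, c(1, length(r$values)))  # leading/trailing gaps stay
  r$values[idx] <- TRUE
  y <- inverse.rle(r)
  r2 <- rle(y)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= min_run
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep] - 1L)
}
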