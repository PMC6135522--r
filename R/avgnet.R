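#' Frobenius matching objective
#'
#' The graph-matching objective \eqn{\|W_1 - P W_2 P^T\|_F} for a candidate
#' permutation matrix P.
#'
#' @param W1,W2 square matrices of equal size.
#' @param P permutation matrix.
#' @return non-negative scalar.
#' @export
frobenius_objective <- function(W1, W2, P) {
  stopifnot(all(dim(W1) == dim(W2)), all(dim(P) == dim(W1)))
  if (!is_permutation_matrix(P))
    abort("P is not a permutation matrix", class = "flynet_bad_perm")
  norm(W1 - P %*% W2 %*% t(P), type = "F")
}

# objective in index form: perm[k] = node of W2 placed at position k
frobenius_objective_perm <- function(W1, W2, perm) {
  norm(W1 - W2[perm, perm, drop = FALSE], type = "F")
}

#' Match two networks by graduated assignment
#'
#' Finds an approximate minimizer of \eqn{\|W_1 - P W_2 P^T\|_F} over
#' permutation matrices: the doubly-stochastic relaxation is updated by
#' softassign - an exponentiated compatibility gradient followed by
#' alternating row/column (Sinkhorn) normalization - while the inverse
#' temperature is annealed from `beta0` by factor `beta_rate` up to
#' `beta_max`. The final soft assignment is projected to the nearest
#' permutation by maximum-weight bipartite matching and polished by
#' pairwise-transposition (2-opt) descent. The identity permutation is a
#' guaranteed fallback: the returned objective never exceeds it.
#'
#' @param W1,W2 square matrices of equal size (max-normalized adjacency
#'   weights; relabelling both by outgoing activity first helps, see
#'   [relabel_by_outgoing()]).
#' @param beta0,beta_rate,beta_max annealing schedule of the inverse
#'   temperature.
#' @param sinkhorn_sweeps row/column normalizations per temperature step.
#' @param sinkhorn_tol tolerance on row/column sums.
#' @param polish logical; run 2-opt descent after discretization.
#' @param restarts number of additional seeded random 2-opt starts; the
#'   annealed relaxation finds the right basin on structured inputs, and the
#'   restarts guard against shallow local minima on small noisy ones.
#'   Deterministic: the restart stream is internally seeded.
#' @return list with `P` (permutation matrix), `perm` (index form:
#'   `W2[perm, perm]` is the aligned copy) and `objective`.
#' @export
match_graphs <- function(W1, W2, beta0 = 0.5, beta_rate = 1.075,
                         beta_max = 10, sinkhorn_sweeps = 30L,
                         sinkhorn_tol = 1e-6, polish = TRUE, restarts = 20L) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  stopifnot(all(dim(W1) == dim(W2)), nrow(W1) == ncol(W1))
  n <- nrow(W1)
  if (n == 1L)
    return(list(P = matrix(1, 1, 1), perm = 1L, objective = abs(W1 - W2)))
  M <- matrix(1 / n, n, n)
  beta <- beta0
  while (beta <= beta_max) {
    # gradient of tr(W1^T P W2 P^T) wrt P
    G <- W1 %*% M %*% t(W2) + t(W1) %*% M %*% W2
    M <- exp(beta * (G - max(G)))
    for (s in seq_len(sinkhorn_sweeps)) {
      M <- M / rowSums(M)
      M <- sweep(M, 2, colSums(M), "/")
      if (max(abs(rowSums(M) - 1)) < sinkhorn_tol) break
    }
    if (max(abs(rowSums(M) - 1)) > sinkhorn_tol &&
        max(abs(colSums(M) - 1)) > sinkhorn_tol)
      warn("Sinkhorn normalization did not converge; projecting current state")
    beta <- beta * beta_rate
  }
  # project to the nearest permutation: maximize sum of selected entries
  perm_rows <- solve_assignment(max(M) - M)$assignment
  # perm_rows[i] = j means P[i, j] = 1, i.e. position i takes W2 node j
  perm <- perm_rows
  if (polish) {
    perm <- polish_2opt(W1, W2, perm)
    if (restarts > 0L) {
      best <- frobenius_objective_perm(W1, W2, perm)
      with_seed(1000003L, {
        for (r in seq_len(restarts)) {
          cand <- polish_2opt(W1, W2, sample.int(n))
          val <- frobenius_objective_perm(W1, W2, cand)
          if (val < best - 1e-12) { best <- val; perm <- cand }
        }
      })
    }
  }
  if (frobenius_objective_perm(W1, W2, perm) >
      frobenius_objective_perm(W1, W2, seq_len(n)))
    perm <- seq_len(n)
  P <- perm_to_matrix(perm)
  list(P = P, perm = perm,
       objective = frobenius_objective_perm(W1, W2, perm))
}

# first-improvement 2-opt descent over pairwise transpositions,
# lowest-index preference makes tie handling deterministic
polish_2opt <- function(W1, W2, perm) {
  n <- length(perm)
  best <- frobenius_objective_perm(W1, W2, perm)
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cand <- perm
        cand[c(i, j)] <- cand[c(j, i)]
        val <- frobenius_objective_perm(W1, W2, cand)
        if (val < best - 1e-12) {
          perm <- cand; best <- val; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  perm
}

#' Average a set of social networks by incremental matching
#'
#' Computes the average network of k node-unaligned networks: the running
#' mean M starts at the first network; each further network is aligned to the
#' current mean by [match_graphs()] and absorbed with the running-mean update
#' \eqn{M \leftarrow \frac{i-1}{i} M + \frac{1}{i} W_i^\circ}, where
#' \eqn{W_i^\circ = P W_i P^T} is the aligned copy.
#'
#' @param nets list of k square matrices (same size), or of
#'   `social_network` objects (their max-normalized weights are used).
#' @param anchor `"first"` uses the given order; `"median"` anchors on the
#'   network with median total interaction.
#' @param ... passed to [match_graphs()].
#' @return An `average_network` object: list with `M` (mean matrix), `k`,
#'   `permutations` (index form, one per input) and `order` (input order
#'   used).
#' @export
average_networks <- function(nets, anchor = c("first", "median"), ...) {
  anchor <- match.arg(anchor)
  mats <- lapply(nets, function(x) {
    if (inherits(x, "social_network")) x$weights else as.matrix(x)
  })
  k <- length(mats)
  stopifnot(k >= 1)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == n), logical(1))))
    abort("all networks must have the same size", class = "flynet_size_mismatch")
  ord <- seq_len(k)
  if (anchor == "median" && k > 1) {
    tot <- vapply(mats, sum, numeric(1))
    first <- order(abs(tot - median(tot)))[1]
    ord <- c(first, setdiff(ord, first))
  }
  M <- mats[[ord[1]]]
  perms <- vector("list", k)
  perms[[ord[1]]] <- seq_len(n)
  if (k > 1) {
    for (step in 2:k) {
      i <- ord[step]
      mt <- match_graphs(M, mats[[i]], ...)
      aligned <- mats[[i]][mt$perm, mt$perm, drop = FALSE]
      M <- (step - 1) / step * M + aligned / step
      perms[[i]] <- mt$perm
    }
  }
  structure(list(M = M, k = k, permutations = perms, order = ord),
            class = "average_network")
}

#' @export
print.average_network <- function(x, ...) {
  cat(sprintf("<average_network: mean of %d networks, %d nodes>\n",
              x$k, nrow(x$M)))
  invisible(x)
}

#' @export
tidy.average_network <- function(x, ...) {
  idx <- which(x$M != 0, arr.ind = TRUE)
  tibble(interactor_id = as.integer(idx[, 1]),
         interacted_id = as.integer(idx[, 2]),
         weight = x$M[idx]) |>
    dplyr::arrange(.data$interactor_id, .data$interacted_id)
}

#' @export
glance.average_network <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$M), total_weight = sum(x$M))
}

#' @export
autoplot.average_network <- function(object, ...) {
  n <- nrow(object$M)
  df <- tidyr::expand_grid(interactor_id = seq_len(n), interacted_id = seq_len(n))
  df$weight <- object$M[cbind(df$interactor_id, df$interacted_id)]
  ggplot2::ggplot(df, ggplot2::aes(.data$interacted_id, .data$interactor_id,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(n)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n), position = "top") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "interacted", y = "interactor", fill = "mean weight",
                  title = "Average network (matched mean adjacency)") +
    ggplot2::theme_minimal()
}
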