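# internal helpers shared across modules

# run code under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vec_norm <- function(x) sqrt(sum(x^2))

# row-wise Euclidean norm of an n x 2 matrix
rownorm <- function(m) sqrt(m[, 1]^2 + m[, 2]^2)

unit <- function(x) {
  n <- vec_norm(x)
  if (n < .Machine$double.eps) c(1, 0) else x / n
}

rot90 <- function(x) c(-x[2], x[1])

# half axes of the rendered fly ellipse for a given pixel area and aspect
ellipse_axes <- function(area, aspect = 2.5) {
  b <- sqrt(area / (pi * aspect))
  c(a = aspect * b, b = b)
}

body_length <- function(area, aspect = 2.5) 2 * ellipse_axes(area, aspect)[["a"]]

is_permutation_matrix <- function(P) {
  is.matrix(P) && nrow(P) == ncol(P) &&
    all(P %in% c(0, 1)) &&
    all(rowSums(P) == 1) && all(colSums(P) == 1)
}

perm_to_matrix <- function(perm) {
  n <- length(perm)
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), perm)] <- 1
  P
}

# %||% re-exported from rlang via imports
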