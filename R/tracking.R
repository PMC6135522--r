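#' Build the node-duplication assignment graph for one frame
#'
#' Constructs the square cost structure matching the previous frame's flies
#' to the current frame's blobs. If the frame shows fewer blobs than flies,
#' candidate merged blobs are duplicated so that the bipartite graph stays
#' square: the number of missing components is distributed over candidates in
#' proportion to their excess area (largest excess first). A blob matched by
#' several flies is a multi-fly component.
#'
#' @param prev numeric `n_flies x 2` matrix of previous fly centres.
#' @param bs a `blob_set` for the current frame.
#' @param n_flies known fly count.
#' @param typical_area single-fly area, px.
#' @param merge_factor see [flag_merged()].
#' @return list with `cost` (square matrix of Euclidean distances),
#'   `col_blob` (blob index behind each column) and `blobs` (the flagged
#'   blob set).
#' @export
build_assignment_graph <- function(prev, bs, n_flies, typical_area,
                                   merge_factor = 1.5) {
  stopifnot(nrow(prev) == n_flies)
  bs <- flag_merged(bs, n_flies, typical_area, merge_factor)
  col_blob <- rep(bs$blob, times = bs$multiplicity)
  stopifnot(length(col_blob) == n_flies)
  dx <- outer(prev[, 1], bs$x[col_blob], "-")
  dy <- outer(prev[, 2], bs$y[col_blob], "-")
  list(cost = sqrt(dx^2 + dy^2), col_blob = col_blob, blobs = bs)
}

#' Split a merged blob into individual flies with EM
#'
#' Fits a k-component Gaussian mixture to the blob's pixel coordinates,
#' with means initialised at the predicted positions of the k flies assigned
#' to the blob. Covariances are full, floored to stay non-degenerate at the
#' ~20 px body scale.
#'
#' @param pixels n x 2 matrix of 0-based pixel x, y coordinates.
#' @param k number of flies in the blob.
#' @param init_centers k x 2 matrix of initial means (the assigned flies'
#'   previous centres).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list with `centers` (k x 2), `assign` (per-pixel component index),
#'   `cov` (list of 2x2 covariance matrices).
#' @export
split_merged_blob <- function(pixels, k, init_centers, max_iter = 100L,
                              tol = 1e-4) {
  pixels <- as.matrix(pixels)
  stopifnot(k >= 1, nrow(pixels) >= k)
  if (k == 1L) {
    mu <- colMeans(pixels)
    return(list(centers = matrix(mu, 1), assign = rep(1L, nrow(pixels)),
                cov = list(cov_floored(pixels))))
  }
  fit <- em_gmm(pixels, k, as.matrix(init_centers), max_iter, tol)
  if (is.null(fit)) {
    # degenerate component: one retry from a k-means++ style seeding
    km <- kmeans(pixels, centers = k, nstart = 5)
    fit <- em_gmm(pixels, k, km$centers, max_iter, tol)
    if (is.null(fit))
      abort("EM splitting failed: empty mixture component after re-initialisation",
            class = "flynet_em_degenerate")
  }
  fit
}

cov_floored <- function(P, floor = 0.25) {
  cv <- if (nrow(P) > 1) cov(P) else diag(2) * floor
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(vals) %*% t(e$vectors)
}

em_gmm <- function(P, k, mu, max_iter, tol) {
  n <- nrow(P)
  sig <- replicate(k, diag(2) * 2, simplify = FALSE)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  dens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) dens[, j] <- w[j] * dmvnorm2(P, mu[j, ], sig[[j]])
    rs <- rowSums(dens)
    if (any(rs <= 0)) rs[rs <= 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(r[, j] * P) / nk[j]
      d <- sweep(P, 2, mu[j, ])
      cv <- crossprod(d * r[, j], d) / nk[j]
      e <- eigen(cv, symmetric = TRUE)
      sig[[j]] <- e$vectors %*% diag(pmax(e$values, 0.25)) %*% t(e$vectors)
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  hard <- max.col(dens)
  if (length(unique(hard)) < k) return(NULL)
  list(centers = mu, assign = hard, cov = sig)
}

# bivariate normal density, explicit 2x2 inverse for speed
dmvnorm2 <- function(P, mu, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  inv11 <- S[2, 2] / det; inv22 <- S[1, 1] / det; inv12 <- -S[1, 2] / det
  dx <- P[, 1] - mu[1]; dy <- P[, 2] - mu[2]
  q <- inv11 * dx^2 + 2 * inv12 * dx * dy + inv22 * dy^2
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' Re-assign fly identities to split centres
#'
#' Second assignment stage: once every component holds one fly, identities
#' are inherited by a minimum-cost perfect matching between the previous
#' centres and the current (split) centres on Euclidean distance.
#'
#' @param prev n x 2 matrix of previous centres (row i = fly i).
#' @param centers n x 2 matrix of current centres.
#' @return integer vector: `fly_id[m]` for each row of `centers`.
#' @export
assign_identities <- function(prev, centers) {
  stopifnot(nrow(prev) == nrow(centers))
  dx <- outer(prev[, 1], centers[, 1], "-")
  dy <- outer(prev[, 2], centers[, 2], "-")
  m <- solve_assignment(sqrt(dx^2 + dy^2))$assignment
  # m[i] = column (centre) taken by fly i; invert to per-centre fly id
  ids <- integer(nrow(centers))
  ids[m] <- seq_len(nrow(prev))
  ids
}

#' Resolve head and tail from the body axis and motion
#'
#' A walking fly keeps its head pointing in the direction of its motion: the
#' head is the major-axis endpoint whose direction agrees (positive dot
#' product) with the velocity smoothed over `orient_window` frames. Below
#' `speed_floor` the previous head choice is retained.
#'
#' This sweep runs over an already-tracked sequence of centres and axes.
#'
#' @param centers T x 2 matrix of one fly's centres by frame.
#' @param axes T x 2 matrix of unit body-axis vectors (sign arbitrary).
#' @param half_len T vector of body half lengths, px.
#' @param orient_window frames of velocity smoothing.
#' @param speed_floor px/frame below which orientation is held.
#' @return list of T x 2 matrices `head` and `tail`.
#' @export
update_orientation <- function(centers, axes, half_len, orient_window = 5L,
                               speed_floor = 0.2) {
  TT <- nrow(centers)
  sgn <- numeric(TT)
  v <- rbind(c(0, 0), diff(centers))
  # trailing-window smoothed velocity
  cw <- apply(v, 2, cumsum)
  smooth_v <- function(t) {
    t0 <- max(1L, t - orient_window + 1L)
    (cw[t, ] - if (t0 > 1L) cw[t0 - 1L, ] else c(0, 0)) / (t - t0 + 1L)
  }
  prev_sign <- 1
  provisional <- TRUE
  for (t in seq_len(TT)) {
    sv <- smooth_v(t)
    sp <- vec_norm(sv)
    if (sp >= speed_floor) {
      d <- sum(axes[t, ] * sv)
      prev_sign <- if (d >= 0) 1 else -1
      if (provisional && t > 1L) {
        # back-fill frames before first motion with the first informed choice
        sgn[seq_len(t - 1L)] <- resign_consistent(axes[seq_len(t), , drop = FALSE],
                                                  prev_sign)
      }
      provisional <- FALSE
    } else if (t > 1L) {
      # keep previous head: align sign with previous frame's axis direction
      agree <- sum(axes[t, ] * axes[t - 1L, ] * sgn[t - 1L])
      prev_sign <- if (agree >= 0) 1 else -1
    }
    sgn[t] <- prev_sign
  }
  u <- axes * sgn
  list(head = centers + u * half_len, tail = centers - u * half_len)
}

# propagate a sign choice made at the last row backwards through axis flips
resign_consistent <- function(axes, last_sign) {
  TT <- nrow(axes)
  s <- numeric(TT)
  s[TT] <- last_sign
  for (t in rev(seq_len(TT - 1L))) {
    agree <- sum(axes[t, ] * axes[t + 1L, ])
    s[t] <- if (agree >= 0) s[t + 1L] else -s[t + 1L]
  }
  s[-TT]
}

#' Track a fly video with a constant fly count
#'
#' The full tracker: background estimation, per-frame segmentation,
#' bipartite node-duplication assignment (Hungarian), EM splitting of
#' multi-fly components, identity re-assignment, and motion-based
#' orientation. Exactly `n_flies` states are produced for every frame - the
#' defining constant-count property. If the video starts mid-occlusion, the
#' first frame showing `n_flies` separated blobs anchors the tracker and
#' earlier frames are tracked backwards.
#'
#' @param frames a `frame_source`.
#' @param n_flies known number of flies.
#' @param threshold segmentation threshold, `"otsu"` or grey levels.
#' @param typical_area single-fly area; estimated from clean frames if NULL.
#' @param merge_factor area factor flagging merged blobs.
#' @param min_area noise floor for components, px.
#' @param orient_window,speed_floor see [update_orientation()].
#' @param background optional precomputed background image.
#' @return A `fly_tracks` tibble: one row per (frame, fly_id) with centre
#'   (`cx`, `cy`), head (`hx`, `hy`), tail (`tx`, `ty`) and `speed`
#'   (px/frame). Attributes: `n_flies`, `typical_area`, `threshold`,
#'   `anchor_frame`.
#' @export
track_video <- function(frames, n_flies, threshold = "otsu",
                        typical_area = NULL, merge_factor = 1.5,
                        min_area = 4L, orient_window = 5L, speed_floor = 0.2,
                        background = NULL) {
  stopifnot(inherits(frames, "frame_source"), n_flies >= 1)
  TT <- frames$n_frames
  bg <- background %||% build_background(frames)

  if (identical(threshold, "otsu")) {
    # one threshold for the whole video: lighting is static, and a per-frame
    # threshold would let a frame with no flies segment its own noise
    threshold <- otsu_threshold(abs(frames$get(0L) - bg))
  }
  seg <- function(t) segment_frame(frames$get(t), bg, threshold = threshold,
                                   min_area = min_area, frame_index = t)

  # pass over a sample of frames for the typical area and the anchor frame
  anchor <- NA_integer_
  areas_src <- list()
  probe <- unique(c(0L, seq(0L, TT - 1L, by = max(1L, TT %/% 60L))))
  for (t in probe) {
    b <- seg(t)
    if (nrow(b) == n_flies) {
      areas_src[[length(areas_src) + 1L]] <- b
      if (is.na(anchor)) anchor <- t
    }
  }
  if (is.na(anchor)) {
    for (t in setdiff(0:(TT - 1L), probe)) {  # exhaustive fallback
      b <- seg(t)
      if (nrow(b) == n_flies) { anchor <- t; areas_src <- list(b); break }
    }
  }
  if (is.na(anchor))
    abort("no frame with all flies separated; cannot anchor the tracker",
          class = "flynet_no_anchor")
  if (is.null(typical_area)) typical_area <- estimate_fly_area(areas_src, n_flies)

  CX <- matrix(NA_real_, TT, n_flies); CY <- CX
  AX <- matrix(NA_real_, TT, n_flies); AY <- CX
  HL <- matrix(NA_real_, TT, n_flies)

  b0 <- seg(anchor)
  CX[anchor + 1L, ] <- b0$x; CY[anchor + 1L, ] <- b0$y
  AX[anchor + 1L, ] <- b0$axis_x; AY[anchor + 1L, ] <- b0$axis_y
  HL[anchor + 1L, ] <- b0$axis_half

  step <- function(prev, bs) {
    g <- build_assignment_graph(prev, bs, n_flies, typical_area, merge_factor)
    m <- solve_assignment(g$cost)$assignment
    blob_of_fly <- g$col_blob[m]
    centers <- matrix(NA_real_, n_flies, 2)
    axes <- matrix(NA_real_, n_flies, 2)
    hl <- numeric(n_flies)
    for (b in unique(blob_of_fly)) {
      flies <- which(blob_of_fly == b)
      k <- length(flies)
      row <- which(g$blobs$blob == b)
      if (k == 1L) {
        centers[flies, ] <- c(g$blobs$x[row], g$blobs$y[row])
        axes[flies, ] <- c(g$blobs$axis_x[row], g$blobs$axis_y[row])
        hl[flies] <- g$blobs$axis_half[row]
      } else {
        sp <- split_merged_blob(g$blobs$pixels[[row]], k,
                                prev[flies, , drop = FALSE])
        centers[flies, ] <- sp$centers
        for (idx in seq_len(k)) {
          e <- eigen(sp$cov[[idx]], symmetric = TRUE)
          axes[flies[idx], ] <- e$vectors[, 1]
          hl[flies[idx]] <- 2 * sqrt(max(e$values[1], 0.0625))
        }
      }
    }
    ids <- assign_identities(prev, centers)
    ord <- order(ids)
    list(centers = centers[ord, , drop = FALSE], axes = axes[ord, , drop = FALSE],
         hl = hl[ord])
  }

  run_dir <- function(from, to, by) {
    prev <- cbind(CX[from + 1L, ], CY[from + 1L, ])
    if (from == to) return(invisible())
    for (t in seq(from + by, to, by = by)) {
      s <- step(prev, seg(t))
      CX[t + 1L, ] <<- s$centers[, 1]; CY[t + 1L, ] <<- s$centers[, 2]
      AX[t + 1L, ] <<- s$axes[, 1]; AY[t + 1L, ] <<- s$axes[, 2]
      HL[t + 1L, ] <<- s$hl
      prev <- s$centers
    }
  }
  run_dir(anchor, TT - 1L, 1L)
  if (anchor > 0L) run_dir(anchor, 0L, -1L)

  # orientation sweep in forward time
  out <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    ctr <- cbind(CX[, i], CY[, i])
    o <- update_orientation(ctr, cbind(AX[, i], AY[, i]), HL[, i],
                            orient_window, speed_floor)
    sp <- c(0, rownorm(diff(ctr)))
    out[[i]] <- tibble(frame = 0:(TT - 1L), fly_id = i,
                       cx = ctr[, 1], cy = ctr[, 2],
                       hx = o$head[, 1], hy = o$head[, 2],
                       tx = o$tail[, 1], ty = o$tail[, 2],
                       speed = sp)
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$fly_id)
  attr(res, "n_flies") <- n_flies
  attr(res, "typical_area") <- typical_area
  attr(res, "threshold") <- threshold
  attr(res, "anchor_frame") <- anchor
  class(res) <- c("fly_tracks", class(res))
  res
}

#' Total walking distance
#'
#' Per-fly sum of Euclidean centre displacements over consecutive frames,
#' the locomotor-activity measure reported alongside the network parameters.
#'
#' @param tracks a trajectory table with `frame`, `fly_id`, `cx`, `cy`.
#' @return tibble (fly_id, distance) with attribute `total` (group sum).
#' @export
total_walking_distance <- function(tracks) {
  out <- tracks |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(distance = sum(sqrt(diff(.data$cx)^2 + diff(.data$cy)^2)),
                     .groups = "drop")
  attr(out, "total") <- sum(out$distance)
  out
}

#' @export
autoplot.fly_tracks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$cx, .data$cy,
                                       colour = factor(.data$fly_id),
                                       group = .data$fly_id)) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Fly trajectories (image coordinates)") +
    ggplot2::theme_minimal()
}
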