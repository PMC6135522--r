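#' Estimate the static background of an arena video
#'
#' Computes the per-pixel temporal median over a sample of frames. With
#' bright flies moving over a dark static arena, the median removes the
#' flies and recovers the empty-arena image.
#'
#' @param frames a `frame_source` (see [render_frames()], [frames_from_array()]).
#' @param sample_stride sample every `sample_stride`-th frame; must leave at
#'   least 2 sampled frames.
#' @param max_samples cap on the number of sampled frames.
#' @return numeric matrix of grey levels, same size as the frames.
#' @export
build_background <- function(frames, sample_stride = NULL, max_samples = 9L) {
  stopifnot(inherits(frames, "frame_source"))
  TT <- frames$n_frames
  if (TT == 1L) {
    warn("single-frame video: using the frame itself as background; segment with a global threshold")
    return(frames$get(0L))
  }
  stride <- sample_stride %||% max(1L, TT %/% max_samples)
  if (stride >= TT)
    abort("sample_stride leaves fewer than 2 sampled frames",
          class = "flynet_invalid_config")
  idx <- seq(0L, TT - 1L, by = stride)
  if (length(idx) > max_samples)
    idx <- idx[round(seq(1, length(idx), length.out = max_samples))]
  cols <- lapply(idx, function(t) as.vector(frames$get(t)))
  matrix(vec_median(cols), frames$height, frames$width)
}

# exact per-position median of a list of equal-length vectors, computed by a
# pmin/pmax exchange network (a per-pixel median() call would dominate the
# whole tracking run)
vec_median <- function(cols) {
  k <- length(cols)
  if (k == 1L) return(cols[[1]])
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      a <- cols[[j]]; b <- cols[[j + 1L]]
      lo <- pmin(a, b)
      cols[[j]] <- lo
      cols[[j + 1L]] <- a + b - lo
    }
  }
  if (k %% 2L) cols[[(k + 1L) %/% 2L]]
  else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' Segment one frame into fly-candidate blobs
#'
#' Foreground = pixels whose absolute difference from the background exceeds
#' `threshold`; 8-connected components smaller than `min_area` pixels are
#' discarded as sensor noise.
#'
#' @param frame,background numeric matrices of identical shape.
#' @param threshold grey-level threshold; `"otsu"` (default) picks it from
#'   the difference-image histogram.
#' @param min_area minimum component area kept, px.
#' @return A `blob_set`: tibble with columns `blob` (index), `x`, `y`
#'   (centroid), `area`, `axis_x`, `axis_y` (major-axis unit vector),
#'   `axis_half` (half length of the body along the major axis, px) and
#'   `pixels` (list column of n x 2 matrices of 0-based x, y pixel
#'   coordinates), plus attributes `frame_index` and `threshold`.
#' @export
segment_frame <- function(frame, background, threshold = "otsu", min_area = 4L,
                          frame_index = NA_integer_) {
  stopifnot(identical(dim(frame), dim(background)))
  d <- abs(frame - background)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(d) else threshold
  H <- nrow(d); W <- ncol(d)
  idx <- which(d > thr)
  comp <- components8(idx, H)
  blob_table(idx, comp, H, min_area, thr, frame_index)
}

# Otsu's threshold on the difference-image histogram (256 grey-level bins)
otsu_threshold <- function(d) {
  v <- pmin(pmax(round(as.vector(d)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  which.max(sb2) - 1L
}

# 8-connected components over the sparse foreground pixel set: the frame is
# almost entirely background, so adjacency is resolved by index matching on
# the foreground pixels alone rather than by labelling the whole image
components8 <- function(idx, H) {
  n <- length(idx)
  if (!n) return(integer())
  r <- (idx - 1L) %% H
  from <- integer(); to <- integer()
  for (off in c(1L, H, H + 1L, H - 1L)) {
    sel <- if (off == 1L || off == H + 1L) r < H - 1L
           else if (off == H - 1L) r > 0L
           else rep(TRUE, n)
    m <- match(idx[sel] + off, idx)
    hit <- !is.na(m)
    from <- c(from, which(sel)[hit])
    to <- c(to, m[hit])
  }
  if (!length(from)) return(seq_len(n))
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  unname(igraph::components(g)$membership)
}

# assemble the blob tibble from per-pixel component ids
blob_table <- function(idx, comp, H, min_area, thr, frame_index) {
  if (length(idx)) {
    x <- (idx - 1L) %/% H
    y <- (idx - 1L) %% H
    area <- tabulate(comp)
    keep <- which(area >= min_area)
  } else keep <- integer()
  if (!length(keep)) {
    out <- tibble(blob = integer(), x = numeric(), y = numeric(),
                  area = integer(), axis_x = numeric(), axis_y = numeric(),
                  axis_half = numeric(), pixels = list())
    attr(out, "frame_index") <- frame_index
    attr(out, "threshold") <- thr
    class(out) <- c("blob_set", class(out))
    return(out)
  }
  sel <- comp %in% keep
  x <- x[sel]; y <- y[sel]
  comp <- match(comp[sel], keep)
  k <- length(keep)
  area <- tabulate(comp, nbins = k)
  cx <- as.vector(rowsum(x, comp)) / area
  cy <- as.vector(rowsum(y, comp)) / area
  px <- split.data.frame(cbind(x = x, y = y), comp)
  axes <- matrix(0, k, 3)
  for (b in seq_len(k)) {
    P <- px[[b]]
    if (nrow(P) < 2) { axes[b, ] <- c(1, 0, 0.5); next }
    cv <- cov(P)
    e <- eigen(cv, symmetric = TRUE)
    # uniform ellipse: variance along the major axis = a^2 / 4
    axes[b, ] <- c(e$vectors[1, 1], e$vectors[2, 1],
                   2 * sqrt(max(e$values[1], 0.0625)))
  }
  out <- tibble(blob = seq_len(k), x = cx, y = cy, area = as.integer(area),
                axis_x = axes[, 1], axis_y = axes[, 2], axis_half = axes[, 3],
                pixels = unname(px))
  attr(out, "frame_index") <- frame_index
  attr(out, "threshold") <- thr
  class(out) <- c("blob_set", class(out))
  out
}

#' Estimate the typical single-fly blob area
#'
#' Median area over all blobs in frames whose blob count equals the known
#' number of flies (frames with no merged detections).
#'
#' @param blobsets list of `blob_set`s.
#' @param n_flies known fly count.
#' @return estimated single-fly area, px.
#' @export
estimate_fly_area <- function(blobsets, n_flies) {
  clean <- purrr::keep(blobsets, ~ nrow(.x) == n_flies)
  if (!length(clean))
    abort(paste0("no frame shows ", n_flies, " separated flies; ",
                 "supply a typical single-fly area manually"),
          class = "flynet_no_clean_frame")
  median(unlist(purrr::map(clean, "area")))
}

#' Flag candidate merged (multi-fly) blobs
#'
#' When a frame shows fewer blobs than flies, blobs whose area exceeds
#' `merge_factor` times the typical single-fly area are candidates for
#' containing several flies. Multiplicities returned here are provisional:
#' final per-blob fly counts come from the tracking assignment.
#'
#' @param bs a `blob_set`.
#' @param n_flies known fly count.
#' @param typical_area single-fly area, px (see [estimate_fly_area()]).
#' @param merge_factor area factor above which a blob is a merge candidate.
#' @return `bs` with columns `candidate` (logical) and `multiplicity`
#'   (provisional integer fly count).
#' @export
flag_merged <- function(bs, n_flies, typical_area, merge_factor = 1.5) {
  stopifnot(typical_area > 0)
  if (nrow(bs) > n_flies) {
    warn(sprintf("frame %s: %d blobs for %d flies; keeping the %d largest",
                 attr(bs, "frame_index"), nrow(bs), n_flies, n_flies))
    bs <- bs[order(bs$area, decreasing = TRUE)[seq_len(n_flies)], ]
    bs <- bs[order(bs$blob), ]
    bs$blob <- seq_len(nrow(bs))
    class(bs) <- unique(c("blob_set", class(bs)))
  }
  bs$candidate <- bs$area > merge_factor * typical_area
  bs$multiplicity <- 1L
  missing <- n_flies - nrow(bs)
  if (missing > 0L) {
    bs$multiplicity <- distribute_duplicates(bs$area, bs$candidate,
                                             missing, typical_area)
  } else {
    bs$candidate <- FALSE
  }
  bs
}

# Distribute `missing` duplicate slots greedily by residual excess area:
# each duplicate goes to the blob whose area most exceeds its current
# multiplicity's worth of typical fly area (ties by larger area, then lower
# blob index). Candidates (area test) get duplicates first in the natural
# course; if the area test failed for some truly merged blob, count
# conservation still places the duplicate on the most oversized blob.
distribute_duplicates <- function(area, candidate, missing, typical_area) {
  mult <- rep(1L, length(area))
  if (!any(candidate))
    warn("blob count below fly count but no blob passes the merged-area test; duplicating the most oversized blobs")
  for (k in seq_len(missing)) {
    resid <- area - mult * typical_area
    b <- order(-resid, -area, seq_along(area))[1]
    mult[b] <- mult[b] + 1L
  }
  mult
}
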