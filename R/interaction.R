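#' Extract the 22 temporal pair features for one frame
#'
#' For an ordered pair (interactor i, interacted j) at frame t, the feature
#' vector holds 11 inter-fly distances - the Euclidean distance from i's head
#' to j's tail at each of the 11 frames t-5..t+5 - followed by 11 relative
#' displacements of the interactor: the magnitude of i's offset from its
#' window-centre position, expressed in a coordinate frame translated to j's
#' concurrent position, at the same 11 frames (the t+0 entry is 0 by
#' construction).
#'
#' @param tracks trajectory table (frame, fly_id, cx, cy, hx, hy, tx, ty).
#' @param i,j interactor and interacted fly ids.
#' @param t centre frame; frames t-5..t+5 must all exist.
#' @return numeric vector of length 22.
#' @export
extract_features <- function(tracks, i, j, t) {
  pf <- pair_features(tracks, tibble(interactor_id = i, interacted_id = j, frame = t))
  as.numeric(pf[1, ])
}

# Vectorised feature computation for many (i, j, t) candidates at once.
# Returns a numeric matrix, one row per candidate, 22 columns.
pair_features <- function(tracks, cand, half_window = 5L) {
  stopifnot(all(c("interactor_id", "interacted_id", "frame") %in% names(cand)))
  frames <- sort(unique(tracks$frame))
  t0 <- min(frames); t1 <- max(frames)
  if (any(cand$frame - half_window < t0 | cand$frame + half_window > t1))
    abort("feature window extends outside the video; drop boundary frames",
          class = "flynet_window")
  n_flies <- max(tracks$fly_id)
  TT <- t1 - t0 + 1L
  ord <- order(tracks$fly_id, tracks$frame)
  grab <- function(col) matrix(tracks[[col]][ord], nrow = TT) # frame x fly
  HX <- grab("hx"); HY <- grab("hy")
  TX <- grab("tx"); TY <- grab("ty")
  CX <- grab("cx"); CY <- grab("cy")
  n <- nrow(cand)
  out <- matrix(NA_real_, n, 2L * (2L * half_window + 1L))
  ri <- cand$interactor_id; rj <- cand$interacted_id
  base <- cand$frame - t0 + 1L
  # window-centre relative offset of i in j's translated frame
  ox0 <- CX[cbind(base, ri)] - CX[cbind(base, rj)]
  oy0 <- CY[cbind(base, ri)] - CY[cbind(base, rj)]
  for (w in -half_window:half_window) {
    k <- base + w
    ii <- cbind(k, ri); jj <- cbind(k, rj)
    out[, w + half_window + 1L] <-
      sqrt((HX[ii] - TX[jj])^2 + (HY[ii] - TY[jj])^2)
    out[, w + 3L * half_window + 2L] <-
      sqrt((CX[ii] - CX[jj] - ox0)^2 + (CY[ii] - CY[jj] - oy0)^2)
  }
  out
}

#' Build a balanced touch/no-touch training table
#'
#' Samples labelled single-frame touch events and no-touch events from a
#' trajectory table with ground-truth (or expert) frame labels. No-touch
#' examples mix gated near-miss pairs (within `candidate_radius`) with
#' random far pairs, mirroring what the classifier will see at prediction
#' time.
#'
#' @param tracks trajectory table.
#' @param labels tibble (frame, interactor_id, interacted_id) of positive
#'   frames.
#' @param n_per_class examples per class.
#' @param candidate_radius px radius for near-miss negatives.
#' @param seed RNG seed.
#' @return tibble (interactor_id, interacted_id, frame, label) with label
#'   1 = touch, 0 = no touch.
#' @export
build_touch_training <- function(tracks, labels, n_per_class = 1000L,
                                 candidate_radius = NULL, seed = 1L) {
  half_window <- 5L
  t0 <- min(tracks$frame); t1 <- max(tracks$frame)
  ok <- labels$frame - half_window >= t0 & labels$frame + half_window <= t1
  pos <- labels[ok, c("frame", "interactor_id", "interacted_id")]
  if (!nrow(pos)) abort("no usable positive frames", class = "flynet_no_positives")
  candidate_radius <- candidate_radius %||% (3 * guess_body_length(tracks))
  with_seed(seed, {
    pos <- pos[sample.int(nrow(pos), min(n_per_class, nrow(pos)), replace = FALSE), ]
    if (nrow(pos) < n_per_class)
      pos <- pos[sample.int(nrow(pos), n_per_class, replace = TRUE), ]
    neg <- sample_negatives(tracks, labels, n_per_class, candidate_radius,
                            half_window)
    dplyr::bind_rows(
      dplyr::mutate(pos, label = 1L),
      dplyr::mutate(neg, label = 0L)
    )
  })
}

guess_body_length <- function(tracks) {
  median(sqrt((tracks$hx - tracks$tx)^2 + (tracks$hy - tracks$ty)^2))
}

sample_negatives <- function(tracks, labels, n, candidate_radius, half_window) {
  t0 <- min(tracks$frame); t1 <- max(tracks$frame)
  n_flies <- max(tracks$fly_id)
  key <- function(f, i, j) paste(f, i, j)
  pos_key <- key(labels$frame, labels$interactor_id, labels$interacted_id)
  # gated near-miss candidates from a subsample of frames
  frames_try <- sample(seq(t0 + half_window, t1 - half_window),
                       min(400L, t1 - t0 - 2L * half_window + 1L))
  gated <- candidate_pairs(tracks, frames_try, candidate_radius)
  gated <- gated[!key(gated$frame, gated$interactor_id, gated$interacted_id) %in% pos_key, ]
  take_gated <- min(nrow(gated), n %/% 2L)
  out <- gated[sample.int(nrow(gated), take_gated), ]
  # fill with random pairs/frames
  need <- n - take_gated
  got <- 0L; fill <- list()
  while (got < need) {
    m <- (need - got) * 2L
    cand <- tibble(
      frame = sample(seq(t0 + half_window, t1 - half_window), m, replace = TRUE),
      interactor_id = sample.int(n_flies, m, replace = TRUE),
      interacted_id = sample.int(n_flies, m, replace = TRUE)
    )
    cand <- cand[cand$interactor_id != cand$interacted_id, ]
    cand <- cand[!key(cand$frame, cand$interactor_id, cand$interacted_id) %in% pos_key, ]
    if (nrow(cand)) {
      fill[[length(fill) + 1L]] <- cand
      got <- got + nrow(cand)
    }
  }
  dplyr::bind_rows(out, dplyr::bind_rows(fill)[seq_len(need), ])
}

# ordered pairs whose head-to-tail distance is within the gating radius
candidate_pairs <- function(tracks, frames, candidate_radius) {
  sub <- tracks[tracks$frame %in% frames, ]
  joined <- dplyr::inner_join(
    dplyr::select(sub, frame = "frame", interactor_id = "fly_id", hx = "hx", hy = "hy"),
    dplyr::select(sub, frame = "frame", interacted_id = "fly_id", tx = "tx", ty = "ty"),
    by = "frame", relationship = "many-to-many"
  )
  joined <- joined[joined$interactor_id != joined$interacted_id, ]
  d <- sqrt((joined$hx - joined$tx)^2 + (joined$hy - joined$ty)^2)
  joined[d <= candidate_radius, c("frame", "interactor_id", "interacted_id")]
}

#' Train the single-frame touch classifier
#'
#' Fits a radial-basis support vector machine on the 22 temporal features.
#' Features are z-scored from the training set (the standardisation constants
#' travel with the model). Hyperparameters are chosen by 5-fold
#' cross-validation over a small grid unless `tune = FALSE`.
#'
#' @param tracks trajectory table the examples refer to.
#' @param training tibble from [build_touch_training()] (columns
#'   interactor_id, interacted_id, frame, label).
#' @param tune logical; cross-validate over a small cost/gamma grid.
#' @param seed RNG seed (cross-validation folds, SVM internals).
#' @return A `touch_classifier` object.
#' @export
train_touch_classifier <- function(tracks, training, tune = TRUE, seed = 1L) {
  stopifnot(all(c("interactor_id", "interacted_id", "frame", "label") %in% names(training)))
  y <- factor(training$label, levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L)
    abort("training data must contain both classes", class = "flynet_one_class")
  X <- pair_features(tracks, training)
  colnames(X) <- feature_names()
  # the t+0 displacement entry is 0 by construction; z-scale the rest
  scale_cols <- apply(X, 2, stats::sd) > 0
  with_seed(seed, {
    if (tune) {
      grid <- expand.grid(cost = c(1, 10), gamma = c(0.01, 1 / ncol(X), 0.2))
      acc <- vapply(seq_len(nrow(grid)), function(r) {
        fit <- e1071::svm(X, y, kernel = "radial", cost = grid$cost[r],
                          gamma = grid$gamma[r], scale = scale_cols, cross = 5)
        fit$tot.accuracy
      }, numeric(1))
      best <- grid[which.max(acc), ]
    } else {
      best <- data.frame(cost = 1, gamma = 1 / ncol(X))
    }
    fit <- e1071::svm(X, y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = scale_cols)
    structure(list(svm = fit, cost = best$cost, gamma = best$gamma,
                   n_features = ncol(X), n_train = nrow(X)),
              class = "touch_classifier")
  })
}

feature_names <- function(half_window = 5L) {
  w <- -half_window:half_window
  c(paste0("dist_t", ifelse(w >= 0, "+", ""), w),
    paste0("disp_t", ifelse(w >= 0, "+", ""), w))
}

#' @export
print.touch_classifier <- function(x, ...) {
  cat(sprintf("<touch_classifier: RBF SVM, %d features, %d training frames, cost=%g, gamma=%g>\n",
              x$n_features, x$n_train, x$cost, x$gamma))
  invisible(x)
}

#' @export
glance.touch_classifier <- function(x, ...) {
  tibble(n_train = x$n_train, n_features = x$n_features,
         cost = x$cost, gamma = x$gamma,
         n_support_vectors = nrow(x$svm$SV))
}

#' Predict touch labels for a table of candidate frames
#' @param object a `touch_classifier`.
#' @param tracks trajectory table.
#' @param candidates tibble (interactor_id, interacted_id, frame).
#' @param ... unused.
#' @return integer vector of 0/1 labels.
#' @export
predict.touch_classifier <- function(object, tracks, candidates, ...) {
  if (!nrow(candidates)) return(integer())
  X <- pair_features(tracks, candidates)
  colnames(X) <- feature_names()
  as.integer(as.character(predict(object$svm, X)))
}

#' Classify every frame of a tracked video for touch events
#'
#' Scores ordered fly pairs per frame with the trained classifier. For
#' tractability only pairs whose head-to-tail distance is within
#' `candidate_radius` (default 3 body lengths) are scored; all other ordered
#' pairs are no-touch by definition of the gate.
#'
#' @param model a `touch_classifier`.
#' @param tracks trajectory table.
#' @param candidate_radius gating radius in px; `NULL` = 3 body lengths
#'   estimated from the tracks. `Inf` disables gating.
#' @return tibble (frame, interactor_id, interacted_id) of frames classified
#'   as touch events (sparse true set).
#' @export
classify_frames <- function(model, tracks, candidate_radius = NULL) {
  stopifnot(inherits(model, "touch_classifier"))
  half_window <- 5L
  t0 <- min(tracks$frame); t1 <- max(tracks$frame)
  frames <- seq(t0 + half_window, t1 - half_window)
  if (!length(frames))
    return(tibble(frame = integer(), interactor_id = integer(),
                  interacted_id = integer()))
  radius <- candidate_radius %||% (3 * guess_body_length(tracks))
  cand <- candidate_pairs(tracks, frames, radius)
  if (!nrow(cand)) return(cand)
  lab <- predict(model, tracks, cand)
  cand[lab == 1L, ]
}

#' Extract touch interactions from frame-level labels
#'
#' Applies the run-length rules that turn single-frame touch events into
#' touch interactions: for each ordered pair, runs of touch frames separated
#' by gaps shorter than `min_gap` frames are merged first (a flickering
#' classifier output is one sustained touch), then merged runs shorter than
#' `min_run` frames are dropped.
#'
#' @param frame_labels tibble (frame, interactor_id, interacted_id) of touch
#'   frames, e.g. from [classify_frames()].
#' @param min_run minimum interaction duration, frames (~0.5 s at 30 fps).
#' @param min_gap minimum separation between distinct interactions, frames.
#' @return tibble (interactor_id, interacted_id, start_frame, end_frame),
#'   end inclusive, ordered by pair then start.
#' @export
extract_interactions <- function(frame_labels, min_run = 15L, min_gap = 15L) {
  empty <- tibble(interactor_id = integer(), interacted_id = integer(),
                  start_frame = integer(), end_frame = integer())
  if (!nrow(frame_labels)) return(empty)
  frame_labels |>
    dplyr::distinct(.data$interactor_id, .data$interacted_id, .data$frame) |>
    dplyr::group_by(.data$interactor_id, .data$interacted_id) |>
    dplyr::reframe(runs_from_frames(sort(.data$frame), min_run, min_gap)) |>
    dplyr::arrange(.data$interactor_id, .data$interacted_id, .data$start_frame)
}

runs_from_frames <- function(f, min_run, min_gap) {
  brk <- which(diff(f) > min_gap)          # gaps >= min_gap split; smaller merge
  start <- f[c(1L, brk + 1L)]
  end <- f[c(brk, length(f))]
  keep <- (end - start + 1L) >= min_run
  tibble(start_frame = start[keep], end_frame = end[keep])
}
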