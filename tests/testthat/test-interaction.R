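# small deterministic trajectory builders ---------------------------------

# fly i moving at constant velocity, fly j stationary; long enough for any
# 11-frame window
two_fly_tracks <- function(vi = c(2, 0), pj = c(50, 10), frames = 0:20) {
  a <- 4   # half body length
  dplyr::bind_rows(
    tibble::tibble(frame = frames, fly_id = 1,
                   cx = 10 + vi[1] * frames, cy = 10 + vi[2] * frames,
                   hx = cx + a, hy = cy, tx = cx - a, ty = cy),
    tibble::tibble(frame = frames, fly_id = 2,
                   cx = pj[1], cy = pj[2],
                   hx = pj[1] + a, hy = pj[2], tx = pj[1] - a, ty = pj[2])
  )
}

test_that("feature vectors have length 22 with a zero centre displacement entry", {
  tk <- two_fly_tracks()
  f <- extract_features(tk, 1, 2, 10)
  expect_length(f, 22)
  expect_equal(f[17], 0)    # the t+0 relative-displacement entry
  expect_true(all(f[1:11] >= 0))
})

test_that("features match hand computation for constant-velocity motion", {
  v <- c(2, 0)
  tk <- two_fly_tracks(vi = v)
  t0 <- 10
  f <- extract_features(tk, 1, 2, t0)
  a <- 4
  for (w in -5:5) {
    head_x <- 10 + v[1] * (t0 + w) + a
    tail_x <- 50 - a
    expect_equal(f[w + 6], abs(head_x - tail_x))      # head-to-tail distance
    expect_equal(f[w + 17], abs(w) * sqrt(sum(v^2)))  # relative displacement
  }
})

test_that("coincident stationary head and tail give an all-zero distance block", {
  a <- 4
  frames <- 0:14
  tk <- dplyr::bind_rows(
    tibble::tibble(frame = frames, fly_id = 1, cx = 20, cy = 10,
                   hx = 24, hy = 10, tx = 16, ty = 10),
    tibble::tibble(frame = frames, fly_id = 2, cx = 28, cy = 10,
                   hx = 32, hy = 10, tx = 24, ty = 10)
  )
  f <- extract_features(tk, 1, 2, 7)  # fly 1 head at fly 2 tail
  expect_equal(f, rep(0, 22))
})

test_that("windows truncated by the video boundary are rejected", {
  tk <- two_fly_tracks(frames = 0:12)
  expect_error(extract_features(tk, 1, 2, 3), class = "flynet_window")
  expect_error(extract_features(tk, 1, 2, 10), class = "flynet_window")
  expect_silent(extract_features(tk, 1, 2, 6))
})

test_that("run rules: 14-frame runs are dropped, 15-frame runs kept", {
  mk <- function(frames) tibble::tibble(frame = frames, interactor_id = 1,
                                        interacted_id = 2)
  expect_equal(nrow(extract_interactions(mk(0:13))), 0)
  one <- extract_interactions(mk(0:14))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_frame, 0)
  expect_equal(one$end_frame, 14)
})

test_that("run rules: a 14-frame gap merges two runs, a 15-frame gap splits them", {
  mk <- function(frames) tibble::tibble(frame = frames, interactor_id = 1,
                                        interacted_id = 2)
  merged <- extract_interactions(mk(c(0:14, 29:43)))   # gap of 14 frames
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end_frame, 43)
  split <- extract_interactions(mk(c(0:14, 30:44)))    # gap of 15 frames
  expect_equal(nrow(split), 2)
})

test_that("extraction matches a run-length oracle on random boolean series", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      horizon <- 400L
      frames <- sort(sample(0:horizon, 150))
      got <- extract_interactions(tibble::tibble(frame = frames,
                                                 interactor_id = 3,
                                                 interacted_id = 7))
      want <- oracle_interactions(frames, horizon, 15L, 15L)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start_frame, want$start_frame)
        expect_equal(got$end_frame, want$end_frame)
      }
      # idempotence: re-extracting the covered frames returns the same runs
      if (nrow(got)) {
        cover <- unlist(purrr::map2(got$start_frame, got$end_frame, seq))
        again <- extract_interactions(tibble::tibble(frame = cover,
                                                     interactor_id = 3,
                                                     interacted_id = 7))
        expect_equal(again$start_frame, got$start_frame)
        expect_equal(again$end_frame, got$end_frame)
      }
    }
  })
})

test_that("ordered pairs are independent: i->j labels do not imply j->i", {
  lab <- tibble::tibble(frame = 0:19, interactor_id = 1, interacted_id = 2)
  res <- extract_interactions(lab)
  expect_equal(nrow(res), 1)
  expect_equal(res$interactor_id, 1)
  expect_equal(nrow(res[res$interactor_id == 2, ]), 0)
})

# fly 1 alternates between sitting head-to-tail behind fly 2 (40-frame
# blocks) and sitting far away; labels follow the geometry
blockwise_tracks <- function(n_frames = 800) {
  frames <- 0:(n_frames - 1)
  near <- (frames %/% 40) %% 2 == 1
  a <- 4
  cx1 <- ifelse(near, 90, 30)
  dplyr::bind_rows(
    tibble::tibble(frame = frames, fly_id = 1, cx = cx1, cy = 50,
                   hx = cx1 + a, hy = 50, tx = cx1 - a, ty = 50),
    tibble::tibble(frame = frames, fly_id = 2, cx = 100, cy = 50,
                   hx = 104, hy = 50, tx = 96, ty = 50)
  )
}

block_interior <- function(n_frames = 800) {
  frames <- 0:(n_frames - 1)
  frames[frames %% 40 >= 15 & frames %% 40 <= 25]
}

test_that("classifier separates geometrically distinct classes; one class errors", {
  tk <- blockwise_tracks()
  cand <- tibble::tibble(frame = block_interior(),
                         interactor_id = 1, interacted_id = 2,
                         label = as.integer((block_interior() %/% 40) %% 2 == 1))
  model <- train_touch_classifier(tk, cand, tune = FALSE, seed = 2)
  pred <- predict(model, tk, cand)
  expect_equal(mean(pred == cand$label), 1)
  expect_error(train_touch_classifier(tk, dplyr::mutate(cand, label = 1L)),
               class = "flynet_one_class")
})

test_that("permuted labels give chance-level held-out accuracy", {
  withr::with_seed(31, {
    tk <- blockwise_tracks(1600)
    fr <- block_interior(1600)
    cand <- tibble::tibble(frame = fr, interactor_id = 1, interacted_id = 2,
                           label = sample(rep(0:1, length.out = length(fr))))
    split <- sample(c(TRUE, FALSE), nrow(cand), replace = TRUE)
    model <- train_touch_classifier(tk, cand[split, ], tune = FALSE, seed = 3)
    pred <- predict(model, tk, cand[!split, ])
    acc <- mean(pred == cand$label[!split])
    expect_gt(acc, 0.35)
    expect_lt(acc, 0.65)
  })
})

test_that("gating: distant pairs are never scored as touches", {
  tk <- blockwise_tracks()
  cand <- tibble::tibble(frame = block_interior(),
                         interactor_id = 1, interacted_id = 2,
                         label = as.integer((block_interior() %/% 40) %% 2 == 1))
  model <- train_touch_classifier(tk, cand, tune = FALSE, seed = 4)
  hits <- classify_frames(model, tk, candidate_radius = 24)
  # far blocks are outside the gate and can never be scored as touches
  expect_true(all((hits$frame %/% 40) %% 2 == 1))
  # the planted direction is recovered in the near blocks
  near_int <- block_interior()[(block_interior() %/% 40) %% 2 == 1]
  found <- hits[hits$interactor_id == 1, ]
  expect_gt(mean(near_int %in% found$frame), 0.9)
})
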