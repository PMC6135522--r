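test_that("EM splitting: k = 1 returns the centroid; partitions conserve pixels", {
  withr::with_seed(1, {
    px <- cbind(x = round(runif(40, 0, 10)), y = round(runif(40, 0, 10)))
    s1 <- split_merged_blob(px, 1, matrix(c(5, 5), 1))
    expect_equal(s1$centers[1, ], colMeans(px), ignore_attr = TRUE)
    expect_equal(s1$assign, rep(1L, 40))
  })
})

test_that("EM splitting separates two lightly overlapping bodies", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      c1 <- c(10, 10); c2 <- c(17, 11)   # ~1 body length apart
      e1 <- cbind(rnorm(30, c1[1], 1.6), rnorm(30, c1[2], 1.2))
      e2 <- cbind(rnorm(30, c2[1], 1.6), rnorm(30, c2[2], 1.2))
      px <- rbind(e1, e2)
      sp <- split_merged_blob(px, 2, rbind(c1, c2) + rnorm(4, 0, 0.5))
      expect_equal(length(sp$assign), 60)
      d <- sqrt(rowSums((sp$centers - rbind(c1, c2))^2))
      dswap <- sqrt(rowSums((sp$centers - rbind(c2, c1))^2))
      expect_lt(min(max(d), max(dswap)), 2)
      # centers inside the pixel bounding box
      expect_true(all(sp$centers[, 1] >= min(px[, 1]) &
                        sp$centers[, 1] <= max(px[, 1])))
    }
  })
})

test_that("node duplication reproduces the two-pair occlusion scenario", {
  # four flies, two double-area components: each component is duplicated
  # once and receives the two nearest previous flies
  prev <- rbind(c(10, 10), c(14, 10), c(60, 40), c(64, 40))
  bs <- tibble::tibble(
    blob = 1:2, x = c(12, 62), y = c(10, 40), area = c(40L, 40L),
    axis_x = 1, axis_y = 0, axis_half = 4,
    pixels = list(cbind(x = 1:40, y = 1), cbind(x = 1:40, y = 1))
  )
  class(bs) <- c("blob_set", class(bs))
  g <- build_assignment_graph(prev, bs, 4, typical_area = 20)
  expect_equal(sort(g$col_blob), c(1L, 1L, 2L, 2L))
  m <- solve_assignment(g$cost)$assignment
  expect_equal(sort(g$col_blob[m[1:2]]), c(1L, 1L))  # P1, P2 -> C1
  expect_equal(sort(g$col_blob[m[3:4]]), c(2L, 2L))  # P3, P4 -> C2
})

test_that("a triple-size component appears three times in the graph", {
  prev <- rbind(c(10, 10), c(12, 10), c(14, 10))
  bs <- tibble::tibble(blob = 1L, x = 12, y = 10, area = 60L,
                       axis_x = 1, axis_y = 0, axis_half = 6,
                       pixels = list(cbind(x = 1:60, y = 1)))
  class(bs) <- c("blob_set", class(bs))
  g <- build_assignment_graph(prev, bs, 3, typical_area = 20)
  expect_equal(g$col_blob, c(1L, 1L, 1L))
})

test_that("identity re-assignment follows proximity and tolerates jitter", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- sample(3:7, 1)
      prev <- matrix(runif(2 * n, 0, 100), n, 2)
      # enforce spacing so jitter cannot flip the optimum
      while (min(dist(prev)) < 10) prev <- matrix(runif(2 * n, 0, 100), n, 2)
      p <- sample(n)
      centers <- prev[p, ] + matrix(runif(2 * n, -1, 1), n, 2)
      ids <- assign_identities(prev, centers)
      expect_equal(ids, p)
    }
  })
})

test_that("orientation resolves the head from smoothed motion and holds when stopped", {
  TT <- 40
  centers <- cbind(seq(0, 39), rep(5, TT))          # moving +x
  axes <- matrix(rep(c(1, 0), TT), ncol = 2, byrow = TRUE)
  axes[seq(2, TT, 2), ] <- -axes[seq(2, TT, 2), ]   # arbitrary sign flips
  o <- update_orientation(centers, axes, rep(4, TT))
  expect_true(all(o$head[5:TT, 1] > centers[5:TT, 1]))
  # stationary tail keeps the last orientation
  centers2 <- rbind(centers, matrix(rep(centers[TT, ], 10), 10, 2, byrow = TRUE))
  axes2 <- rbind(axes, matrix(rep(c(1, 0), 10), 10, 2, byrow = TRUE))
  o2 <- update_orientation(centers2, axes2, rep(4, TT + 10))
  expect_true(all(o2$head[(TT + 1):(TT + 10), 1] > centers2[(TT + 1):(TT + 10), 1]))
})

test_that("a single fly is tracked within a pixel of ground truth", {
  cfg <- sim_config(n_flies = 1, n_frames = 150, arena_width = 120,
                    arena_height = 90, seed = 6)
  gt <- simulate_trajectories(cfg)
  tk <- track_video(render_frames(gt), n_flies = 1)
  expect_equal(nrow(tk), 150)
  err <- sqrt((tk$cx - gt$trajectories$cx)^2 + (tk$cy - gt$trajectories$cy)^2)
  expect_lt(max(err), 1)
})

test_that("constant count holds through scripted crossings with identities intact", {
  cfg <- sim_config(n_flies = 8, n_frames = 600, crossings = 6, seed = 8)
  gt <- simulate_trajectories(cfg)
  tk <- suppressWarnings(track_video(render_frames(gt), n_flies = 8))
  # exactly N states per frame, N continuous tracks
  expect_equal(unname(table(tk$frame)), rep(8L, 600), ignore_attr = TRUE)
  expect_equal(sort(unique(tk$fly_id)), 1:8)
  # count conservation even while blobs merge
  errs <- centre_errors(tk, gt$trajectories, 8)
  expect_lt(mean(errs > 2), 0.005)
  m0 <- match_ids_at(tk, gt$trajectories, 0L, 8)
  mL <- match_ids_at(tk, gt$trajectories, 599L, 8)
  expect_equal(m0, mL)
})

test_that("sixteen flies keep their identities through twenty scripted crossings", {
  cfg <- sim_config(n_flies = 16, n_frames = 1200, crossings = 20, seed = 1)
  gt <- simulate_trajectories(cfg)
  tk <- suppressWarnings(track_video(render_frames(gt), n_flies = 16))
  expect_equal(unname(table(tk$frame)), rep(16L, 1200), ignore_attr = TRUE)
  m0 <- match_ids_at(tk, gt$trajectories, 0L, 16)
  mL <- match_ids_at(tk, gt$trajectories, 1199L, 16)
  expect_equal(sum(m0 == mL), 16)
})

test_that("tracking anchors on a later frame when the video starts mid-occlusion", {
  cfg <- sim_config(n_flies = 4, n_frames = 260, arena_width = 200,
                    arena_height = 150, seed = 9)
  gt <- simulate_trajectories(cfg)
  # overwrite the first 30 frames so flies 1 and 2 overlap from frame 0
  tr <- gt$trajectories
  for (t in 0:29) {
    i1 <- tr$frame == t & tr$fly_id == 1
    i2 <- tr$frame == t & tr$fly_id == 2
    tr[i2, c("cx", "cy", "hx", "hy", "tx", "ty")] <-
      tr[i1, c("cx", "cy", "hx", "hy", "tx", "ty")] +
      matrix(c(3, 1, 3, 1, 3, 1), nrow = 1)
  }
  # fade the displaced fly back towards its own frame-30 position
  gt$trajectories <- tr
  tk <- suppressWarnings(track_video(render_frames(gt), n_flies = 4))
  expect_gt(attr(tk, "anchor_frame"), 0)
  expect_equal(unname(table(tk$frame)), rep(4L, 260), ignore_attr = TRUE)
})

test_that("total walking distance matches direct summation and closed forms", {
  # constant speed: v * (T - 1)
  tkc <- tibble::tibble(frame = 0:49, fly_id = 1, cx = 2 * (0:49), cy = 5)
  d <- total_walking_distance(tkc)
  expect_equal(d$distance, 2 * 49)
  # stationary fly: 0
  tks <- tibble::tibble(frame = 0:49, fly_id = 1, cx = 3, cy = 5)
  expect_equal(total_walking_distance(tks)$distance, 0)
  # random walk: equals brute-force summation, group total is the sum
  withr::with_seed(10, {
    tkr <- tibble::tibble(frame = rep(0:99, 2), fly_id = rep(1:2, each = 100),
                          cx = runif(200, 0, 50), cy = runif(200, 0, 50))
    d2 <- total_walking_distance(tkr)
    brute <- sapply(1:2, function(i) {
      o <- tkr[tkr$fly_id == i, ]
      sum(sqrt(diff(o$cx)^2 + diff(o$cy)^2))
    })
    expect_equal(d2$distance, brute)
    expect_equal(attr(d2, "total"), sum(brute))
  })
})
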