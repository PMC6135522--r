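#' Configure a synthetic arena simulation
#'
#' Builds the configuration object for the synthetic walking-arena simulator.
#' The simulator emulates the recording conditions of an overhead infrared
#' arena camera: bright fly-sized ellipses on a dark background, smooth
#' random-walk motion with heading persistence, and scripted pairwise
#' episodes (crossings that merge two flies into one connected component,
#' and head-to-tail touches with exact frame-level ground-truth labels).
#'
#' @param n_flies number of flies (>= 1).
#' @param n_frames number of frames to simulate (0-based frame indices).
#' @param arena_width,arena_height arena size in pixels.
#' @param fps nominal frame rate, frames per second.
#' @param fly_area target rendered body area of one fly, in pixels.
#' @param aspect major/minor axis ratio of the rendered body ellipse.
#' @param speed_mean,speed_sd walking speed distribution, px/frame.
#' @param heading_persistence in \[0, 1\]; 1 = straight walking, 0 = fully
#'   diffusive heading.
#' @param touches either a count of touch episodes to plan at random, or a
#'   data frame with columns `interactor`, `interacted`, `start`, `duration`.
#' @param crossings either a count of crossing episodes, or a data frame with
#'   columns `fly_a`, `fly_b`, `start`, `duration`.
#' @param touch_duration,crossing_duration integer range (length 2) from which
#'   planned episode durations are drawn, in frames.
#' @param touch_radius maximum head-to-tail distance (px) defining a planted
#'   touch; defaults to half a body length.
#' @param noise_sd standard deviation of optional additive Gaussian pixel
#'   noise, in grey levels (0 disables noise).
#' @param bg_level,fly_level background and fly intensity, grey levels 0-255.
#' @param seed integer seed; the simulation is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_flies = 4, n_frames = 200, touches = 1, seed = 1)
#' gt <- simulate_trajectories(cfg)
sim_config <- function(n_flies = 16,
                       n_frames = 1800,
                       arena_width = 480,
                       arena_height = 360,
                       fps = 30,
                       fly_area = 20,
                       aspect = 2.5,
                       speed_mean = 1.2,
                       speed_sd = 0.4,
                       heading_persistence = 0.9,
                       touches = 0,
                       crossings = 0,
                       touch_duration = c(20, 30),
                       crossing_duration = c(12, 25),
                       touch_radius = NULL,
                       noise_sd = 0,
                       bg_level = 10,
                       fly_level = 230,
                       seed = 1) {
  stopifnot(n_flies >= 1, n_frames >= 1, arena_width > 0, arena_height > 0,
            fly_area > 0, speed_mean >= 0, speed_sd >= 0,
            heading_persistence >= 0, heading_persistence <= 1)
  blen <- body_length(fly_area, aspect)
  cfg <- structure(list(
    n_flies = as.integer(n_flies), n_frames = as.integer(n_frames),
    arena_width = as.integer(arena_width), arena_height = as.integer(arena_height),
    fps = fps, fly_area = fly_area, aspect = aspect,
    speed_mean = speed_mean, speed_sd = speed_sd,
    heading_persistence = heading_persistence,
    touch_duration = as.integer(touch_duration),
    crossing_duration = as.integer(crossing_duration),
    touch_radius = touch_radius %||% (0.5 * blen),
    body_length = blen,
    noise_sd = noise_sd, bg_level = bg_level, fly_level = fly_level,
    approach_frames = 75L,
    seed = as.integer(seed)
  ), class = "sim_config")
  cfg$crossings <- normalize_episodes(crossings, cfg, kind = "crossing")
  cfg$touches <- normalize_episodes(touches, cfg, kind = "touch",
                                    avoid = cfg$crossings)
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  eps <- dplyr::bind_rows(
    if (nrow(cfg$touches)) cfg$touches[c("start", "duration")],
    if (nrow(cfg$crossings)) cfg$crossings[c("start", "duration")]
  )
  ids <- c(cfg$touches$interactor, cfg$touches$interacted,
           cfg$crossings$fly_a, cfg$crossings$fly_b)
  if (length(ids) && (any(ids < 1) || any(ids > cfg$n_flies)))
    abort("episode references a fly id outside 1..n_flies", class = "flynet_invalid_config")
  if (!is.null(eps) && nrow(eps)) {
    if (any(eps$duration < 1) || any(eps$start < 0))
      abort("episodes must have start >= 0 and duration >= 1",
            class = "flynet_invalid_config")
    if (cfg$n_frames <= max(eps$duration))
      abort("n_frames must exceed the longest scripted episode",
            class = "flynet_invalid_config")
    if (any(eps$start + eps$duration > cfg$n_frames))
      abort("scripted episode extends past the end of the video",
            class = "flynet_invalid_config")
  }
  same <- c(cfg$touches$interactor == cfg$touches$interacted,
            cfg$crossings$fly_a == cfg$crossings$fly_b)
  if (any(same))
    abort("episodes need two distinct flies", class = "flynet_invalid_config")
  invisible(cfg)
}

# Turn a count into a planned episode table, or validate a user table.
# Planned episodes keep each fly free around its own episodes so approach
# steering and release do not collide with another scripted event.
normalize_episodes <- function(x, cfg, kind = c("touch", "crossing"),
                               avoid = NULL) {
  kind <- match.arg(kind)
  cols <- if (kind == "touch") c("interactor", "interacted") else c("fly_a", "fly_b")
  if (is.data.frame(x)) {
    stopifnot(all(c(cols, "start", "duration") %in% names(x)))
    out <- as_tibble(x)[, c(cols, "start", "duration")]
    out[] <- lapply(out, as.integer)
    return(out)
  }
  n <- as.integer(x)
  empty <- tibble(a = integer(), b = integer(), start = integer(), duration = integer())
  names(empty)[1:2] <- cols
  if (n == 0) return(empty)
  if (cfg$n_flies < 2)
    abort("scripted episodes need at least two flies", class = "flynet_invalid_config")
  dur_rng <- if (kind == "touch") cfg$touch_duration else cfg$crossing_duration
  # keep each fly clear around its episodes: approach window plus the
  # largest activation delay the runtime scheduler may add
  # asymmetric clearance: approach window before, activation-delay slack
  # plus release grace after
  pre <- cfg$approach_frames + 10L
  post <- 110L
  lo <- cfg$approach_frames + 10L
  hi <- cfg$n_frames - max(dur_rng) - 20L
  if (hi <= lo)
    abort("video too short to place the requested episodes",
          class = "flynet_invalid_config")
  with_seed(cfg$seed + switch(kind, touch = 7919L, crossing = 104729L), {
    busy <- vector("list", cfg$n_flies) # list of [from, to] busy windows per fly
    if (!is.null(avoid) && nrow(avoid)) {
      # a fly cannot serve two scripted episodes at once, whatever their kind
      for (r in seq_len(nrow(avoid))) {
        win <- c(avoid$start[r] - pre, avoid$start[r] + avoid$duration[r] + post)
        for (id in as.integer(avoid[r, 1:2]))
          busy[[id]] <- c(busy[[id]], list(win))
      }
    }
    res <- vector("list", n)
    placed <- 0L
    for (attempt in seq_len(n * 200L)) {
      if (placed == n) break
      pair <- sample.int(cfg$n_flies, 2L)
      dur <- sample(seq(dur_rng[1], dur_rng[2]), 1L)
      start <- sample(seq(lo, hi), 1L)
      win <- c(start - pre, start + dur + post)
      free <- function(id) {
        !any(vapply(busy[[id]], function(w) win[1] <= w[2] && w[1] <= win[2], logical(1)))
      }
      if (free(pair[1]) && free(pair[2])) {
        placed <- placed + 1L
        res[[placed]] <- tibble(a = pair[1], b = pair[2],
                                start = start, duration = dur)
        busy[[pair[1]]] <- c(busy[[pair[1]]], list(win))
        busy[[pair[2]]] <- c(busy[[pair[2]]], list(win))
      }
    }
    if (placed < n)
      abort(sprintf("could only place %d of %d %s episodes; use more frames or flies",
                    placed, n, kind), class = "flynet_invalid_config")
    out <- dplyr::bind_rows(res)
    names(out)[1:2] <- cols
    out
  })
}

#' Simulate ground-truth fly trajectories
#'
#' Runs the arena motion model: an Ornstein-Uhlenbeck-like heading walk with
#' wall reflection and soft collision avoidance, plus scripted crossing and
#' head-to-tail touch episodes. Scripted flies are steered smoothly towards
#' their partner before an episode starts, so trajectories stay physically
#' plausible for the tracker.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `fly_ground_truth`: a list with
#'   * `trajectories`: tibble (frame, fly_id, cx, cy, hx, hy, tx, ty), one row
#'     per fly and frame;
#'   * `touch_labels`: tibble (frame, interactor_id, interacted_id) of frames
#'     where a planted touch is active;
#'   * `crossing_frames`: tibble (frame, fly_a, fly_b);
#'   * `episodes`: the realized episode table (`start` holds the frame each
#'     episode actually began; it can trail the requested start when the
#'     approach needed more time);
#'   * `cfg`: the configuration.
#'
#' Scripted episodes are orchestrated by a runtime scheduler: the episode
#' begins once the approaching fly has genuinely reached its slot (within a
#' bounded delay), so ground-truth trajectories never jump.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  N <- cfg$n_flies; TT <- cfg$n_frames
  W <- cfg$arena_width; H <- cfg$arena_height
  a_half <- ellipse_axes(cfg$fly_area, cfg$aspect)[["a"]]
  blen <- cfg$body_length
  margin <- blen
  min_sep <- 2 * blen
  v_app <- max(3.5, 1.5 * cfg$speed_mean)   # approach speed cap, px/frame
  app <- cfg$approach_frames
  snap_tol <- 4.5                           # arrival tolerance at the slot
  force_delay <- 90L                        # latest activation after the cue

  # episode table; the runtime state machine activates each episode when its
  # follower has actually arrived, so scripted events never teleport a fly
  eps <- dplyr::bind_rows(
    if (nrow(cfg$touches))
      tibble(kind = 1L, fol = cfg$touches$interactor, led = cfg$touches$interacted,
             req_start = cfg$touches$start, duration = cfg$touches$duration),
    if (nrow(cfg$crossings))
      tibble(kind = 2L, fol = cfg$crossings$fly_b, led = cfg$crossings$fly_a,
             req_start = cfg$crossings$start, duration = cfg$crossings$duration)
  )
  nE <- if (is.null(eps)) 0L else nrow(eps)
  status <- rep(0L, nE)          # 0 pending, 1 approach, 2 active, 3 done
  act_start <- rep(NA_integer_, nE)

  with_seed(cfg$seed, {
    pos <- matrix(NA_real_, N, 2)
    for (i in seq_len(N)) {
      for (try in 1:2000) {
        p <- c(runif(1, margin, W - 1 - margin), runif(1, margin, H - 1 - margin))
        if (i == 1 || all(rownorm(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p)) > 2 * min_sep)) {
          pos[i, ] <- p; break
        }
      }
      if (anyNA(pos[i, ]))
        abort("arena too crowded for the requested number of flies")
    }
    theta <- runif(N, 0, 2 * pi)
    speed <- pmax(0, rnorm(N, cfg$speed_mean, cfg$speed_sd))
    heading <- cbind(cos(theta), sin(theta))  # ground-truth body axis

    CX <- matrix(NA_real_, TT, N); CY <- matrix(NA_real_, TT, N)
    UX <- matrix(NA_real_, TT, N); UY <- matrix(NA_real_, TT, N)
    record <- function(t) {
      CX[t + 1L, ] <<- pos[, 1]; CY[t + 1L, ] <<- pos[, 2]
      UX[t + 1L, ] <<- heading[, 1]; UY[t + 1L, ] <<- heading[, 2]
    }
    record(0L)

    turn_sd <- 1.2 * (1 - cfg$heading_persistence)
    uslot <- matrix(0, N, 2)        # smoothed slot axis per engaged follower
    grace_until <- rep(-1L, N)      # released flies drift apart freely
    touch_rows <- vector("list", nE)
    cross_rows <- vector("list", nE)

    active_slot <- function(jpos, us, kind) {
      if (kind == 1L) (jpos - a_half * us) - (a_half + 0.5 * cfg$touch_radius) * us
      else jpos + 0.9 * blen * us + 0.15 * blen * rot90(us)
    }

    for (t in seq_len(TT - 1L)) {
      # --- episode state transitions (based on last frame's positions)
      role <- rep(0L, N); pt <- rep(0L, N); kd <- rep(0L, N); ep_of <- rep(0L, N)
      for (e in seq_len(nE)) {
        if (status[e] == 0L && t >= eps$req_start[e] - app) status[e] <- 1L
        if (status[e] == 1L && t >= eps$req_start[e]) {
          i <- eps$fol[e]; j <- eps$led[e]
          slot <- active_slot(pos[j, ], if (sum(uslot[i, ]^2) > 0) uslot[i, ] else heading[j, ],
                              eps$kind[e])
          latest <- min(eps$req_start[e] + force_delay, TT - eps$duration[e] - 2L)
          if (vec_norm(pos[i, ] - slot) <= snap_tol || t >= latest) {
            status[e] <- 2L
            act_start[e] <- t
          }
        }
        if (status[e] == 2L && t - act_start[e] >= eps$duration[e]) {
          status[e] <- 3L
          i <- eps$fol[e]; j <- eps$led[e]
          grace_until[c(i, j)] <- t + 15L
          # released fly turns off the partner's track and hurries away so
          # the head-to-tail distance clears the touch radius immediately
          theta[i] <- atan2(uslot[i, 2], uslot[i, 1]) +
            if (eps$kind[e] == 1L) pi else 0.6
          speed[i] <- v_app
        }
        if (status[e] %in% c(1L, 2L)) {
          i <- eps$fol[e]; j <- eps$led[e]
          role[i] <- if (status[e] == 2L) 2L else 1L
          role[j] <- 3L
          pt[i] <- j; pt[j] <- i
          kd[i] <- eps$kind[e]; kd[j] <- eps$kind[e]
          ep_of[i] <- e; ep_of[j] <- e
        }
      }
      old <- pos

      # --- 1. leaders and normal flies take an ordinary walk step
      for (i in seq_len(N)) {
        if (role[i] == 2L) next
        # an engaged leader walks steadier: a sharp turn would drag the
        # approaching or slaved partner sideways
        theta[i] <- theta[i] + rnorm(1, 0, if (role[i] == 3L) 0.3 * turn_sd else turn_sd)
        tgt <- max(0, rnorm(1, cfg$speed_mean, cfg$speed_sd))
        if (role[i] == 3L) tgt <- max(tgt, 0.8 * cfg$speed_mean)
        speed[i] <- 0.7 * speed[i] + 0.3 * tgt
        if (role[i] == 1L) {
          # approach: home on the standoff slot with fly-like speeds; the
          # episode will simply start late if the way is long
          e <- ep_of[i]; j <- pt[i]
          if (sum(uslot[i, ]^2) == 0) uslot[i, ] <- heading[j, ]
          uslot[i, ] <- unit(0.75 * uslot[i, ] + 0.25 * heading[j, ])
          frames_left <- max(1L, eps$req_start[e] - t)
          slot <- approach_slot(old[j, ], uslot[i, ], kd[i], a_half,
                                cfg$touch_radius, blen,
                                ramp = min(1, frames_left / (0.3 * app)))
          togo <- slot - pos[i, ]
          d <- vec_norm(togo)
          d_led <- vec_norm(old[j, ] - pos[i, ])
          if (d_led < 3 * blen &&
              sum((pos[i, ] - old[j, ]) * (slot - old[j, ])) < 0) {
            # wrong side of the partner: round its body on a forward-curving
            # arc instead of walking straight over it
            side <- sign(sum(rot90(uslot[i, ]) * (pos[i, ] - old[j, ])))
            if (side == 0) side <- 1
            arc <- unit(side * rot90(uslot[i, ]) + unit(slot - old[j, ]))
            togo <- (old[j, ] + 1.8 * blen * arc) - pos[i, ]
            d <- vec_norm(togo)
          }
          need <- d / frames_left + cfg$speed_mean
          speed[i] <- min(v_app, max(speed[i], 1.1 * need))
          w <- if (t >= eps$req_start[e]) 1 else
            min(1, 0.15 + 0.85 * (1 - frames_left / app))
          dir <- unit((1 - w) * c(cos(theta[i]), sin(theta[i])) + w * unit(togo))
          theta[i] <- atan2(dir[2], dir[1])
          pos[i, ] <- pos[i, ] + min(speed[i], d) * dir
        } else {
          pos[i, ] <- pos[i, ] + speed[i] * c(cos(theta[i]), sin(theta[i]))
        }
      }

      # --- 2. soft collision avoidance; engaged or just-released flies are
      # not shoved (their geometry is scripted), bystanders give way in
      # capped steps
      engaged <- role != 0L | grace_until >= t
      # a scripted fly is moved through its episode leader, so pushing two
      # colliding episodes apart shifts each pair as a rigid unit
      anchor_of <- function(x) if (role[x] %in% c(1L, 2L)) pt[x] else x
      pos_presep <- pos
      for (pass in 1:2) {
        for (i in seq_len(N - 1L)) {
          for (j in (i + 1L):N) {
            if (pt[i] == j || pt[j] == i) next     # same episode pair
            d <- pos[j, ] - pos[i, ]
            dn <- vec_norm(d)
            if (dn >= min_sep) next
            gap <- min(min_sep - dn, 2.5)
            dirn <- if (dn < 1e-9) c(1, 0) else unit(d)
            if (engaged[i] && engaged[j]) {
              ai <- anchor_of(i); aj <- anchor_of(j)
              if (ai == aj) next
              pos[ai, ] <- pos[ai, ] - gap / 2 * dirn
              pos[aj, ] <- pos[aj, ] + gap / 2 * dirn
            } else if (engaged[i]) {
              pos[j, ] <- pos[j, ] + gap * dirn
            } else if (engaged[j]) {
              pos[i, ] <- pos[i, ] - gap * dirn
            } else {
              pos[i, ] <- pos[i, ] - gap / 2 * dirn
              pos[j, ] <- pos[j, ] + gap / 2 * dirn
            }
          }
        }
      }
      # several overlapping conflicts can stack pushes; cap the net
      # separation displacement so avoidance never becomes a teleport
      sep_disp <- pos - pos_presep
      sep_n <- rownorm(sep_disp)
      over <- which(sep_n > 2.5)
      for (i in over)
        pos[i, ] <- pos_presep[i, ] + 2.5 * sep_disp[i, ] / sep_n[i]

      # --- 3. walls: clamp and reflect; engaged leaders keep a wider margin
      # (ramped over the approach) and curve away instead of mirror
      # reflecting, which would teleport the slaved partner
      emarg <- rep(margin, N)
      for (i in seq_len(N)) {
        if (role[i] != 3L) next
        prog <- if (role[pt[i]] == 2L) 1 else
          1 - max(0L, eps$req_start[ep_of[i]] - t) / app
        emarg[i] <- margin + prog * 2.5 * blen
      }
      for (i in seq_len(N)) {
        if (role[i] == 2L) next
        mrg <- emarg[i]
        hit <- FALSE
        if (pos[i, 1] < mrg || pos[i, 1] > W - 1 - mrg) {
          pos[i, 1] <- min(max(pos[i, 1], mrg), W - 1 - mrg)
          if (role[i] != 3L) theta[i] <- pi - theta[i]
          hit <- TRUE
        }
        if (pos[i, 2] < mrg || pos[i, 2] > H - 1 - mrg) {
          pos[i, 2] <- min(max(pos[i, 2], mrg), H - 1 - mrg)
          if (role[i] != 3L) theta[i] <- -theta[i]
          hit <- TRUE
        }
        if (role[i] == 3L && hit) {
          ctr_dir <- atan2(H / 2 - pos[i, 2], W / 2 - pos[i, 1])
          dang <- ((ctr_dir - theta[i] + pi) %% (2 * pi)) - pi
          theta[i] <- theta[i] + sign(dang) * min(0.3, abs(dang))
        }
      }

      # --- 4. active followers are slaved to their (already moved) partner;
      # the smoothed slot axis absorbs abrupt partner turns
      for (i in seq_len(N)) {
        if (role[i] != 2L) next
        j <- pt[i]
        u <- heading[j, ]
        stepj <- pos[j, ] - old[j, ]
        if (vec_norm(stepj) > 0.05) u <- unit(stepj)
        uslot[i, ] <- unit(0.75 * uslot[i, ] + 0.25 * u)
        us <- uslot[i, ]
        if (kd[i] == 1L) {
          # head-to-tail touch: head_i sits within the touch radius of j's
          # tail by construction, whatever the smoothed axis does
          tail_j <- pos[j, ] - a_half * u
          pos[i, ] <- tail_j - (a_half + 0.5 * cfg$touch_radius) * us
        } else {
          pos[i, ] <- pos[j, ] + 0.9 * blen * us + 0.15 * blen * rot90(us)
        }
        theta[i] <- atan2(us[2], us[1])
        heading[i, ] <- us
        e <- ep_of[i]
        if (kd[i] == 1L)
          touch_rows[[e]] <- c(touch_rows[[e]], t)
        else
          cross_rows[[e]] <- c(cross_rows[[e]], t)
      }
      # clear the slot axis of flies that finished their episode
      uslot[role == 0L, ] <- 0

      # --- 5. body axis follows realized motion (slaved flies already set)
      step <- pos - old
      slaved <- role == 2L
      moved <- rownorm(step) > 0.05 & !slaved
      heading[moved, ] <- step[moved, , drop = FALSE] / rownorm(step[moved, , drop = FALSE])
      record(t)
    }

    frames <- rep(0:(TT - 1L), each = N)
    ids <- rep(seq_len(N), times = TT)
    ux <- as.vector(t(UX)); uy <- as.vector(t(UY))
    cx <- as.vector(t(CX)); cy <- as.vector(t(CY))
    traj <- tibble(
      frame = frames, fly_id = ids,
      cx = cx, cy = cy,
      hx = cx + a_half * ux, hy = cy + a_half * uy,
      tx = cx - a_half * ux, ty = cy - a_half * uy
    )

    empty_touch <- tibble(frame = integer(), interactor_id = integer(),
                          interacted_id = integer())
    empty_cross <- tibble(frame = integer(), fly_a = integer(), fly_b = integer())
    touch_labels <- empty_touch
    crossing_frames <- empty_cross
    realized <- NULL
    if (nE) {
      touch_labels <- dplyr::bind_rows(empty_touch, purrr::map_dfr(seq_len(nE), function(e) {
        if (is.null(touch_rows[[e]])) return(NULL)
        tibble(frame = touch_rows[[e]], interactor_id = eps$fol[e],
               interacted_id = eps$led[e])
      }))
      crossing_frames <- dplyr::bind_rows(empty_cross, purrr::map_dfr(seq_len(nE), function(e) {
        if (is.null(cross_rows[[e]])) return(NULL)
        tibble(frame = cross_rows[[e]], fly_a = eps$led[e], fly_b = eps$fol[e])
      }))
      realized <- dplyr::mutate(eps, start = act_start)
    }
    touch_labels <- dplyr::arrange(touch_labels, .data$interactor_id,
                                   .data$interacted_id, .data$frame)

    structure(list(trajectories = traj, touch_labels = touch_labels,
                   crossing_frames = crossing_frames, episodes = realized,
                   cfg = cfg),
              class = "fly_ground_truth")
  })
}

# standoff point near the leader where an approaching fly waits. For
# touches it stays outside the touch radius so the planted label run starts
# exactly on cue; for crossings the radius ramps down (ramp 1 -> 0) into the
# active overlap slot so the episode starts without a position snap.
approach_slot <- function(pos_j, u_j, kindcode, a_half, touch_radius, blen,
                          ramp = 1) {
  if (kindcode == 1L)
    pos_j - (2 * a_half + (1.1 + 0.4 * ramp) * touch_radius) * u_j
  else
    pos_j + (0.9 + 0.4 * ramp) * blen * u_j +
      (0.15 + 0.15 * ramp) * blen * rot90(u_j)
}

#' Render simulated frames
#'
#' Rasterizes ground-truth trajectories into grayscale frames: a dark
#' background with one bright filled ellipse per fly, major axis along the
#' head-tail line. Overlapping ellipses merge into a single connected
#' component, exactly as interacting flies do under an overhead camera.
#' Frames are produced lazily so hour-long videos never need to fit in
#' memory.
#'
#' @param gt a `fly_ground_truth` from [simulate_trajectories()].
#' @param cfg the matching [sim_config()]; defaults to `gt$cfg`.
#' @return A `frame_source`: a list with `n_frames`, `width`, `height` and
#'   `get(t)` returning the frame at 0-based index `t` as a numeric
#'   `height x width` matrix of grey levels in 0-255.
#' @export
render_frames <- function(gt, cfg = gt$cfg) {
  stopifnot(inherits(gt, "fly_ground_truth"))
  traj <- gt$trajectories
  N <- cfg$n_flies
  ax <- ellipse_axes(cfg$fly_area, cfg$aspect)
  # column-major per-frame blocks for O(1) slicing
  ord <- order(traj$frame, traj$fly_id)
  cx <- matrix(traj$cx[ord], nrow = N); cy <- matrix(traj$cy[ord], nrow = N)
  hx <- matrix(traj$hx[ord], nrow = N); hy <- matrix(traj$hy[ord], nrow = N)
  W <- cfg$arena_width; H <- cfg$arena_height
  getter <- function(t) {
    stopifnot(t >= 0, t < cfg$n_frames)
    f <- matrix(cfg$bg_level, H, W)
    k <- t + 1L
    for (i in seq_len(N)) {
      idx <- ellipse_pixels(c(cx[i, k], cy[i, k]),
                            unit(c(hx[i, k] - cx[i, k], hy[i, k] - cy[i, k])),
                            ax[["a"]], ax[["b"]], W, H)
      f[idx] <- cfg$fly_level
    }
    if (cfg$noise_sd > 0) {
      f <- with_seed(cfg$seed + 131071L * (t + 1L) %% .Machine$integer.max,
                     f + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W))
      f <- pmin(pmax(f, 0), 255)
    }
    f
  }
  structure(list(n_frames = cfg$n_frames, width = W, height = H, get = getter),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source: %d frames, %d x %d px>\n", x$n_frames, x$width, x$height))
  invisible(x)
}

#' Fetch one frame from a frame source
#' @param src a `frame_source`.
#' @param t 0-based frame index.
#' @return numeric matrix of grey levels.
#' @export
frame_at <- function(src, t) src$get(t)

#' The empty-arena image a renderer configuration would produce
#' @param cfg a [sim_config()].
#' @return numeric matrix of grey levels (the noise-free background).
#' @export
empty_arena <- function(cfg) matrix(cfg$bg_level, cfg$arena_height, cfg$arena_width)

# linear indices (column-major, H rows) of the filled ellipse's pixels
ellipse_pixels <- function(centre, u, a, b, W, H) {
  r <- ceiling(a) + 1L
  cxi <- round(centre[1]); cyi <- round(centre[2])
  xs <- max(0L, cxi - r):min(W - 1L, cxi + r)
  ys <- max(0L, cyi - r):min(H - 1L, cyi + r)
  if (!length(xs) || !length(ys)) return(integer())
  dx <- outer(rep(1, length(ys)), xs - centre[1])
  dy <- outer(ys - centre[2], rep(1, length(xs)))
  along <- (dx * u[1] + dy * u[2]) / a
  across <- (-dx * u[2] + dy * u[1]) / b
  mask <- which(along^2 + across^2 <= 1)
  yy <- ys[(mask - 1L) %% length(ys) + 1L]
  xx <- xs[(mask - 1L) %/% length(ys) + 1L]
  xx * H + yy + 1L
}

#' Wrap an in-memory array as a frame source
#' @param arr numeric array, height x width x frames.
#' @return a `frame_source`.
#' @export
frames_from_array <- function(arr) {
  stopifnot(length(dim(arr)) == 3)
  structure(list(n_frames = dim(arr)[3], width = dim(arr)[2], height = dim(arr)[1],
                 get = function(t) arr[, , t + 1L]),
            class = "frame_source")
}
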