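# Shared simulation helpers for the tracking and interaction tests.

# map tracker fly ids to ground-truth fly ids by nearest centre at `frame`
match_ids_at <- function(tracks, gt_traj, frame, n_flies) {
  k <- tracks[tracks$frame == frame, ]
  vapply(seq_len(n_flies), function(i) {
    g <- gt_traj[gt_traj$frame == frame & gt_traj$fly_id == i, ]
    k$fly_id[which.min((k$cx - g$cx)^2 + (k$cy - g$cy)^2)]
  }, integer(1))
}

# per-record centre error of tracks against ground truth under the identity
# mapping fixed at frame 0
centre_errors <- function(tracks, gt_traj, n_flies) {
  m0 <- match_ids_at(tracks, gt_traj, 0L, n_flies)
  inv <- integer(n_flies); inv[m0] <- seq_len(n_flies)
  key <- paste(gt_traj$frame, gt_traj$fly_id)
  i2 <- match(paste(tracks$frame, inv[tracks$fly_id]), key)
  sqrt((tracks$cx - gt_traj$cx[i2])^2 + (tracks$cy - gt_traj$cy[i2])^2)
}
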