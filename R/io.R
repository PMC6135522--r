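#' @name flynet_io
#' @title File formats used by the pipeline
#' @description
#' All interchange files are plain CSV (comma separated, header row, UTF-8,
#' "." decimal, full numeric precision) with a leading comment line that
#' embeds the hash of the configuration that produced the file:
#'
#' * trajectories: `frame, fly_id, cx, cy, hx, hy, tx, ty` (0-based frames,
#'   1-based fly ids, pixel coordinates, origin top-left, y down);
#' * events: `interactor_id, interacted_id, start_frame, end_frame`;
#' * adjacency: N x N integer counts, header row of fly ids;
#' * label files for training: `frame, interactor_id, interacted_id, label`.
#'
#' Networks can additionally be exported as GraphML with `count` and
#' `weight` edge attributes. Frame input comes from in-memory arrays,
#' multi-frame TIFF files or directories of numbered PNG/TIFF images
#' (grayscale); see [read_frames()].
NULL

hash_header <- function(config) {
  sprintf("# flynet config_hash: %s", rlang::hash(config))
}

write_csv_hashed <- function(x, path, config) {
  writeLines(hash_header(config), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write / read trajectory tables
#'
#' Bit-exact CSV round trip for trajectory tables (numbers serialized at
#' full precision). A comment header records the configuration hash.
#'
#' @param tracks trajectory table (frame, fly_id, cx, cy, hx, hy, tx, ty).
#' @param path file path.
#' @param config any object describing the producing run (hashed into the
#'   header).
#' @return `write_trajectories` the path, invisibly; `read_trajectories`
#'   a validated tibble.
#' @export
write_trajectories <- function(tracks, path, config = list()) {
  req <- c("frame", "fly_id", "cx", "cy", "hx", "hy", "tx", "ty")
  validate_table(tracks, req, "trajectory")
  if (anyDuplicated(tracks[c("frame", "fly_id")]))
    abort("duplicate (frame, fly_id) rows", class = "flynet_schema")
  write_csv_hashed(tracks[union(req, names(tracks))], path, config)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_table(out, c("frame", "fly_id", "cx", "cy", "hx", "hy", "tx", "ty"),
                 "trajectory")
  if (anyDuplicated(out[c("frame", "fly_id")]))
    abort("duplicate (frame, fly_id) rows", class = "flynet_schema")
  class(out) <- c("fly_tracks", class(out))
  out
}

validate_table <- function(x, req, what) {
  miss <- setdiff(req, names(x))
  if (length(miss))
    abort(sprintf("%s table lacks column(s): %s", what,
                  paste(miss, collapse = ", ")), class = "flynet_schema")
  invisible(x)
}

#' Write / read touch interaction event tables
#'
#' Events are validated on both directions: same-pair intervals must not
#' overlap and ends must not precede starts; offending rows are named in the
#' error.
#'
#' @param events tibble (interactor_id, interacted_id, start_frame,
#'   end_frame).
#' @param path file path.
#' @param config hashed into the header comment.
#' @export
write_events <- function(events, path, config = list()) {
  validate_events(events)
  write_csv_hashed(events, path, config)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_events(out)
  out
}

validate_events <- function(events) {
  validate_table(events, c("interactor_id", "interacted_id", "start_frame",
                           "end_frame"), "events")
  bad <- which(events$end_frame < events$start_frame)
  if (length(bad))
    abort(paste("end_frame precedes start_frame in row(s):",
                paste(bad, collapse = ", ")), class = "flynet_schema")
  by_pair <- split(seq_len(nrow(events)),
                   paste(events$interactor_id, events$interacted_id))
  for (rows in by_pair) {
    if (length(rows) < 2) next
    o <- rows[order(events$start_frame[rows])]
    overlap <- which(events$start_frame[o][-1] <=
                       events$end_frame[o][-length(o)])
    if (length(overlap))
      abort(paste("overlapping same-pair intervals in row(s):",
                  paste(o[overlap + 1L], collapse = ", ")),
            class = "flynet_schema")
  }
  invisible(events)
}

#' Write / read adjacency matrices
#'
#' N x N integer interaction counts with a header row of fly ids and the
#' config-hash comment line.
#'
#' @param net a `social_network` (or bare count matrix).
#' @param path file path.
#' @param config hashed into the header comment.
#' @export
write_adjacency <- function(net, path, config = list()) {
  counts <- if (inherits(net, "social_network")) net$counts else as.matrix(net)
  df <- as.data.frame(counts)
  names(df) <- paste0("X", seq_len(ncol(counts)))
  write_csv_hashed(df, path, config)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  social_network(m)
}

#' Export a network as GraphML
#'
#' Nodes carry the fly id, edges carry `count` (raw interactions) and
#' `weight` (max-normalized) attributes.
#'
#' @param net a `social_network`.
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "social_network"))
  g <- igraph::graph_from_adjacency_matrix(net$counts, mode = "directed",
                                           weighted = "count")
  igraph::V(g)$fly_id <- seq_len(net$n)
  mx <- max(net$counts)
  igraph::E(g)$weight <- igraph::E(g)$count / if (mx > 0) mx else 1
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read frames from image files
#'
#' Accepts a multi-frame grayscale TIFF, or a directory of numbered
#' single-frame PNG/TIFF images. Images are converted to grey levels 0-255.
#' Compressed video containers are not read directly; export such videos to
#' an image sequence first.
#'
#' @param path TIFF file or directory of frames.
#' @return a `frame_source`.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) abort("no PNG/TIFF frames found", class = "flynet_io")
    probe <- load_gray(files[1])
    getter <- function(t) {
      if (t < 0 || t >= length(files))
        abort(sprintf("frame %d out of range (last good frame: %d)",
                      t, length(files) - 1L), class = "flynet_io")
      load_gray(files[t + 1L])
    }
    structure(list(n_frames = length(files), width = ncol(probe),
                   height = nrow(probe), get = getter),
              class = "frame_source")
  } else {
    img <- EBImage::readImage(path)
    arr <- gray_array(img)
    frames_from_array(arr * 255)
  }
}

load_gray <- function(file) {
  img <- EBImage::readImage(file)
  a <- gray_array(img)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}

# EBImage stores x (columns) as the first dimension; transpose to row=y
gray_array <- function(img) {
  d <- dim(img)
  if (length(d) >= 3 && EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "gray")
    d <- dim(img)
  }
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
}

#' Write a frame source to a multi-frame TIFF
#' @param frames a `frame_source`.
#' @param path output file (.tif).
#' @export
write_frames <- function(frames, path) {
  arr <- array(0, c(frames$width, frames$height, frames$n_frames))
  for (t in seq_len(frames$n_frames) - 1L)
    arr[, , t + 1L] <- t(frames$get(t)) / 255
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff")
  invisible(path)
}

#' Run configuration objects
#'
#' A flat, namespaced key-value document collecting every tunable of the
#' pipeline. Unknown keys are rejected so typos cannot silently change a
#' run; the full resolved configuration (and its hash) should be logged with
#' every artifact.
#'
#' @param ... overrides as `name = value` pairs (see
#'   `names(flynet_config())` for the known keys).
#' @return named list of class `flynet_config`.
#' @export
flynet_config <- function(...) {
  defaults <- list(
    detection.threshold = "otsu",
    detection.min_area = 4,
    detection.merge_factor = 1.5,
    tracking.orient_window = 5,
    tracking.speed_floor = 0.2,
    interaction.min_run = 15,
    interaction.min_gap = 15,
    interaction.candidate_radius = NA,
    interaction.n_per_class = 1000,
    matching.beta0 = 0.5,
    matching.beta_rate = 1.075,
    matching.beta_max = 10,
    matching.sinkhorn_sweeps = 30,
    stats.alpha = 0.01,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
          class = "flynet_config_key")
  defaults[names(over)] <- over
  structure(defaults, class = "flynet_config")
}

#' @rdname flynet_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  do.call(flynet_config, yaml::read_yaml(path))
}

#' @rdname flynet_config
#' @param config a `flynet_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.flynet_config <- function(x, ...) {
  cat("<flynet_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  cat(sprintf("  [hash %s]\n", rlang::hash(x)))
  invisible(x)
}
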