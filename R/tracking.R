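# Spot detection, trajectory linking, and TrackMate-style track filtering.

#' Construct a track set
#'
#' The shared currency of the tracking, dwell, and diffusion stages: a data
#' frame of trajectory points plus the acquisition metadata.
#'
#' @param tracks Data frame with columns `track_id`, `frame` (0-based),
#'   `x_um`, `y_um`. Frames must be strictly increasing within a track.
#' @param acquisition An [acquisition_params()].
#' @return An object of class `TrackSet`.
#' @export
track_set <- function(tracks, acquisition) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)),
            inherits(acquisition, "AcquisitionParams"))
  if (nrow(tracks)) {
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    bad <- tapply(tracks$frame, tracks$track_id,
                  function(f) any(diff(f) <= 0))
    if (any(unlist(bad)))
      stop("frames must be strictly increasing within each track",
           call. = FALSE)
    if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um)))
      stop("track coordinates must be finite", call. = FALSE)
  }
  structure(list(tracks = tracks, acquisition = acquisition),
            class = "TrackSet")
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet: %d tracks, %d points, dt = %g s\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              x$acquisition$frame_interval_s))
  invisible(x)
}

#' Write a track set as a TrackMate-dialect CSV
#'
#' Columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y` (positions in um).
#'
#' @param tracks A [track_set()].
#' @param path Output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "TrackSet"))
  df <- data.frame(TRACK_ID = tracks$tracks$track_id,
                   FRAME = tracks$tracks$frame,
                   POSITION_X = tracks$tracks$x_um,
                   POSITION_Y = tracks$tracks$y_um)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TrackMate-dialect CSV into a track set
#'
#' Accepts the column subset `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`
#' (um). Non-numeric header continuation rows (as in raw TrackMate exports)
#' are skipped.
#'
#' @param path CSV path.
#' @param acquisition An [acquisition_params()] describing the recording.
#' @return A [track_set()].
#' @export
read_tracks_csv <- function(path, acquisition = acquisition_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns TRACK_ID, FRAME, POSITION_X, POSITION_Y",
         call. = FALSE)
  keep <- !is.na(suppressWarnings(as.numeric(df$FRAME)))
  df <- df[keep, , drop = FALSE]
  track_set(data.frame(track_id = as.integer(as.numeric(df$TRACK_ID)),
                       frame = as.integer(as.numeric(df$FRAME)),
                       x_um = as.numeric(df$POSITION_X),
                       y_um = as.numeric(df$POSITION_Y)),
            acquisition)
}

#' Detect spots in an image stack with a Laplacian-of-Gaussian filter
#'
#' Computes the scale-normalized (negated) LoG response per frame; local
#' maxima above `quality_threshold` are reported with sub-pixel position from
#' quadratic interpolation of the response peak, converted to um.
#'
#' @param stack An `ImageStack`.
#' @param sigma_px Detection scale: Gaussian sigma in pixels (match the PSF).
#' @param quality_threshold Minimum peak response (a.u.) to report.
#' @return Data frame of spots: `frame` (0-based), `x_um`, `y_um`,
#'   `intensity` (raw image value at the peak), `quality` (LoG response).
#' @export
detect_spots <- function(stack, sigma_px, quality_threshold) {
  if (is.null(dim(stack)) || length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("`stack` must be a non-empty rows x cols x frames array",
         call. = FALSE)
  check_positive(sigma_px, "sigma_px")
  px <- attr(stack, "pixel_size_um")
  if (is.null(px)) px <- 1
  kern <- log_kernel(sigma_px)
  out <- vector("list", dim(stack)[3])
  for (k in seq_len(dim(stack)[3])) {
    img <- unclass(stack)[, , k]
    resp <- EBImage::filter2(img, kern, boundary = "replicate")
    pk <- local_maxima(resp, quality_threshold)
    if (nrow(pk)) {
      sub <- t(vapply(seq_len(nrow(pk)), function(s) {
        subpixel_peak(resp, pk$i[s], pk$j[s])
      }, numeric(2)))
      out[[k]] <- data.frame(frame = k - 1L,
                             x_um = sub[, 2] * px,
                             y_um = sub[, 1] * px,
                             intensity = img[cbind(pk$i, pk$j)],
                             quality = pk$val)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), quality = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Scale-normalized negated LoG kernel: positive response on bright blobs.
log_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(x^2, x^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * G
  k <- k * sigma^2           # scale normalization
  k - mean(k)                # zero-sum: flat background gives zero response
}

# Strict interior local maxima of a matrix above a threshold.
local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L)
    return(data.frame(i = integer(), j = integer(), val = numeric()))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- m[2:(nr - 1) + di, 2:(nc - 1) + dj]
    is_max <- is_max & (core > shifted |
                          (core == shifted & (di > 0 | (di == 0 & dj > 0))))
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(i = idx[, 1] + 1L, j = idx[, 2] + 1L,
             val = core[is_max][seq_len(nrow(idx))])
}

# Quadratic sub-pixel refinement; returns c(y_px, x_px), 0-based.
subpixel_peak <- function(resp, i, j) {
  refine <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    if (den >= 0) return(0)
    d <- 0.5 * (fm - fp) / den
    max(min(d, 0.5), -0.5)
  }
  dy <- refine(resp[i - 1, j], resp[i, j], resp[i + 1, j])
  dx <- refine(resp[i, j - 1], resp[i, j], resp[i, j + 1])
  c(i - 1 + dy, j - 1 + dx)
}

#' Link detected spots into trajectories
#'
#' Frame-to-frame linking by minimum-total-squared-displacement bipartite
#' assignment (Hungarian algorithm) among candidate pairs within the gate
#' distance; unmatched spots start new tracks. Tracks tolerate up to
#' `max_gap_frames` missing frames, with the gate scaled by the frame gap.
#'
#' @param spots Data frame from [detect_spots()] (columns `frame`, `x_um`,
#'   `y_um`).
#' @param max_displacement_um Gate: maximum linking distance per frame step.
#' @param max_gap_frames Maximum number of missed frames bridged (default 0).
#' @param acquisition An [acquisition_params()] attached to the result.
#' @return A [track_set()].
#' @export
link_spots <- function(spots, max_displacement_um, max_gap_frames = 0L,
                       acquisition = acquisition_params()) {
  check_positive(max_displacement_um, "max_displacement_um")
  check_positive(max_gap_frames, "max_gap_frames", strict = FALSE)
  empty <- track_set(data.frame(track_id = integer(), frame = integer(),
                                x_um = numeric(), y_um = numeric()),
                     acquisition)
  if (is.null(spots) || nrow(spots) == 0L) return(empty)
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  # Active track state: id, last frame, last position.
  act_id <- integer(0); act_frame <- integer(0)
  act_x <- numeric(0); act_y <- numeric(0)
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    sp <- spots[spots$frame == f, , drop = FALSE]
    ns <- nrow(sp)
    assigned <- rep(NA_integer_, ns)
    cand <- which(act_frame >= f - 1L - max_gap_frames & act_frame < f)
    if (length(cand) && ns) {
      gap <- f - act_frame[cand]           # frames elapsed per candidate
      gate2 <- (max_displacement_um * gap)^2
      d2 <- outer(act_x[cand], sp$x_um, "-")^2 +
        outer(act_y[cand], sp$y_um, "-")^2
      pair <- assign_gated(d2, gate2)
      assigned[pair$col] <- cand[pair$row]
    }
    ids <- integer(ns)
    for (s in seq_len(ns)) {
      if (is.na(assigned[s])) {
        ids[s] <- next_id
        next_id <- next_id + 1L
        act_id <- c(act_id, ids[s])
        act_frame <- c(act_frame, f)
        act_x <- c(act_x, sp$x_um[s]); act_y <- c(act_y, sp$y_um[s])
      } else {
        a <- assigned[s]
        ids[s] <- act_id[a]
        act_frame[a] <- f
        act_x[a] <- sp$x_um[s]; act_y[a] <- sp$y_um[s]
      }
    }
    rows[[fi]] <- data.frame(track_id = ids, frame = f,
                             x_um = sp$x_um, y_um = sp$y_um)
  }
  tracks <- do.call(rbind, rows)
  tracks$track_id <- match(tracks$track_id, sort(unique(tracks$track_id)))
  track_set(tracks, acquisition)
}

# Gated rectangular assignment minimizing total squared displacement.
# d2: n_tracks x n_spots squared distances; gate2: per-row squared gates.
# Returns matched (row, col) pairs whose cost is within the gate. Uses the
# standard birth/death augmentation so unmatched rows/cols are allowed at the
# gate cost, solved by the Hungarian method (clue::solve_LSAP).
assign_gated <- function(d2, gate2) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  big <- max(gate2) * (n1 + n2 + 1) + 1
  allowed <- d2 <= gate2   # gate2 recycled down columns (per-row gates)
  if (!any(allowed)) return(list(row = integer(0), col = integer(0)))
  m <- n1 + n2
  cost <- matrix(big, m, m)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(allowed, d2, big)
  # Death (track unmatched) and birth (spot unmatched) at the gate cost.
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- gate2
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- max(gate2)
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  sol <- as.integer(clue::solve_LSAP(cost))
  row <- seq_len(n1)
  col <- sol[seq_len(n1)]
  keep <- col <= n2 & allowed[cbind(row, pmin(col, n2))]
  list(row = row[keep], col = col[keep])
}

#' Track filtering rules
#'
#' Mirrors TrackMate-style post-tracking filters: drop tracks alive in the
#' first movie frame ("Track Start"), alive in the last frame ("Track End"),
#' shorter than `min_frames` ("Duration"), exceeding a net displacement bound,
#' or entering an edge margin.
#'
#' @param drop_present_at_start,drop_present_at_end Logical flags.
#' @param min_frames Minimum observed frames per track (default 2).
#' @param max_displacement_um Optional cap on net start-to-end displacement.
#' @param edge_margin_um Optional margin from the field border; tracks with
#'   any position inside the margin are dropped.
#' @return An object of class `FilterRules`.
#' @export
filter_rules <- function(drop_present_at_start = TRUE,
                         drop_present_at_end = TRUE,
                         min_frames = 2L,
                         max_displacement_um = NULL,
                         edge_margin_um = NULL) {
  if (min_frames < 1L) stop("`min_frames` must be >= 1", call. = FALSE)
  structure(list(drop_present_at_start = isTRUE(drop_present_at_start),
                 drop_present_at_end = isTRUE(drop_present_at_end),
                 min_frames = as.integer(min_frames),
                 max_displacement_um = max_displacement_um,
                 edge_margin_um = edge_margin_um),
            class = "FilterRules")
}

#' Filter a track set
#'
#' Applies [filter_rules()] and returns a new `TrackSet`; the input is left
#' untouched. The operation is idempotent. The movie's first/last frames are
#' taken from the acquisition (`0` and `n_frames - 1`).
#'
#' @param tracks A [track_set()].
#' @param rules A [filter_rules()].
#' @return Filtered [track_set()].
#' @export
filter_tracks <- function(tracks, rules = filter_rules()) {
  stopifnot(inherits(tracks, "TrackSet"), inherits(rules, "FilterRules"))
  tr <- tracks$tracks
  if (!nrow(tr)) return(tracks)
  acq <- tracks$acquisition
  last_frame <- acq$n_frames - 1L
  by_id <- split(seq_len(nrow(tr)), tr$track_id)
  keep <- vapply(by_id, function(idx) {
    f <- tr$frame[idx]
    if (rules$drop_present_at_start && min(f) == 0L) return(FALSE)
    if (rules$drop_present_at_end && max(f) >= last_frame) return(FALSE)
    if (length(idx) < rules$min_frames) return(FALSE)
    if (!is.null(rules$max_displacement_um)) {
      net <- sqrt((tr$x_um[idx[length(idx)]] - tr$x_um[idx[1]])^2 +
                    (tr$y_um[idx[length(idx)]] - tr$y_um[idx[1]])^2)
      if (net > rules$max_displacement_um) return(FALSE)
    }
    if (!is.null(rules$edge_margin_um) && !is.null(acq$image_shape)) {
      lx <- acq$image_shape[2] * acq$pixel_size_um
      ly <- acq$image_shape[1] * acq$pixel_size_um
      m <- rules$edge_margin_um
      if (any(tr$x_um[idx] < m | tr$x_um[idx] > lx - m |
                tr$y_um[idx] < m | tr$y_um[idx] > ly - m)) return(FALSE)
    }
    TRUE
  }, logical(1))
  kept <- unlist(by_id[keep], use.names = FALSE)
  out <- tr[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  track_set(out, acq)
}
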