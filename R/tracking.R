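# Projection/reslicing track extraction: volumes are max-projected to 2D
# time series, particles detected per frame by threshold + connected
# components + intensity-weighted centroid, then linked frame-to-frame by
# greedy nearest neighbour. Fields here are sparse (tens of particles per
# 356 um field) so greedy linking is adequate; the exact assignment is kept
# as a test oracle only.

#' Maximum-intensity projections of a volume series
#'
#' `project_xyt()` collapses each z-stack along z to an XY image per time
#' point; `project_xzt()` reslices and collapses along y, giving an XZ image
#' per time point in which sinking particles descend.
#'
#' @param volumes 4D array `[y, x, z, t]` as from [render_volume_series()].
#' @return 3D array: `[y, x, t]` (`project_xyt`) or `[z, x, t]`
#'   (`project_xzt`).
#' @export
project_xyt <- function(volumes) {
  if (length(dim(volumes)) != 4) abort("`volumes` must be a 4D [y,x,z,t] array.")
  apply(volumes, c(1, 2, 4), max)
}

#' @rdname project_xyt
#' @export
project_xzt <- function(volumes) {
  if (length(dim(volumes)) != 4) abort("`volumes` must be a 4D [y,x,z,t] array.")
  aperm(apply(volumes, c(2, 3, 4), max), c(2, 1, 3))
}

#' Detect particles in one projected image
#'
#' Threshold (Otsu by default, or an absolute intensity), label connected
#' components, and return the intensity-weighted centroid of each component
#' in physical units. Pixel `[i, j]` (1-based) is centred at
#' ((j-1) px[1], (i-1) px[2]) um, matching [render_volume_series()].
#'
#' @param image 2D numeric matrix `[rows, cols]` (rows = y or z, cols = x).
#' @param threshold `"otsu"` or an absolute intensity on the image scale.
#' @param px Pixel pitch `c(col_um, row_um)`: for XY projections both are
#'   the lateral pitch; for XZ pass `c(lateral, z_step)`.
#' @param min_area Minimum component area in pixels.
#' @return Tibble with `x_um` (columns axis), `y_um` (rows axis — the z
#'   coordinate for XZ projections) and `intensity` (component total). A
#'   blank frame yields zero rows, not an error.
#' @export
detect_particles <- function(image, threshold = "otsu", px = c(1, 1),
                             min_area = 1) {
  stopifnot(is.matrix(image), length(px) == 2)
  empty <- tibble(x_um = numeric(), y_um = numeric(), intensity = numeric())
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(empty)
  img <- EBImage::Image(t(image)) # EBImage dim 1 = x
  if (identical(threshold, "otsu")) {
    scaled <- (img - rng[1]) / diff(rng)
    th <- rng[1] + EBImage::otsu(scaled) * diff(rng)
  } else {
    stopifnot(is.numeric(threshold))
    th <- threshold
  }
  mask <- img > th
  if (sum(mask) == 0) return(empty)
  lab <- EBImage::bwlabel(mask)
  feats <- EBImage::computeFeatures.moment(lab, ref = img)
  if (is.null(feats)) return(empty)
  feats <- as_tibble(feats)
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  tot <- as.vector(tapply(as.numeric(img)[EBImage::imageData(lab) > 0],
                          as.integer(EBImage::imageData(lab))[
                            EBImage::imageData(lab) > 0], sum))
  keep <- areas >= min_area
  tibble(x_um = (feats$m.cx - 1) * px[1],
         y_um = (feats$m.cy - 1) * px[2],
         intensity = tot)[keep, ]
}

#' Detect particles across a projected image series
#'
#' @param images 3D array `[rows, cols, t]` from [project_xyt()] /
#'   [project_xzt()].
#' @inheritParams detect_particles
#' @return Tibble of detections with a 0-based `frame` column.
#' @export
detect_series <- function(images, threshold = "otsu", px = c(1, 1),
                          min_area = 1) {
  stopifnot(length(dim(images)) == 3)
  purrr::map_dfr(seq_len(dim(images)[3]), function(it) {
    d <- detect_particles(images[, , it], threshold = threshold, px = px,
                          min_area = min_area)
    d$frame <- it - 1L
    d
  })
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour association: within each frame, candidate
#' (track end, detection) pairs closer than `max_disp` are accepted in
#' order of increasing distance (ties to the lowest track id); leftover
#' detections seed new tracks. A track end stays eligible for `gap_max`
#' missed frames. The result is invariant to the order of detections
#' within a frame.
#'
#' @param detections Tibble with `frame` (0-based), `x_um`, `y_um` and
#'   optionally `intensity`.
#' @param max_disp Maximum frame-to-frame displacement (um).
#' @param gap_max Maximum number of consecutive missed frames to bridge.
#' @param frame_rate Frames/s used to fill `t_s`.
#' @return Track tibble: `track_id`, `frame`, `t_s`, `x_um`, `y_um`.
#' @export
link_detections <- function(detections, max_disp, gap_max = 2,
                            frame_rate = 15) {
  stopifnot(max_disp > 0, gap_max >= 0)
  det <- dplyr::arrange(detections, .data$frame)
  ends <- data.frame(id = integer(), x = numeric(), y = numeric(),
                     last = integer())
  out <- vector("list", 0)
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    d <- det[det$frame == f, ]
    live <- ends[ends$last >= f - 1L - gap_max, , drop = FALSE]
    assigned_det <- rep(FALSE, nrow(d))
    assigned_trk <- rep(FALSE, nrow(live))
    if (nrow(live) > 0 && nrow(d) > 0) {
      dist <- outer(live$x, d$x_um, "-")^2 + outer(live$y, d$y_um, "-")^2
      dist <- sqrt(dist)
      repeat {
        dist_ok <- dist
        dist_ok[assigned_trk, ] <- Inf
        dist_ok[, assigned_det] <- Inf
        m <- min(dist_ok)
        if (!is.finite(m) || m > max_disp) break
        cand <- which(dist_ok == m, arr.ind = TRUE)
        # ties: smallest distance first (by construction), then lowest id
        cand <- cand[order(live$id[cand[, 1]], cand[, 2]), , drop = FALSE]
        i <- cand[1, 1]; j <- cand[1, 2]
        assigned_trk[i] <- TRUE; assigned_det[j] <- TRUE
        idx <- which(ends$id == live$id[i])
        ends$x[idx] <- d$x_um[j]; ends$y[idx] <- d$y_um[j]
        ends$last[idx] <- f
        out[[length(out) + 1]] <- tibble(track_id = live$id[i], frame = f,
                                         x_um = d$x_um[j], y_um = d$y_um[j])
      }
    }
    for (j in which(!assigned_det)) {
      ends <- rbind(ends, data.frame(id = next_id, x = d$x_um[j],
                                     y = d$y_um[j], last = f))
      out[[length(out) + 1]] <- tibble(track_id = next_id, frame = f,
                                       x_um = d$x_um[j], y_um = d$y_um[j])
      next_id <- next_id + 1L
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$track_id, .data$frame)
  res$t_s <- res$frame / frame_rate
  res[, c("track_id", "frame", "t_s", "x_um", "y_um")]
}

#' Ensemble drift per frame
#'
#' The uniform flow of the sample is the ensemble mean frame-to-frame
#' displacement over all tracks observed in consecutive frames. Lateral
#' drift is estimated and removed before diffusivity estimation; axial
#' drift is the sedimentation signal itself and must never be subtracted.
#'
#' @param tracks Track tibble.
#' @param axes Coordinate columns to estimate drift for (without the
#'   `_um` suffix); lateral by default.
#' @return Tibble `frame`, one displacement column per axis (`dx_um`, ...),
#'   and `n` (tracks contributing). Frames with no concurrent pair get zero
#'   drift; with fewer than 2 contributing tracks everywhere a warning is
#'   raised and zeros returned.
#' @export
estimate_drift <- function(tracks, axes = c("x", "y")) {
  stopifnot(nrow(tracks) > 0)
  cols <- paste0(axes, "_um")
  frames <- sort(unique(tracks$frame))
  d <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cols),
                                ~ .x - dplyr::lag(.x), .names = "d{.col}"),
                  consec = .data$frame - dplyr::lag(.data$frame) == 1) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$consec) & .data$consec)
  if (nrow(d) == 0) {
    warn("No consecutive-frame displacements: drift undefined, returning zeros.")
    out <- tibble(frame = frames[-1])
    for (cc in cols) out[[paste0("d", cc)]] <- 0
    out$n <- 0L
    return(out)
  }
  out <- d |>
    dplyr::group_by(frame = .data$frame) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(paste0("d", cols)), mean),
                     n = dplyr::n())
  missing <- setdiff(frames[-1], out$frame)
  if (length(missing) > 0) {
    pad <- tibble(frame = missing)
    for (cc in cols) pad[[paste0("d", cc)]] <- 0
    pad$n <- 0L
    out <- dplyr::arrange(dplyr::bind_rows(out, pad), .data$frame)
  }
  out
}

#' Subtract estimated drift from tracks
#'
#' Removes the cumulative drift displacement from each coordinate present
#' in `drift`, leaving zero ensemble mean displacement per frame.
#' Subtracting and re-estimating returns (numerically) zero drift.
#'
#' @param tracks Track tibble.
#' @param drift Output of [estimate_drift()].
#' @return Track tibble with drift-corrected coordinates.
#' @export
subtract_drift <- function(tracks, drift) {
  dcols <- grep("^d.*_um$", names(drift), value = TRUE)
  cum <- drift |> dplyr::arrange(.data$frame)
  for (cc in dcols) cum[[cc]] <- cumsum(cum[[cc]])
  out <- tracks
  idx <- match(out$frame, cum$frame)
  for (cc in dcols) {
    target <- sub("^d", "", cc)
    corr <- ifelse(is.na(idx), 0, cum[[cc]][idx])
    out[[target]] <- out[[target]] - corr
  }
  out
}
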