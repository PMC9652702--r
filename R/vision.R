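#' Render a synthetic microscope frame
#'
#' Stand-in for the CCD: particles are drawn as dark disks, virtual
#' electrodes as bright annuli on a mid-grey background, with optional
#' additive Gaussian noise. Intensities live in `[0, 1]`. Pixel (row, col)
#' covers the square `[(col-1), col] x [(row-1), row]` times `pixel_size`
#' um, so a position x um maps to pixel column `x / pixel_size + 0.5`.
#'
#' @param world simulator world ([sim_world()]), or an `oet_scenario`.
#' @param commands optional electrode-command frame ([electrode_command()]);
#'   annuli are drawn from their centres and geometry.
#' @param optics list: `pixel_size` (um/px, default 1), `noise_sd`
#'   (default 0), `background` (0.5), `particle_intensity` (0.15),
#'   `pattern_intensity` (0.9).
#' @param seed optional seed making the noise deterministic.
#' @return Matrix of class `oet_frame` (rows = y) with attributes
#'   `pixel_size` and `timestamp`.
#' @export
render_frame <- function(world, commands = NULL, optics = list(), seed = NULL) {
  if (inherits(world, "oet_scenario")) world <- sim_world(world)
  op <- utils::modifyList(list(pixel_size = 1, noise_sd = 0,
                               background = 0.5, particle_intensity = 0.15,
                               pattern_intensity = 0.9), optics)
  ws <- world$workspace
  ext <- workspace_extent(ws)
  W <- as.integer(round(ext[1] / op$pixel_size))
  H <- as.integer(round(ext[2] / op$pixel_size))
  img <- matrix(op$background, H, W)

  px_of <- function(u, origin) u / op$pixel_size + 0.5  # continuous px coord
  draw_disk <- function(img, cx, cy, r, value) {
    c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
    r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
    if (c0 > c1 || r0 > r1) return(img)
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    img[rows, cols][d2 <= r^2] <- value
    img
  }
  draw_annulus <- function(img, cx, cy, rin, rout, value) {
    c0 <- max(1L, floor(cx - rout)); c1 <- min(W, ceiling(cx + rout))
    r0 <- max(1L, floor(cy - rout)); r1 <- min(H, ceiling(cy + rout))
    if (c0 > c1 || r0 > r1) return(img)
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    sel <- d2 >= rin^2 & d2 <= rout^2
    img[rows, cols][sel] <- value
    img
  }

  if (!is.null(commands) && nrow(commands)) {
    for (k in seq_len(nrow(commands))) {
      cmd <- commands[k, ]
      img <- draw_annulus(img,
                          px_of(cmd$cx - ws$origin[1]),
                          px_of(cmd$cy - ws$origin[2]),
                          cmd$inner_radius / op$pixel_size,
                          (cmd$inner_radius + cmd$width) / op$pixel_size,
                          op$pattern_intensity)
    }
  }
  p <- world$particles
  for (i in seq_len(nrow(p))) {
    ty <- world$types[[p$type[i]]]
    img <- draw_disk(img,
                     px_of(p$x[i] - ws$origin[1]),
                     px_of(p$y[i] - ws$origin[2]),
                     ty$radius / op$pixel_size, op$particle_intensity)
  }
  if (op$noise_sd > 0) {
    add_noise <- function() {
      img + matrix(rnorm(H * W, sd = op$noise_sd), H, W)
    }
    img <- if (is.null(seed)) add_noise() else
      with_local_seed(seed, add_noise())
    img <- pmin(pmax(img, 0), 1)
  }
  structure(img, pixel_size = op$pixel_size, timestamp = world$time,
            class = c("oet_frame", "matrix", "array"))
}

#' Threshold preprocessing for light patterns
#'
#' Isolates the bright (projected light pattern) pixels by a global
#' intensity threshold.
#'
#' @param frame an `oet_frame` (or plain matrix in `[0, 1]`).
#' @param threshold global threshold; pixels strictly above it are "light".
#'   The default 0.7 sits between the background and the rendered pattern
#'   intensity.
#' @return Logical matrix mask.
#' @export
preprocess_light <- function(frame, threshold = 0.7) {
  unclass(frame) > threshold
}

#' Grayscale normalization and Gaussian smoothing for particles
#'
#' Rescales the frame to span `[0, 1]` (constant frames pass through
#' unchanged) and applies separable Gaussian smoothing with edge-
#' renormalised taps, which preserves constants and is shift-equivariant
#' away from the border.
#'
#' @param frame an `oet_frame` or matrix.
#' @param sigma Gaussian standard deviation in px; 0 is the identity.
#' @return Smoothed matrix, same dimensions, attributes preserved.
#' @export
preprocess_particles <- function(frame, sigma = 1) {
  img <- unclass(frame)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  if (sigma > 0) {
    h <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-h:h)^2) / (2 * sigma^2))
    k <- k / sum(k)
    img <- conv_sep(img, k)
  }
  attributes(img) <- attributes(frame)
  img
}

# separable convolution with replicate padding
conv_sep <- function(img, k) {
  h <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  padc <- img[, c(rep(1L, h), seq_len(W), rep(W, h)), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * padc[, t:(t + W - 1L), drop = FALSE]
  padr <- out[c(rep(1L, h), seq_len(H), rep(H, h)), , drop = FALSE]
  out2 <- matrix(0, H, W)
  for (t in seq_along(k)) out2 <- out2 + k[t] * padr[t:(t + H - 1L), , drop = FALSE]
  out2
}

boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(mask & !interior, arr.ind = TRUE)
}

#' Circle detection by Hough accumulation
#'
#' A from-scratch three-parameter (x, y, r) circle Hough transform: the
#' image is binarised (dark disks for particles, bright pixels for light
#' patterns), boundary pixels of the mask vote along circles of each
#' candidate radius, and accumulator peaks above `score_min` (fraction of
#' the maximum attainable votes) become detections. Non-maximum
#' suppression removes any detection closer to a stronger one than the
#' smaller of the two radii, which also collapses the concentric
#' inner/outer edges of an annulus onto one detection. Centres are refined
#' to sub-pixel precision by a 3 x 3 centroid around the accumulator peak.
#'
#' @param image an `oet_frame`/matrix (grayscale) or a logical mask.
#' @param radius_range integer vector of candidate radii in px (e.g.
#'   `4:12`), or length-2 `c(min, max)`.
#' @param kind `"particle"` (vote on dark regions) or `"light_pattern"`
#'   (vote on bright regions). Ignored when `image` is already a mask.
#' @param intensity_threshold binarisation threshold (default 0.35 below
#'   for particles, 0.7 above for light patterns).
#' @param n_angles votes cast per boundary pixel.
#' @param score_min minimum accepted score in `[0, 1]`.
#' @return Data frame of detections: `x_px`, `y_px`, `r_px`, `kind`,
#'   `score` (empty if none).
#' @export
hough_circles <- function(image, radius_range,
                          kind = c("particle", "light_pattern"),
                          intensity_threshold = NULL,
                          n_angles = 72L, score_min = 0.35) {
  kind <- match.arg(kind)
  if (length(radius_range) == 2L) {
    radius_range <- seq(radius_range[1], radius_range[2])
  }
  radii <- sort(unique(as.integer(round(radius_range))))
  if (!length(radii)) stop("radius range must be non-empty")
  mask <- if (is.logical(image)) {
    image
  } else if (kind == "particle") {
    unclass(image) < (intensity_threshold %||% 0.35)
  } else {
    unclass(image) > (intensity_threshold %||% 0.7)
  }
  H <- nrow(mask); W <- ncol(mask)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      r_px = numeric(0), kind = character(0),
                      score = numeric(0))
  edges <- boundary_pixels(mask)
  if (!nrow(edges)) return(empty)
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  ct <- cos(theta); st <- sin(theta)
  cand <- list()
  for (r in radii) {
    cx <- round(rep(edges[, 2], each = n_angles) + r * ct)
    cy <- round(rep(edges[, 1], each = n_angles) + r * st)
    ok <- cx >= 1 & cx <= W & cy >= 1 & cy <= H
    idx <- (cx[ok] - 1L) * H + cy[ok]
    votes <- tabulate(idx, nbins = H * W)
    acc <- matrix(votes, H, W)
    peaks <- which(acc >= score_min * n_angles, arr.ind = TRUE)
    if (!nrow(peaks)) next
    for (q in seq_len(nrow(peaks))) {
      py <- peaks[q, 1]; px <- peaks[q, 2]
      # local maximum only
      r0 <- max(1L, py - 1L):min(H, py + 1L)
      c0 <- max(1L, px - 1L):min(W, px + 1L)
      nb <- acc[r0, c0]
      if (acc[py, px] < max(nb)) next
      wsum <- sum(nb)
      cxr <- sum(rep(c0, each = length(r0)) * nb) / wsum
      cyr <- sum(rep(r0, times = length(c0)) * nb) / wsum
      cand[[length(cand) + 1]] <- data.frame(
        x_px = cxr, y_px = cyr, r_px = r, kind = kind,
        score = acc[py, px] / n_angles)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      d <- sqrt((cand$x_px[i] - cand$x_px[j])^2 +
                  (cand$y_px[i] - cand$y_px[j])^2)
      if (d < min(cand$r_px[i], cand$r_px[j])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Classify detections into size classes by k-means
#'
#' One-dimensional k-means on the detected radii with a deterministic
#' quantile initialisation; labels are renumbered in ascending order of
#' cluster mean radius, so label 1 is always the smallest size class.
#'
#' @param detections detection frame from [hough_circles()] (needs `r_px`).
#' @param k number of size classes (`1 <= k <= nrow(detections)`).
#' @return Integer label vector (1-based) parallel to the detections.
#' @export
classify_particle_sizes <- function(detections, k) {
  r <- detections$r_px
  if (k < 1L || k > length(r)) stop("k must be between 1 and the number of detections")
  if (k == 1L) return(rep(1L, length(r)))
  init <- unname(stats::quantile(r, probs = (seq_len(k) - 0.5) / k, type = 1))
  init <- init + seq(0, 1e-6, length.out = k)   # distinct starting centres
  km <- stats::kmeans(r, centers = matrix(init, ncol = 1))
  relabel <- rank(km$centers[, 1], ties.method = "first")
  as.integer(relabel[km$cluster])
}

#' Screen target particles by proximity to light patterns
#'
#' A particle detection is a manipulation target iff it lies within
#' `threshold` of the centre of some light-pattern detection; each light
#' pattern claims at most one particle (the nearest; ties go to the lower
#' detection index). Everything else is a nontarget.
#'
#' @param particles particle detections (data frame with `x_px`, `y_px`).
#' @param lights light-pattern detections (same columns).
#' @param threshold claiming radius in px (> 0).
#' @return Logical vector: `TRUE` for targets.
#' @export
screen_targets <- function(particles, lights, threshold) {
  stopifnot(threshold > 0)
  n <- nrow(particles)
  target <- logical(n)
  if (!n || !nrow(lights)) return(target)
  claimed <- logical(n)
  for (l in seq_len(nrow(lights))) {
    d <- sqrt((particles$x_px - lights$x_px[l])^2 +
                (particles$y_px - lights$y_px[l])^2)
    d[claimed] <- Inf
    i <- which.min(d)          # lower index wins ties
    if (is.finite(d[i]) && d[i] <= threshold) {
      target[i] <- TRUE
      claimed[i] <- TRUE
    }
  }
  target
}

#' Create an empty multi-object tracker state
#'
#' @param sigma_accel process noise (white acceleration), px/frame^2.
#' @param sigma_meas measurement noise, px.
#' @param gate_px minimum association gate, px.
#' @param miss_limit frames a track may coast unmatched before dying.
#' @return An object of class `oet_tracks`.
#' @export
make_tracker <- function(sigma_accel = 0.5, sigma_meas = 1,
                         gate_px = 15, miss_limit = 5L) {
  structure(list(tracks = list(), next_id = 1L,
                 sigma_accel = sigma_accel, sigma_meas = sigma_meas,
                 gate_px = gate_px, miss_limit = miss_limit),
            class = "oet_tracks")
}

#' Kalman-filter track update
#'
#' Constant-velocity Kalman tracking with stable IDs: every live track is
#' predicted one frame ahead; detections are greedily associated to the
#' nearest predicted position within a gate of
#' `max(gate_px, 3 * predicted sd)`; matched tracks are Kalman-updated
#' (a track matched on its second frame initialises its velocity from the
#' two positions); unmatched detections spawn new tracks; unmatched tracks
#' coast and die after `miss_limit` consecutive misses.
#'
#' @param tracker an `oet_tracks` from [make_tracker()].
#' @param detections data frame with `x_px`, `y_px` (may be empty).
#' @param frame_index integer frame counter (for bookkeeping only).
#' @return The updated `oet_tracks`; element `tracks` holds per-track
#'   `id`, state `x` = (x, y, vx, vy), covariance `P`, `age`, `missed`.
#' @export
update_tracks <- function(tracker, detections, frame_index = NA_integer_) {
  Fm <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
  q <- tracker$sigma_accel^2
  Qm <- q * rbind(c(1 / 4, 0, 1 / 2, 0), c(0, 1 / 4, 0, 1 / 2),
                  c(1 / 2, 0, 1, 0), c(0, 1 / 2, 0, 1))
  Hm <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Rm <- diag(tracker$sigma_meas^2, 2)

  # predict
  preds <- lapply(tracker$tracks, function(tr) {
    tr$x_pred <- as.numeric(Fm %*% tr$x)
    tr$P_pred <- Fm %*% tr$P %*% t(Fm) + Qm
    tr
  })
  nt <- length(preds); nd <- nrow(detections)
  matched_t <- integer(0); matched_d <- integer(0)
  if (nt && nd) {
    D <- matrix(Inf, nt, nd)
    gate <- numeric(nt)
    for (i in seq_len(nt)) {
      S <- Hm %*% preds[[i]]$P_pred %*% t(Hm) + Rm
      gate[i] <- max(tracker$gate_px, 3 * sqrt(max(diag(S))))
      D[i, ] <- sqrt((preds[[i]]$x_pred[1] - detections$x_px)^2 +
                       (preds[[i]]$x_pred[2] - detections$y_px)^2)
    }
    repeat {
      m <- which.min(D)
      if (!length(m) || !is.finite(D[m])) break
      i <- (m - 1) %% nt + 1; j <- (m - 1) %/% nt + 1
      if (D[i, j] <= gate[i]) {
        matched_t <- c(matched_t, i); matched_d <- c(matched_d, j)
      }
      D[i, ] <- Inf; D[, j] <- Inf
    }
  }

  out <- list()
  for (i in seq_len(nt)) {
    tr <- preds[[i]]
    k <- match(i, matched_t)
    if (!is.na(k)) {
      z <- c(detections$x_px[matched_d[k]], detections$y_px[matched_d[k]])
      if (tr$age == 1L) {
        # two-point initialisation: velocity from the first two fixes
        v <- z - tr$x[1:2]
        tr$x <- c(z, v)
        tr$P <- diag(c(tracker$sigma_meas^2, tracker$sigma_meas^2,
                       2 * tracker$sigma_meas^2, 2 * tracker$sigma_meas^2))
      } else {
        S <- Hm %*% tr$P_pred %*% t(Hm) + Rm
        K <- tr$P_pred %*% t(Hm) %*% solve(S)
        tr$x <- as.numeric(tr$x_pred + K %*% (z - Hm %*% tr$x_pred))
        tr$P <- (diag(4) - K %*% Hm) %*% tr$P_pred
        tr$P <- (tr$P + t(tr$P)) / 2
      }
      tr$missed <- 0L
    } else {
      tr$x <- tr$x_pred
      tr$P <- tr$P_pred
      tr$missed <- tr$missed + 1L
    }
    tr$age <- tr$age + 1L
    tr$x_pred <- NULL; tr$P_pred <- NULL
    if (tr$missed <= tracker$miss_limit) out[[length(out) + 1]] <- tr
  }
  if (nd) {
    for (j in setdiff(seq_len(nd), matched_d)) {
      out[[length(out) + 1]] <- list(
        id = tracker$next_id,
        x = c(detections$x_px[j], detections$y_px[j], 0, 0),
        P = diag(c(tracker$sigma_meas^2, tracker$sigma_meas^2, 25, 25)),
        age = 1L, missed = 0L)
      tracker$next_id <- tracker$next_id + 1L
    }
  }
  tracker$tracks <- out
  tracker
}

#' Current track table
#' @param tracker an `oet_tracks`.
#' @return Data frame: `id`, `x_px`, `y_px`, `vx`, `vy`, `age`, `missed`.
#' @export
track_table <- function(tracker) {
  if (!length(tracker$tracks)) {
    return(data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      vx = numeric(0), vy = numeric(0), age = integer(0),
                      missed = integer(0)))
  }
  do.call(rbind, lapply(tracker$tracks, function(tr) {
    data.frame(id = tr$id, x_px = tr$x[1], y_px = tr$x[2],
               vx = tr$x[3], vy = tr$x[4], age = tr$age, missed = tr$missed)
  }))
}

# --- vision-in-the-loop feedback for run_task ------------------------------

vision_state <- function(optics = list(pixel_size = 1, noise_sd = 0.02),
                         cell_size = 15) {
  v <- new.env(parent = emptyenv())
  v$optics <- optics
  # the in-loop tracker sees one frame per control period, i.e. up to a
  # cell-diagonal of motion between fixes; gate accordingly
  gate <- 1.5 * sqrt(2) * cell_size / (optics$pixel_size %||% 1)
  v$tracker <- make_tracker(gate_px = max(15, gate))
  v$assoc <- NULL          # track id -> particle id
  v$last <- NULL           # particle id -> last estimate (um)
  v$frame_index <- 0L
  v
}

# one feedback cycle: render, detect, track, and map stable track ids back
# to particle ids (bootstrapped from the operator-known starting layout)
observe_vision <- function(world, vis) {
  if (is.null(vis)) return(NULL)
  op <- vis$optics
  frame <- render_frame(world, commands = NULL, optics = op,
                        seed = derive_seed(world$time * 1e3 + 7, "frame"))
  sm <- preprocess_particles(frame)
  radii_px <- vapply(world$types, function(t) t$radius / op$pixel_size,
                     numeric(1))
  rng <- seq(max(2L, floor(min(radii_px)) - 1L), ceiling(max(radii_px)) + 1L)
  det <- hough_circles(sm, rng, kind = "particle")
  vis$frame_index <- vis$frame_index + 1L
  vis$tracker <- update_tracks(vis$tracker, det, vis$frame_index)
  tt <- track_table(vis$tracker)
  p <- world$particles
  if (is.null(vis$assoc)) {
    # first frame: bind each track to the nearest known start position
    vis$assoc <- list()
    for (r in seq_len(nrow(tt))) {
      ux <- (tt$x_px[r] - 0.5) * op$pixel_size + world$workspace$origin[1]
      uy <- (tt$y_px[r] - 0.5) * op$pixel_size + world$workspace$origin[2]
      d <- sqrt((p$x - ux)^2 + (p$y - uy)^2)
      vis$assoc[[as.character(tt$id[r])]] <- p$id[which.min(d)]
    }
    vis$last <- setNames(lapply(seq_len(nrow(p)), function(i) c(p$x[i], p$y[i])),
                         as.character(p$id))
  }
  est <- do.call(rbind, vis$last[as.character(p$id)])
  rownames(est) <- as.character(p$id)
  for (r in seq_len(nrow(tt))) {
    pid <- vis$assoc[[as.character(tt$id[r])]]
    if (is.null(pid)) next
    est[as.character(pid), ] <- c(
      (tt$x_px[r] - 0.5) * op$pixel_size + world$workspace$origin[1],
      (tt$y_px[r] - 0.5) * op$pixel_size + world$workspace$origin[2])
  }
  for (key in rownames(est)) vis$last[[key]] <- est[key, ]
  est
}
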