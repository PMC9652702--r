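# small world on a 16 x 16 grid (240 x 240 um -> 240 x 240 px at 1 um/px)
small_world <- function(starts, type_names = rep("bead20", nrow(rbind(starts)))) {
  sc <- make_scenario(starts = rbind(starts),
                      goals = rbind(c(220, 220))[rep(1, 1), , drop = FALSE],
                      type_names = type_names[1],
                      ws = workspace(16, 16, cell_size = 15))
  # make_scenario builds one target; append the rest manually for rendering
  starts <- rbind(starts)
  if (nrow(starts) > 1) {
    for (i in 2:nrow(starts)) {
      sc$particles <- rbind(sc$particles, data.frame(
        id = i, type = type_names[i], x = starts[i, 1], y = starts[i, 2],
        status = "trapped", goal_id = NA_integer_))
      if (!type_names[i] %in% names(sc$types)) {
        sc$types[[type_names[i]]] <- preset_type(type_names[i])
      }
    }
  }
  sim_world(sc)
}

test_that("the renderer draws what the optics see", {
  # empty world, zero noise: constant background
  w <- small_world(c(120, 120))
  w$particles <- w$particles[0, ]
  f <- render_frame(w)
  expect_true(all(f == 0.5))
  expect_identical(dim(unclass(f)), c(240L, 240L))
  # one particle: strict local minimum at its centre pixel
  w2 <- small_world(c(120.5, 120.5))   # centred on a pixel corner-free spot
  f2 <- render_frame(w2)
  expect_equal(unclass(f2)[121, 121], 0.15)
  expect_true(all(f2 >= 0.15))
  # an electrode annulus: maximal intensities exactly on the annulus pixels
  cmd <- electrode_command(1L, c(120.5, 120.5), preset_type("bead20"))
  w3 <- small_world(c(120.5, 120.5))
  w3$particles <- w3$particles[0, ]
  f3 <- render_frame(w3, commands = cmd)
  expect_identical(max(f3), 0.9)
  d2 <- outer((1:240 - 121)^2, (1:240 - 121)^2, `+`)
  on_annulus <- d2 >= 20^2 & d2 <= 35^2
  expect_true(all(unclass(f3)[on_annulus] == 0.9))
  expect_true(all(unclass(f3)[!on_annulus] == 0.5))
})

test_that("light-pattern preprocessing isolates exactly the bright pixels", {
  w <- small_world(c(120.5, 120.5))
  cmd <- electrode_command(1L, c(120.5, 120.5), preset_type("bead20"))
  f <- render_frame(w, commands = cmd)
  mask <- preprocess_light(f)
  expect_identical(unname(mask), unname(unclass(f) == 0.9))
  # constant frame and particles-only frame give empty masks
  expect_false(any(preprocess_light(matrix(0.5, 50, 50))))
  expect_false(any(preprocess_light(render_frame(w))))
})

test_that("particle preprocessing normalizes, smooths, and respects sigma = 0", {
  const <- matrix(0.42, 40, 40)
  expect_equal(unclass(preprocess_particles(const)), const)
  expect_equal(unclass(preprocess_particles(const, sigma = 0)), const)
  # impulse noise: smoothing strictly reduces variance
  set.seed(8)
  noisy <- matrix(0.5, 60, 60)
  noisy[cbind(sample(60, 40, TRUE), sample(60, 40, TRUE))] <- 1
  sm <- preprocess_particles(noisy, sigma = 1.5)
  expect_lt(var(as.numeric(sm)), var(as.numeric((noisy - min(noisy)) /
                                                  diff(range(noisy)))))
})

test_that("preprocessing commutes with translation away from borders", {
  set.seed(4)
  base <- matrix(runif(80 * 80, 0.3, 0.7), 80, 80)
  shift <- 5L
  shifted <- matrix(0.5, 80, 80)
  shifted[(1 + shift):80, (1 + shift):80] <- base[1:(80 - shift), 1:(80 - shift)]
  a <- preprocess_particles(base, sigma = 1)
  b <- preprocess_particles(shifted, sigma = 1)
  inner <- 12:68
  expect_equal(unclass(b)[inner + shift, inner + shift],
               unclass(a)[inner, inner], tolerance = 1e-6)
  m1 <- preprocess_light(base, threshold = 0.6)
  m2 <- preprocess_light(shifted, threshold = 0.6)
  expect_identical(m2[inner + shift, inner + shift], m1[inner, inner])
})

test_that("Hough detection recovers rendered disks to within a pixel", {
  expect_identical(nrow(hough_circles(matrix(0.5, 60, 60), 3:12)), 0L)
  w <- small_world(rbind(c(70.3, 80.7), c(170.2, 160.4)),
                   c("bead20", "bead20"))
  f <- preprocess_particles(render_frame(w), sigma = 1)
  det <- hough_circles(f, 6:14, kind = "particle")
  expect_identical(nrow(det), 2L)
  det <- det[order(det$x_px), ]
  truth <- cbind(c(70.3, 170.2) + 0.5, c(80.7, 160.4) + 0.5)  # um -> px
  expect_lt(max(abs(det$x_px - truth[, 1])), 1)
  expect_lt(max(abs(det$y_px - truth[, 2])), 1)
  expect_lte(max(abs(det$r_px - 10)), 1)
})

test_that("render -> detect round trip holds for particles and electrodes over seeds", {
  for (seed in 1:5) {
    sc <- generate_scenario(
      list(targets = c(bead20 = 3L), pattern = NULL, min_separation = 80,
           workspace = workspace(16, 16, cell_size = 15)),
      seed = seed)
    world <- sim_world(sc)
    cmds <- do.call(rbind, lapply(seq_len(3), function(i) {
      electrode_command(i, c(sc$particles$x[i], sc$particles$y[i]),
                        sc$types$bead20)
    }))
    frame <- render_frame(world, commands = cmds)
    pdet <- hough_circles(preprocess_particles(frame, sigma = 1), 6:14,
                          kind = "particle")
    ldet <- hough_circles(preprocess_light(frame), c(15, 40),
                          kind = "light_pattern")
    expect_identical(nrow(pdet), 3L)
    expect_identical(nrow(ldet), 3L)
    for (i in 1:3) {
      tx <- sc$particles$x[i] + 0.5; ty <- sc$particles$y[i] + 0.5
      dp <- sqrt((pdet$x_px - tx)^2 + (pdet$y_px - ty)^2)
      dl <- sqrt((ldet$x_px - tx)^2 + (ldet$y_px - ty)^2)
      expect_lt(min(dp), 1)
      expect_lt(min(dl), 1)
      # electrode radius snaps to the inner or outer annulus edge
      r <- ldet$r_px[which.min(dl)]
      expect_lte(min(abs(r - 20), abs(r - 35)), 1)
    }
  }
})

test_that("detection survives moderate additive noise", {
  w <- small_world(rbind(c(70.3, 80.7), c(170.2, 160.4)),
                   c("bead20", "bead20"))
  f <- render_frame(w, optics = list(noise_sd = 0.04), seed = 31)
  det <- hough_circles(preprocess_particles(f, sigma = 1.5), 6:14,
                       kind = "particle")
  expect_identical(nrow(det), 2L)
})

test_that("k-means size classes split well-separated radii deterministically", {
  det <- data.frame(r_px = c(5, 5, 10, 10))
  expect_identical(classify_particle_sizes(det, 2), c(1L, 1L, 2L, 2L))
  expect_identical(classify_particle_sizes(det, 1), rep(1L, 4))
  expect_error(classify_particle_sizes(det, 5), "between")
  set.seed(12)
  r <- c(rnorm(25, 5, 0.3), rnorm(25, 10, 0.3))
  lab <- classify_particle_sizes(data.frame(r_px = r), 2)
  expect_identical(lab, rep(1:2, each = 25L))
})

test_that("distance screening claims one particle per light pattern", {
  parts <- data.frame(x_px = c(50, 52, 200), y_px = c(50, 50, 200))
  lights <- data.frame(x_px = 51, y_px = 50)
  tgt <- screen_targets(parts, lights, threshold = 10)
  expect_identical(tgt, c(TRUE, FALSE, FALSE))   # nearest wins
  # equidistant tie goes to the lower detection index
  lights2 <- data.frame(x_px = 51, y_px = 60)
  expect_identical(screen_targets(parts, lights2, threshold = 20),
                   c(TRUE, FALSE, FALSE))
  # farther than the threshold from every pattern: nontarget
  expect_identical(screen_targets(parts, lights, threshold = 0.5),
                   rep(FALSE, 3))
  # a particle centred in an annulus is a target
  expect_identical(screen_targets(data.frame(x_px = 51, y_px = 50), lights, 5),
                   TRUE)
})

test_that("the tracker is exact on noiseless constant-velocity detections", {
  trk <- make_tracker()
  pos <- function(k) data.frame(x_px = c(10 + 2 * k, 100 - 3 * k),
                                y_px = c(10 + k, 100))
  for (k in 0:6) {
    trk <- update_tracks(trk, pos(k), k)
    tt <- track_table(trk)
    if (k >= 2) {
      # after two frames the constant-velocity model matches reality exactly
      expect_equal(sort(tt$x_px), sort(pos(k)$x_px), tolerance = 1e-9)
      expect_equal(sort(tt$vx), c(-3, 2), tolerance = 1e-9)
    }
  }
})

test_that("track identities survive a crossing", {
  trk <- make_tracker()
  # two tracks crossing at frame 10 with distinct velocities
  for (k in 0:20) {
    det <- data.frame(x_px = c(10 + 4 * k, 90 - 4 * k),
                      y_px = c(50 + 0.5 * k, 50 - 0.5 * k))
    if (k %% 2 == 1) det <- det[2:1, ]     # detection order must not matter
    trk <- update_tracks(trk, det, k)
  }
  tt <- track_table(trk)
  expect_identical(nrow(tt), 2L)
  # track 1 started at x = 10 moving +4: it must now be the rightmost
  expect_identical(tt$id[which.max(tt$x_px)], 1L)
  expect_identical(tt$id[which.min(tt$x_px)], 2L)
})

test_that("tracks coast through a missed frame and die after the miss limit", {
  trk <- make_tracker(miss_limit = 3L)
  for (k in 0:3) trk <- update_tracks(trk, data.frame(x_px = 10 + 2 * k, y_px = 20), k)
  # one missing frame: the track coasts and re-associates
  trk <- update_tracks(trk, data.frame(x_px = numeric(0), y_px = numeric(0)), 4)
  expect_identical(track_table(trk)$missed, 1L)
  trk <- update_tracks(trk, data.frame(x_px = 20, y_px = 20), 5)
  tt <- track_table(trk)
  expect_identical(tt$missed, 0L)
  expect_identical(tt$id, 1L)
  # persistent absence kills it
  for (k in 6:9) trk <- update_tracks(trk, data.frame(x_px = numeric(0), y_px = numeric(0)), k)
  expect_identical(nrow(track_table(trk)), 0L)
})

test_that("track-id to particle mapping stays fixed over a 100-frame simulation", {
  # two particles on known curved paths, detections perturbed by pixel noise
  set.seed(77)
  trk <- make_tracker()
  truth <- function(k) rbind(
    c(30 + 1.5 * k, 40 + 10 * sin(k / 15)),
    c(200 - 1.2 * k, 60 + 0.8 * k))
  for (k in 0:99) {
    z <- truth(k) + matrix(rnorm(4, sd = 0.5), 2, 2)
    trk <- update_tracks(trk, data.frame(x_px = z[, 1], y_px = z[, 2]), k)
    tt <- track_table(trk)
    expect_identical(sort(tt$id), 1:2)
    # id 1 must always be the track nearest truth row 1
    d1 <- sqrt((tt$x_px - truth(k)[1, 1])^2 + (tt$y_px - truth(k)[1, 2])^2)
    expect_identical(tt$id[which.min(d1)], 1L)
  }
})

test_that("frames round-trip through PNG at 8-bit precision", {
  w <- small_world(c(120.5, 120.5))
  f <- render_frame(w)
  path <- tempfile(fileext = ".png")
  write_frame(f, path)
  g <- read_frame(path, pixel_size = attr(f, "pixel_size"))
  expect_lt(max(abs(unclass(g) - unclass(f))), 1 / 255)
  expect_identical(dim(unclass(g)), dim(unclass(f)))
})
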