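test_that("Hilbert phase of a cosine advances linearly and ignores DC offsets", {
  t <- seq(0, 500, by = 1)
  om <- 2 * pi / 100
  cfg <- strand_config(N = 16, L = 1)
  movie <- matrix(rep(cos(om * t), each = 16), 16)
  pm <- phase_movie(movie, times = t, config = cfg)
  dph <- cardiofrac:::wrap_pi(diff(pm$phase[1, ]))
  # linear advance at omega per ms (away from the series edges)
  expect_equal(median(dph), om, tolerance = 1e-3)
  pm2 <- phase_movie(movie + 40, times = t, config = cfg)
  expect_equal(pm2$phase, pm$phase, tolerance = 1e-9)
  # constant trace: phase undefined, node masked
  movie[3, ] <- -80
  pm3 <- phase_movie(movie, times = t, config = cfg)
  expect_true(all(is.na(pm3$phase[3, ])))
})

test_that("spiral fixture phase matches its constructed angular form", {
  fx <- make_fixture("spiral_movie", N = 32, dx = 0.1, omega = 2 * pi / 100,
                     k = 1, duration = 400, frame_dt = 2)
  pm <- phase_movie(fx$movie, times = fx$times, config = fx$config)
  # phase at mid-movie equals the analytic phase up to a global rotation:
  # compare phase DIFFERENCES between two off-center nodes
  n1 <- 5 + 15 * 32; n2 <- 28 + 15 * 32
  f <- 100  # frame away from the Hilbert edge artifacts
  xy <- cardiofrac:::node_coords(fx$config)
  ana <- function(n) {
    thr <- atan2(xy$y[n] - fx$center[2], xy$x[n] - fx$center[1])
    r <- sqrt((xy$x[n] - fx$center[1])^2 + (xy$y[n] - fx$center[2])^2)
    # V = A cos(theta - omega t + k r): temporal phase is -(theta + k r) + omega t
    -(thr + 1 * r)
  }
  dph_num <- cardiofrac:::wrap_pi(pm$phase[n1, f] - pm$phase[n2, f])
  dph_ana <- cardiofrac:::wrap_pi(ana(n1) - ana(n2))
  expect_equal(dph_num, dph_ana, tolerance = 0.05)
})

test_that("singularity detection finds spiral tips and ignores plane waves", {
  # planar phase field: zero winding everywhere
  plane <- outer(seq(-pi, pi, length.out = 32), rep(1, 32))
  expect_equal(nrow(find_singularities(plane, 32, 32, 0.1)), 0)
  fx <- make_fixture("spiral_movie", N = 32, dx = 0.1, duration = 300,
                     frame_dt = 2)
  pm <- phase_movie(fx$movie, times = fx$times, config = fx$config)
  tips <- find_singularities(pm$phase[, 75], 32, 32, 0.1)
  expect_equal(nrow(tips), 1)
  # tip localization within one grid spacing of the analytic center
  expect_lt(sqrt((tips$x - fx$center[1])^2 + (tips$y - fx$center[2])^2),
            0.1 * sqrt(2) + 1e-9)
  # mirrored spiral: opposite chirality gives the opposite charge
  fx2 <- make_fixture("spiral_movie", N = 32, dx = 0.1, duration = 300,
                      frame_dt = 2, chirality = -1)
  pm2 <- phase_movie(fx2$movie, times = fx2$times, config = fx2$config)
  tips2 <- find_singularities(pm2$phase[, 75], 32, 32, 0.1)
  expect_equal(nrow(tips2), 1)
  expect_equal(tips2$charge, -tips$charge)
  # total topological charge is conserved across consecutive frames
  charges <- vapply(60:90, function(f)
    sum(find_singularities(pm$phase[, f], 32, 32, 0.1)$charge), numeric(1))
  expect_true(all(charges == charges[1]))
})

test_that("filament linking tracks a persistent tip", {
  fx <- make_fixture("spiral_movie", N = 32, dx = 0.1, duration = 300,
                     frame_dt = 2)
  pm <- phase_movie(fx$movie, times = fx$times, config = fx$config)
  tips <- find_singularities_movie(pm)
  fil <- link_filaments(tips)
  expect_equal(length(unique(fil$track_id)), 1)
  expect_equal(nrow(fil), length(fx$times))
  expect_true(all(diff(fil$t[order(fil$frame)]) > 0))
  # a pinned analytic spiral has zero tip-position variance
  expect_lt(stats::sd(fil$x), 1e-9)
  expect_lt(max_tip_displacement(fil), 1e-9)
  # empty input: no filaments
  expect_equal(nrow(link_filaments(tips[0, ])), 0)
})

test_that("maximal tip displacement equals the brute-force pairwise maximum", {
  expect_equal(max_tip_displacement(tibble::tibble(x = c(0, 3), y = c(0, 4))), 5)
  expect_equal(max_tip_displacement(tibble::tibble(x = 1, y = 2)), 0)
  set.seed(42)
  pts <- tibble::tibble(x = runif(200), y = runif(200))
  brute <- 0
  for (i in 1:199) for (j in (i + 1):200)
    brute <- max(brute, sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2))
  expect_equal(max_tip_displacement(pts), brute)
  # permutation and translation invariance
  perm <- pts[sample(200), ]
  expect_equal(max_tip_displacement(perm), brute)
  expect_equal(max_tip_displacement(dplyr::mutate(pts, x = x + 5, y = y - 2)),
               brute)
})

test_that("rotation counting matches the closed form of the fixture", {
  fx <- make_fixture("spiral_movie", N = 32, dx = 0.1, omega = 2 * pi / 100,
                     duration = 500, frame_dt = 2)
  pm <- phase_movie(fx$movie, times = fx$times, config = fx$config)
  fil <- link_filaments(find_singularities_movie(pm))
  rot <- count_rotations(fil, pm)
  expect_equal(rot, 5, tolerance = 0.1)
  # single-frame filament: zero rotations
  expect_equal(count_rotations(fil[1, ], pm), 0)
})
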