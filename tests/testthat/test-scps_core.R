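test_that("success classifier reproduces hand-computed verdicts on scripted traces", {
  crit <- success_criteria(rmsd_th = 3, e_th = 0.3)
  # monotone descent from 10 to 1 A and staying: success at the first frame < 3
  tr1 <- c(seq(10, 1, length.out = 19), rep(1, 11))
  r1 <- check_success(NULL, NULL, crit, rmsd = tr1)
  expect_true(r1$success)
  expect_identical(r1$first_frame, which(tr1 < 3)[1])
  # never below threshold: failure
  r2 <- check_success(NULL, NULL, crit, rmsd = rep(5, 30))
  expect_false(r2$success)
  # hits 2 A then oscillates to 4 A on half the remaining frames:
  # excursion RMS = sqrt(0.5 * (4-3)^2) = 0.707 > 0.3 -> failure
  tr3 <- c(10, 6, 2, rep(c(4, 2), 20), 4, 4)
  r3 <- check_success(NULL, NULL, crit, rmsd = tr3)
  # direct evaluation of the excursion statistic at the first sub-threshold frame
  n <- which(tr3 < 3)[1]
  rest <- tr3[n:length(tr3)]
  rms <- sqrt(sum(pmax(rest - 3, 0)^2) / length(rest))
  expect_equal(rms, 0.71, tolerance = 0.01)
  expect_false(r3$success)
  # same trace but excursions only barely above threshold: success
  tr4 <- c(10, 6, 2, rep(c(3.1, 2), 20))
  expect_true(check_success(NULL, NULL, crit, rmsd = tr4)$success)
  expect_error(check_success(NULL, NULL, crit, rmsd = numeric(0)), "empty")
  expect_error(success_criteria(rmsd_th = 0.2, e_th = 0.3), "rmsd_th > e_th")
})

test_that("classification is a pure function of the stored trajectory", {
  d <- demo_system("mueller-brown", quick = TRUE)
  ens <- run_ensemble(d$system, d$initial, d$ref, n_traj = 4,
                      config = d$config, bias = "rmd",
                      criteria = d$criteria, seed = 8)
  for (i in seq_along(ens$trajectories)) {
    again <- check_success(ens$trajectories[[i]], d$ref, d$criteria)
    expect_identical(again$success, ens$success[i])
    if (ens$success[i]) expect_identical(again$first_frame, ens$first_frame[i])
  }
})

test_that("mean path is the frame-wise average of successful trajectories only", {
  d <- demo_system("double-well", quick = TRUE)
  ens <- run_ensemble(d$system, d$initial, d$ref, n_traj = 6,
                      config = d$config, bias = "rmd",
                      criteria = d$criteria, seed = 4)
  expect_gt(sum(ens$success), 1)
  mp <- compute_mean_path(ens)
  ok <- which(ens$success)
  # oracle: explicit frame-wise mean
  expected <- Reduce(`+`, lapply(ok, function(i) ens$trajectories[[i]]$frames)) /
    length(ok)
  expect_equal(mp$maps, expected, tolerance = 1e-12)
  # permuting trajectory order leaves the mean path unchanged
  ens2 <- ens
  perm <- rev(seq_along(ens$trajectories))
  ens2$trajectories <- ens2$trajectories[perm]
  ens2$success <- ens2$success[perm]
  expect_equal(compute_mean_path(ens2)$maps, mp$maps)
  # convexity: every entry within [min, max] of contributing entries
  lo <- Reduce(pmin, lapply(ok, function(i) ens$trajectories[[i]]$frames))
  hi <- Reduce(pmax, lapply(ok, function(i) ens$trajectories[[i]]$frames))
  expect_true(all(mp$maps >= lo - 1e-12 & mp$maps <= hi + 1e-12))
  # single successful trajectory: identity
  ens3 <- ens
  ens3$success <- seq_along(ens$success) == ok[1]
  expect_equal(compute_mean_path(ens3)$maps, ens$trajectories[[ok[1]]]$frames)
  # no successes: explicit error
  ens4 <- ens; ens4$success[] <- FALSE
  expect_error(compute_mean_path(ens4), "no successful")
})

test_that("downsampling selects maps nearest to equally spaced z with endpoints kept", {
  # synthetic full path with exactly linear z decay: features shrink linearly
  nfull <- 100
  feat <- sqrt(seq(1, 0, length.out = nfull))   # z = feat^2 decays linearly
  maps <- cbind(feat, 0)
  full <- structure(list(maps = maps, params = NULL, pairs = NULL,
                         n_traj = 1L, system_kind = "surface", lambda = NULL,
                         w_indexed = FALSE, frame_index = seq_len(nfull),
                         downsampled = FALSE),
                    class = "mean_path")
  ds <- downsample_mean_path(full, c(0, 0), n_c = 10)
  expect_identical(ds$frame_index, as.integer(seq(1, 100, by = 11)))
  # endpoints always present
  expect_identical(ds$frame_index[1], 1L)
  expect_identical(ds$frame_index[length(ds$frame_index)], 100L)
  # n_c equal to full length: identity selection
  full2 <- full; full2$maps <- maps[1:10, ]; full2$frame_index <- 1:10
  ds2 <- downsample_mean_path(full2, c(0, 0), n_c = 10)
  expect_identical(ds2$frame_index, 1:10)
  # ordered by decreasing z
  zs <- path_z(ds, c(0, 0))
  expect_true(all(diff(zs) <= 1e-12))
})

test_that("an SCPS iteration on the double well yields successes and a valid path", {
  d <- demo_system("double-well")
  it <- scps_iteration(d$system, d$initial, d$ref, n_traj = 20,
                       config = d$config, criteria = d$criteria, seed = 1)
  expect_gte(sum(it$ensemble$success), 1)
  expect_lte(nrow(it$path$maps), 10)
  expect_gte(nrow(it$path$maps), 2)
  expect_false(is.null(it$path$lambda))
  # endpoints near the ensemble-average start and the target
  expect_lt(sum((it$path$maps[1, ] - d$initial)^2), 0.1)
  expect_lt(sum((it$path$maps[nrow(it$path$maps), ] - d$ref)^2), 0.1)
  # bias mode recorded and both memories present under a loaded path
  tr <- run_trajectory(d$system, d$initial, d$config, bias = "scps",
                       cv = it$path, seed = 2)
  expect_identical(tr$bias, "scps")
  expect_true(all(is.finite(tr$cv$mem1)))
  expect_true(all(is.finite(tr$cv$mem2)))
})

test_that("feeding the same ensemble twice converges immediately", {
  d <- demo_system("double-well", quick = TRUE)
  ens <- run_ensemble(d$system, d$initial, d$ref, n_traj = 5,
                      config = d$config, bias = "rmd",
                      criteria = d$criteria, seed = 6)
  p1 <- set_lambda(downsample_mean_path(compute_mean_path(ens), d$ref, 5))
  expect_identical(path_delta(p1, p1), 0)
})

test_that("the SCPS transition channel is stable across iterations on the double well", {
  d <- demo_system("double-well")
  hist <- run_scps(d$system, d$initial, d$ref, n_traj = 20,
                   config = d$config, max_iterations = 2,
                   criteria = d$criteria, seed = 3)
  expect_identical(length(hist$iterations), 2L)
  expect_true(all(is.finite(hist$trace[-1])))
  # channel indicator: sign of y when first crossing x = 0
  channel <- function(ens) {
    vapply(which(ens$success), function(i) {
      fr <- ens$trajectories[[i]]$frames
      k <- which(fr[, 1] > 0)[1]
      sign(fr[k, 2])
    }, numeric(1))
  }
  c1 <- channel(hist$iterations[[1]]$ensemble)
  c2 <- channel(hist$iterations[[2]]$ensemble)
  if (length(unique(c(c1, c2))) == 1) {
    # both iterations unanimously use the same channel: trivially stable
    expect_identical(unique(c1), unique(c2))
  } else {
    tab <- rbind(table(factor(c1, c(-1, 1))), table(factor(c2, c(-1, 1))))
    suppressWarnings(p <- chisq.test(tab)$p.value)
    expect_gt(p, 0.01)
  }
})
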