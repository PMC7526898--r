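test_that("contact function reproduces limit values and the hard cutoff", {
  pr <- function(r) as.numeric(contact_map(rbind(c(0, 0, 0), c(r, 0, 0), c(100, 100, 100), c(200, 200, 200)),
                                contact_map_params(min_separation = 1))$values[1])
  expect_equal(pr(1e-9), 1, tolerance = 1e-9)      # r -> 0 limit
  expect_equal(pr(7.5), 0.6)                        # removable singularity = 3/5
  # numerical cross-check just off the singularity
  expect_equal(pr(7.5 * (1 + 1e-6)), 0.6, tolerance = 1e-5)
  expect_equal(pr(7.5 * (1 - 1e-6)), 0.6, tolerance = 1e-5)
  expect_identical(pr(13), 0)                       # beyond r_c = 12: exactly 0
  expect_identical(pr(12.000001), 0)
})

test_that("contact function is strictly decreasing on (0, r_c)", {
  rs <- seq(0.5, 11.9, by = 0.1)
  vals <- vapply(rs, function(r)
    as.numeric(contact_map(rbind(c(0, 0, 0), c(r, 0, 0), c(50, 50, 50), c(90, 90, 90)),
                contact_map_params(min_separation = 1))$values[1]), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("contact map matches the brute-force double-loop oracle", {
  X <- random_config(12, seed = 301)
  p <- contact_map_params()
  cm <- contact_map(X, p)
  expect_equal(cm$values, contact_oracle(X, cm$pairs), tolerance = 1e-12)
})

test_that("z is zero at the reference, counts single-pair differences, and matches oracles", {
  X <- random_config(12, sd = 5, seed = 42)
  p <- contact_map_params()
  ref <- reference_structure(X, p)
  expect_equal(z_of(X, ref)$value, 0)
  # single differing feature of size 1 -> z = 1
  a <- ref$map$values
  b <- a; b[3] <- b[3] + 1
  expect_equal(cm_distance(a, b), 1)
  # random configuration: brute force + finite differences
  Y <- random_config(12, sd = 5, seed = 43)
  zg <- z_of(Y, ref)
  z_brute <- sum((contact_oracle(Y, ref$map$pairs) - ref$map$values)^2)
  expect_equal(zg$value, z_brute, tolerance = 1e-10)
  fd <- fd_gradient(function(Xi) z_of(Xi, ref)$value, Y)
  expect_lt(max(abs(zg$gradient - fd)) / max(abs(fd)), 1e-5)
})

test_that("z and cm_distance are invariant under rigid transforms", {
  X <- random_config(10, seed = 7)
  p <- contact_map_params()
  ref <- reference_structure(random_config(10, seed = 8), p)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Xr <- X %*% R + matrix(c(3, -2, 5), nrow(X), 3, byrow = TRUE)
  expect_equal(z_of(Xr, ref)$value, z_of(X, ref)$value, tolerance = 1e-9)
  expect_equal(cm_distance(contact_map(Xr, p), contact_map(X, p)), 0,
               tolerance = 1e-12)
})

test_that("cm_distance is symmetric, zero iff equal, and matches a loop", {
  a <- runif(20); b <- runif(20)
  expect_equal(cm_distance(a, b), cm_distance(b, a))
  expect_identical(cm_distance(a, a), 0)
  expect_equal(cm_distance(a, b), sum((a - b)^2))
  # differing in two entries by 0.5 each -> 0.5
  b2 <- a; b2[c(2, 9)] <- b2[c(2, 9)] + 0.5
  expect_equal(cm_distance(a, b2), 0.5)
  expect_error(cm_distance(a, b[1:5]), "different length")
})

test_that("s_lambda endpoint contract and softmax midpoint hold at large lambda", {
  # synthetic 10-map path in feature space
  set.seed(11)
  maps <- outer(seq(0, 1, length.out = 10), runif(25, 0.2, 1))
  path <- structure(list(maps = maps, params = NULL, pairs = NULL,
                         n_traj = 1L, system_kind = "beads", lambda = NULL,
                         w_indexed = FALSE, frame_index = 1:10,
                         downsampled = TRUE),
                    class = "mean_path")
  path <- set_lambda(path)
  lam_big <- 100 / mean(vapply(1:9, function(k)
    sum((maps[k, ] - maps[k + 1, ])^2), numeric(1)))
  expect_equal(s_lambda(maps[10, ], path, lambda = lam_big), 0, tolerance = 1e-6)
  expect_equal(s_lambda(maps[1, ], path, lambda = lam_big), 1, tolerance = 1e-6)
  # monotone non-increasing along the path at large lambda
  svals <- vapply(1:10, function(k) s_lambda(maps[k, ], path, lambda = lam_big),
                  numeric(1))
  expect_true(all(diff(svals) <= 1e-9))
  # equidistant from maps 4 and 5, far from others -> midpoint of their values
  mid <- (maps[4, ] + maps[5, ]) / 2
  s_mid <- s_lambda(mid, path, lambda = lam_big)
  s4 <- s_lambda(maps[4, ], path, lambda = lam_big)
  s5 <- s_lambda(maps[5, ], path, lambda = lam_big)
  expect_equal(s_mid, (s4 + s5) / 2, tolerance = 1e-6)
})

test_that("w_lambda converges to the nearest-map distance and obeys the two-map closed form", {
  set.seed(12)
  maps <- outer(seq(0, 1, length.out = 8), runif(30, 0.2, 1))
  path <- structure(list(maps = maps, params = NULL, pairs = NULL,
                         n_traj = 1L, system_kind = "beads", lambda = NULL,
                         w_indexed = FALSE, frame_index = 1:8,
                         downsampled = TRUE),
                    class = "mean_path")
  x <- runif(30)
  dists <- vapply(1:8, function(k) sum((x - maps[k, ])^2), numeric(1))
  lam_big <- 2000 / min(dists)
  expect_equal(-w_lambda(x, path, lambda = lam_big), min(dists),
               tolerance = 1e-6 * min(dists))
  # on a map: -w -> 0
  expect_equal(-w_lambda(maps[3, ], path, lambda = lam_big), 0, tolerance = 1e-8)
  # two equidistant maps, others negligible: w = ln(2)/lambda - d
  m2 <- rbind(rep(0, 5), rep(1, 5))
  path2 <- structure(list(maps = m2, params = NULL, pairs = NULL,
                          n_traj = 1L, system_kind = "beads", lambda = NULL,
                          w_indexed = FALSE, frame_index = 1:2,
                          downsampled = TRUE),
                     class = "mean_path")
  xm <- rep(0.5, 5)
  d <- sum((xm - m2[1, ])^2)
  lam <- 3.7
  expect_equal(w_lambda(xm, path2, lambda = lam), log(2) / lam - d,
               tolerance = 1e-10)
})

test_that("path CV gradients match finite differences on bead configurations", {
  set.seed(99)
  X0 <- random_config(9, sd = 4)
  p <- contact_map_params()
  pairs <- eligible_pairs(9, p)
  maps <- t(vapply(1:6, function(k)
    contact_map(random_config(9, sd = 4), p)$values, numeric(nrow(pairs))))
  path <- structure(list(maps = maps, params = p, pairs = pairs,
                         n_traj = 1L, system_kind = "beads", lambda = 2.5,
                         w_indexed = FALSE, frame_index = 1:6,
                         downsampled = TRUE),
                    class = "mean_path")
  sg <- s_lambda(X0, path)
  wg <- w_lambda(X0, path)
  fd_s <- fd_gradient(function(Xi) s_lambda(Xi, path)$value, X0)
  fd_w <- fd_gradient(function(Xi) w_lambda(Xi, path)$value, X0)
  expect_lt(max(abs(sg$gradient - fd_s)) / max(abs(fd_s)), 1e-5)
  expect_lt(max(abs(wg$gradient - fd_w)) / max(abs(fd_w)), 1e-5)
  # the indexed Eq-8 variant stays differentiable and consistent
  path$w_indexed <- TRUE
  wg2 <- w_lambda(X0, path)
  fd_w2 <- fd_gradient(function(Xi) w_lambda(Xi, path)$value, X0)
  expect_lt(max(abs(wg2$gradient - fd_w2)) / max(abs(fd_w2)), 1e-5)
})

test_that("set_lambda uses the reciprocal mean neighbor distance with a floor", {
  maps <- matrix(0, 4, 6)
  maps[2, 1] <- sqrt(0.5); maps[3, 1] <- sqrt(0.5) * 2; maps[4, 1] <- sqrt(0.5) * 3
  path <- structure(list(maps = maps, params = NULL, pairs = NULL,
                         n_traj = 1L, system_kind = "beads", lambda = NULL,
                         w_indexed = FALSE, frame_index = 1:4,
                         downsampled = TRUE),
                    class = "mean_path")
  expect_equal(set_lambda(path)$lambda, 2)           # all neighbor dists 0.5
  expect_equal(set_lambda(path, mode = "literal")$lambda, 0.5)
  # brute-force reciprocal mean on a random path
  set.seed(5)
  maps2 <- matrix(runif(60), 10, 6)
  path2 <- path; path2$maps <- maps2; path2$frame_index <- 1:10
  nd <- vapply(1:9, function(k) sum((maps2[k, ] - maps2[k + 1, ])^2), numeric(1))
  expect_equal(set_lambda(path2)$lambda, 1 / mean(nd))
  # degenerate path floors lambda with a warning
  pdg <- path; pdg$maps <- matrix(0.3, 3, 6); pdg$frame_index <- 1:3
  expect_warning(pdg <- set_lambda(pdg), "degenerate")
  expect_equal(pdg$lambda, 1e12)
})
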