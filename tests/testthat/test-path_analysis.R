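test_that("contact formation times follow the persistence rule", {
  # distance trace matrix: frames x contacts
  mk <- function(frames_in) { d <- rep(10, 30); d[frames_in] <- 5; d }
  D <- cbind(mk(7:11),          # exactly 5 consecutive from frame 7
             mk(c(3:6, 20:23)), # only 4-frame runs: never formed
             mk(c(3:5, 10:20))) # runs at 3-5 and 10-20 -> forms at 10
  t5 <- contact_formation_times(D, persistence = 5, threshold = 7.5)
  expect_identical(t5, c(7L, NA_integer_, 10L))
  # short trajectory: all sentinels with a warning
  expect_warning(ts <- contact_formation_times(D[1:3, ], persistence = 5),
                 "shorter than the persistence")
  expect_true(all(is.na(ts)))
})

test_that("order matrix encodes pairwise formation order with ties at 1/2", {
  om <- order_matrix(c(1, 2, 3))
  expect_true(all(om$M[upper.tri(om$M)] == 1))
  om2 <- order_matrix(c(2, 2, 5))
  expect_identical(om2$M[1, 2], 0.5)
  # brute-force oracle on a random vector
  set.seed(61)
  tv <- sample(10, 6, replace = TRUE)
  om3 <- order_matrix(tv)
  for (i in 1:5) for (j in (i + 1):6) {
    expected <- if (tv[i] < tv[j]) 1 else if (tv[i] > tv[j]) 0 else 0.5
    expect_identical(om3$M[i, j], expected)
  }
})

test_that("path similarity is 1 on identical order, 0 on reversed, 2/3 on the 3-contact example", {
  a <- order_matrix(1:10)
  b <- order_matrix(10:1)
  expect_identical(path_similarity(a, a), 1)
  expect_identical(path_similarity(a, b), 0)
  expect_equal(path_similarity(order_matrix(c(1, 2, 3)),
                               order_matrix(c(1, 3, 2))), 2 / 3)
})

test_that("path similarity is symmetric and bounded on random inputs; missing contacts excluded", {
  set.seed(71)
  for (i in 1:25) {
    a <- order_matrix(runif(8))
    b <- order_matrix(runif(8))
    s <- path_similarity(a, b)
    expect_identical(s, path_similarity(b, a))
    expect_true(s >= 0 && s <= 1)
  }
  # never-formed contact: pairs involving it are excluded from the average
  a2 <- order_matrix(c(1, 2, NA))
  b2 <- order_matrix(c(1, 2, 3))
  expect_identical(path_similarity(a2, b2), 1)   # only pair (1,2) evaluable
})

test_that("similarity distributions: identical ensembles concentrate A at 1; random mean matches enumeration", {
  oms <- lapply(1:4, function(i) order_matrix(c(1, 5, 9, 12)))
  sd1 <- similarity_distributions(oms, n_random_sets = 1, seed = 2)
  expect_true(all(sd1$A == 1))
  # reference vs itself as query: R contains the A samples (self-pairs excluded)
  sd2 <- similarity_distributions(oms, query = oms, n_random_sets = 1, seed = 2)
  expect_identical(length(sd2$R), 4L * 3L)
  expect_true(all(sd2$R == 1))
  # with 3 contacts, the mean similarity against random orders approaches the
  # exhaustive average over all 6 permutations of distinct times
  ref <- list(order_matrix(c(1, 2, 3)))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  exact <- mean(vapply(perms, function(p)
    path_similarity(ref[[1]], order_matrix(p)), numeric(1)))
  sd3 <- similarity_distributions(ref, n_random = 3000, n_random_sets = 1,
                                  seed = 3)
  expect_equal(mean(sd3$R_r[[1]]), exact, tolerance = 0.03)
})

test_that("KL divergence: zero on identical input, exact two-bin value, non-negative", {
  x <- runif(200)
  expect_identical(kl_divergence(x, x), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75), masses = TRUE),
               0.5 * log2(2) + 0.5 * log2(0.5 / 0.75), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75), masses = TRUE),
               0.2075, tolerance = 1e-4)
  set.seed(81)
  for (i in 1:20) {
    a <- runif(150); b <- runif(150)^2
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_error(kl_divergence(numeric(0), runif(5)), "empty")
})

test_that("reactive segments start at the last frame below the low threshold", {
  # monotone crossing
  q1 <- seq(0, 1, length.out = 21)
  seg1 <- reactive_segments(q1)
  expect_identical(length(seg1), 1L)
  expect_identical(seg1[[1]][["start"]], max(which(q1 < 0.1)))
  expect_identical(seg1[[1]][["end"]], min(which(q1 > 0.9)))
  # flat trace: no events
  expect_identical(length(reactive_segments(rep(0.5, 50))), 0L)
  # scripted two folding events + one unfolding event
  q3 <- c(0.05, 0.5, 0.95,      # fold 1: start 1, end 3
          0.5, 0.05,            # unfold (reversed: 3..5)
          0.07, 0.96)           # fold 2: start 6, end 7
  segs <- reactive_segments(q3, unfolding = TRUE)
  dirs <- vapply(segs, attr, character(1), "direction")
  expect_identical(sum(dirs == "folding"), 2L)
  expect_identical(sum(dirs == "unfolding"), 1L)
  folds <- segs[dirs == "folding"]
  expect_identical(folds[[1]][["start"]], 1L)
  expect_identical(folds[[2]][["start"]], 6L)
  unf <- segs[dirs == "unfolding"][[1]]
  expect_identical(unname(unf[1]), 3L)   # time-reversed interval bounds
  expect_identical(unname(unf[2]), 5L)
})

test_that("landscape histogram normalizes, matches counting, and -ln P is 0 for a single bin", {
  one <- landscape_histogram(matrix(c(0.5, 0.5), 1, 2), bins = 5)
  expect_equal(sum(one$P), 1)
  expect_identical(max(one$P), 1)
  expect_identical(one$G[which.max(one$P)], 0)
  # counting oracle on a scripted sample set
  set.seed(91)
  xy <- cbind(runif(500), runif(500))
  br <- list(seq(0, 1, length.out = 6), seq(0, 1, length.out = 6))
  lh <- landscape_histogram(xy, bins = br)
  ix <- findInterval(xy[, 1], br[[1]], rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2], br[[2]], rightmost.closed = TRUE, all.inside = TRUE)
  expect_equal(lh$P, unclass(table(factor(ix, 1:5), factor(iy, 1:5))) / 500,
               ignore_attr = TRUE)
  expect_equal(sum(lh$P), 1)
  # uniform masses -> constant G on occupied bins
  u <- landscape_histogram(cbind(rep(1:3 / 4, 9), rep(1:3 / 4, each = 9)),
                           bins = list(c(0, .3, .6, 1), c(0, .3, .6, 1)))
  expect_lt(diff(range(u$G[u$P > 0])), 1e-12)
})

test_that("PCA of contact maps matches an eigendecomposition and normalizes set contributions", {
  # build a tiny synthetic ensemble object around scripted frames
  set.seed(101)
  hp <- build_toy_hairpin()
  m <- build_go_model(hp)
  d <- demo_system("hairpin", quick = TRUE)
  cfg <- d$config; cfg$n_steps <- 3000L; cfg$save_stride <- 20L
  ens <- run_ensemble(m, extended_configuration(m), d$ref, n_traj = 2,
                      config = cfg, bias = "rmd", criteria = d$criteria,
                      seed = 3)
  ens$success <- rep(TRUE, 2)   # analyze all frames regardless of outcome
  pairs <- m$native_pairs
  labs <- ifelse(pairs[, 2] - pairs[, 1] > 6, "long-range", "local")
  suppressWarnings(
    pca <- pca_contact_maps(ens, pairs, set_labels = labs, downsample = 500))
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_equal(colSums(pca$set_contributions), rep(1, 2), ignore_attr = TRUE)
  # oracle: covariance eigendecomposition reproduces loadings up to sign
  feats <- do.call(rbind, lapply(1:2, function(i)
    scps:::cpp_contact_frames(ens$trajectories[[i]]$frames,
                              pairs[, 1] - 1L, pairs[, 2] - 1L, 7.5, 12)))
  keep <- apply(feats, 2, var) > 0
  ev <- eigen(cov(feats[, keep]))
  lo <- pca$loadings[, 1]
  expect_equal(abs(sum(lo * ev$vectors[, 1])), 1, tolerance = 1e-6)
  # single varying feature: PC1 carries all variance and its set everything
  base <- matrix(0.5, 40, 6)
  base[, 3] <- seq(0, 1, length.out = 40)
  pc2 <- prcomp(base, center = TRUE)
  expect_equal(pc2$sdev[1]^2 / sum(pc2$sdev^2), 1, tolerance = 1e-12)
})

test_that("incorporation order is invariant under trajectory reordering", {
  d <- demo_system("hairpin", quick = TRUE)
  m <- d$model
  cfg <- d$config; cfg$n_steps <- 6000L
  ens <- run_ensemble(m, extended_configuration(m), d$ref, n_traj = 3,
                      config = cfg, bias = "rmd", criteria = d$criteria,
                      seed = 5)
  ens$success <- rep(TRUE, 3)
  inc1 <- incorporation_order(ens, m)
  ens2 <- ens
  ens2$trajectories <- ens2$trajectories[c(3, 1, 2)]
  inc2 <- incorporation_order(ens2, m)
  expect_equal(inc1$median_q, inc2$median_q)
  # residues without native contacts are flagged and excluded
  untouched <- setdiff(seq_len(m$n), sort(unique(c(m$native_pairs))))
  if (length(untouched)) {
    expect_warning(incorporation_order(ens, m,
                                       residues = c(untouched[1], 3)),
                   "zero native contacts")
  } else {
    m2 <- m
    m2$native_pairs <- m$native_pairs[m$native_pairs[, 1] != 1 &
                                      m$native_pairs[, 2] != 1, , drop = FALSE]
    m2$native_distances <- m$native_distances[m$native_pairs[, 1] != 1 &
                                              m$native_pairs[, 2] != 1]
    expect_warning(incorporation_order(ens, m2, residues = c(1, 3)),
                   "zero native contacts")
  }
})
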