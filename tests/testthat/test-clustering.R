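gfp_shaped_epoch <- function(shape, map, fs = 200) {
  # columns are `map` scaled by shape (map has unit spatial SD)
  eeg_epoch(outer(map / sqrt(mean((map - mean(map))^2)), shape), fs)
}

test_that("peak-map extraction collects maps at GFP maxima with provenance", {
  m <- prototype_maps()["A", ]
  ep <- gfp_shaped_epoch(c(0, 1, 0, 1, 0), m)
  pk <- extract_peak_maps(list(ep))
  expect_equal(nrow(pk$maps), 2)
  expect_equal(pk$sample, c(2L, 4L))
  expect_equal(pk$gfp, c(1, 1))
  # concatenation across epochs: total = sum of per-epoch counts
  ep2 <- gfp_shaped_epoch(c(0, 2, 0, 3, 0, 1, 0), m)
  both <- extract_peak_maps(list(ep, ep2))
  expect_equal(nrow(both$maps), 2 + 3)
  expect_equal(both$epoch, c(1L, 1L, 2L, 2L, 2L))
  expect_error(extract_peak_maps(list(gfp_shaped_epoch(c(0, 1, 2), m))),
               "no GFP peaks")
})

test_that("a noise-free 2.56 s single-state epoch yields ~51 peak maps", {
  cfg <- synth_config(snr = Inf, seed = 1)
  s <- tibble::tibble(class = "A", n_samples = 512L, duration_ms = 2560,
                      drawn_ms = 2560)
  withr::with_seed(3, ep <- render_epoch(s, prototype_maps(), cfg))
  pk <- extract_peak_maps(list(ep))
  expect_equal(nrow(pk$maps), 51)
})

test_that("spatial correlation behaves as a polarity-carrying cosine", {
  p <- prototype_maps()
  expect_equal(spatial_correlation(p["A", ], p["A", ]), 1)
  expect_equal(spatial_correlation(p["A", ], -p["A", ]), -1)
  m <- montage_1020()
  # left-right vs anterior-posterior gradients are orthogonal on the
  # symmetric montage
  expect_lt(abs(spatial_correlation(m$x, m$y)), 1e-10)
  expect_error(spatial_correlation(rep(1, 16), p["A", ]), "zero-variance")
})

test_that("k=1 clustering of polarity-flipped copies of one map recovers it exactly", {
  set.seed(5)
  base <- prototype_maps()["C", ]
  signs <- sample(c(-1, 1), 20, replace = TRUE)
  maps <- outer(signs, base)
  pk <- make_peaks(maps, runif(20, 0.5, 2))
  fit <- modified_kmeans(pk, k = 1, n_restarts = 3, seed = 1)
  expect_equal(abs(spatial_correlation(fit$templates[1, ], base)), 1,
               tolerance = 1e-9)
  expect_equal(fit$gev, 1, tolerance = 1e-12)
})

test_that("two orthogonal templates with random polarity are recovered exactly at k=2", {
  m <- montage_1020()
  t1 <- m$x - mean(m$x); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- m$y - mean(m$y); t2 <- t2 / sqrt(sum(t2^2))
  set.seed(8)
  which_t <- sample(1:2, 30, replace = TRUE)
  signs <- sample(c(-1, 1), 30, replace = TRUE)
  maps <- rbind(outer(rep(1, 30), t1), outer(rep(1, 30), t2))[
    ifelse(which_t == 1, 1:30, 31:60), ] * signs
  pk <- make_peaks(maps, runif(30, 0.5, 2))
  fit <- modified_kmeans(pk, k = 2, n_restarts = 10, seed = 2)
  cors <- abs(fit$templates %*% cbind(t1, t2))
  expect_true(all(apply(cors, 2, max) > 1 - 1e-9))
  expect_equal(fit$gev, 1, tolerance = 1e-9)
})

test_that("modified K-means attains the exhaustive-assignment optimum on small instances", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(5:8, 1)
    maps <- matrix(rnorm(n * 16), n, 16)
    pk <- make_peaks(maps, runif(n, 0.5, 2))
    fit <- modified_kmeans(pk, k = 2, n_restarts = 100, seed = s)
    expect_equal(fit$gev, brute_force_gev(pk, k = 2), tolerance = 1e-9)
  }
})

test_that("GEV equals the explicit term-by-term sum and hits its 0/1 extremes", {
  p <- prototype_maps()
  # maps exactly equal to (+/-) their assigned template -> GEV 1
  set.seed(2)
  lab <- sample(1:4, 12, replace = TRUE)
  signs <- sample(c(-1, 1), 12, replace = TRUE)
  maps <- p[lab, ] * signs
  pk <- make_peaks(maps, runif(12, 0.5, 3))
  expect_equal(compute_gev(pk, p, lab), 1, tolerance = 1e-12)
  # orthogonal-template assignment -> GEV 0
  m <- montage_1020()
  xg <- m$x - mean(m$x)
  yg <- m$y - mean(m$y)
  pk2 <- make_peaks(outer(rep(1, 5), xg), rep(1, 5))
  tmpl <- rbind(xg / sqrt(sum(xg^2)), yg / sqrt(sum(yg^2)))
  expect_equal(compute_gev(pk2, tmpl, rep(2L, 5)), 0, tolerance = 1e-12)
  # random instance vs direct summation oracle
  set.seed(9)
  maps3 <- matrix(rnorm(7 * 16), 7, 16)
  gfp3 <- runif(7, 0.5, 2)
  pk3 <- make_peaks(maps3, gfp3)
  lab3 <- sample(1:2, 7, replace = TRUE)
  num <- sum(sapply(1:7, function(i) {
    (gfp3[i] * spatial_correlation(pk3$maps[i, ], tmpl[lab3[i], ]))^2
  }))
  expect_equal(compute_gev(pk3, tmpl, lab3), num / sum(gfp3^2),
               tolerance = 1e-12)
})

test_that("clustering is invariant to polarity flips and map order", {
  set.seed(12)
  # three well-separated clusters (noisy prototypes) so every restart finds
  # the same optimum and GEV comparisons are exact
  p <- prototype_maps()
  maps <- p[sample(1:3, 25, replace = TRUE), ] + 0.15 * matrix(rnorm(25 * 16), 25, 16)
  gfp <- runif(25, 0.5, 2)
  pk <- make_peaks(maps, gfp)
  fit <- modified_kmeans(pk, k = 3, n_restarts = 10, seed = 4)

  flip <- sample(c(-1, 1), 25, replace = TRUE)
  pk_flip <- make_peaks(maps * flip, gfp)
  fit_flip <- modified_kmeans(pk_flip, k = 3, n_restarts = 10, seed = 4)
  expect_equal(fit_flip$labels, fit$labels)
  expect_equal(fit_flip$gev, fit$gev, tolerance = 1e-12)
  tmpl_cor <- abs(diag(fit$templates %*% t(fit_flip$templates)))
  expect_true(all(tmpl_cor > 1 - 1e-9))

  perm <- sample(25)
  pk_perm <- make_peaks(maps[perm, ], gfp[perm])
  fit_perm <- modified_kmeans(pk_perm, k = 3, n_restarts = 10, seed = 4)
  expect_equal(fit_perm$gev, fit$gev, tolerance = 1e-9)
})

test_that("GEV is non-decreasing across iterations of the winning restart", {
  set.seed(31)
  for (i in 1:5) {
    maps <- matrix(rnorm(40 * 16), 40, 16)
    pk <- make_peaks(maps, runif(40, 0.5, 2))
    fit <- modified_kmeans(pk, k = 4, n_restarts = 5, seed = i)
    expect_true(all(diff(fit$gev_trace) >= -1e-12))
  }
})

test_that("clustering a synthetic subject at snr 5 recovers all four planted prototypes", {
  cfg <- synth_config(n_subjects_per_group = 1, epochs_per_subject = 12,
                      snr = 5, seed = 19)
  coh <- generate_cohort(cfg)
  prep <- lapply(coh$epochs[[1]], function(e) average_reference(bandpass_filter(e)))
  fit <- modified_kmeans(extract_peak_maps(prep), seed = 6)
  p <- prototype_maps()
  cors <- abs(fit$templates %*% t(unclass(p)))
  best <- apply(cors, 1, which.max)
  expect_equal(sort(unname(best)), 1:4) # distinct prototypes
  expect_true(all(apply(cors, 1, max) >= 0.9))
})
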