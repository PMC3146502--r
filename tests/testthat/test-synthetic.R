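test_that("config validation rejects bad transition matrices and SNR", {
  tm_bad <- matrix(0.25, 4, 4)
  expect_error(synth_config(transition_matrix = tm_bad), "diagonal")
  expect_error(synth_config(snr = 0), "snr")
  expect_error(synth_config(class_mean_duration_ms = -default_duration_means()))
})

test_that("degenerate transition matrix forces strict A/B alternation", {
  tm <- matrix(0, 4, 4, dimnames = list(MS <- c("A", "B", "C", "D"), MS))
  tm["A", "B"] <- 1; tm["B", "A"] <- 1; tm["C", "A"] <- 1; tm["D", "A"] <- 1
  cfg <- synth_config(transition_matrix = tm, seed = 3)
  withr::with_seed(3, {
    s <- sample_state_sequence(cfg, "patient")
  })
  cls <- s$class[-1] # after the random start, only A/B alternate
  expect_true(all(cls %in% c("A", "B")))
  expect_true(all(cls[-1] != cls[-length(cls)]))
})

test_that("successive planted classes always differ and fill the epoch exactly", {
  cfg <- quick_config()
  withr::with_seed(9, {
    for (i in 1:20) {
      s <- sample_state_sequence(cfg, "control")
      expect_equal(sum(s$n_samples), cfg$epoch_samples)
      expect_true(all(s$class[-1] != s$class[-nrow(s)]))
    }
  })
})

test_that("drawn durations follow the lower-truncated normal (Monte-Carlo vs analytic mean)", {
  cfg <- synth_config(seed = 5)
  draws <- list(patient = c(), control = c())
  withr::with_seed(17, {
    while (length(draws$patient) < 10000) {
      for (g in c("patient", "control")) {
        s <- sample_state_sequence(cfg, g)
        draws[[g]] <- c(draws[[g]], s$drawn_ms[s$class == "A"])
      }
    }
  })
  for (g in c("patient", "control")) {
    expected <- truncnorm_mean_oracle(cfg$class_mean_duration_ms[g, "A"],
                                      cfg$class_duration_sd_ms[g, "A"],
                                      2 * 1000 / cfg$sampling_rate)
    expect_equal(mean(draws[[g]]), expected, tolerance = 0.02)
  }
})

test_that("zero-variance duration config yields constant drawn durations", {
  cfg <- synth_config(class_duration_sd_ms = matrix(0, 2, 4), seed = 2)
  withr::with_seed(2, s <- sample_state_sequence(cfg, "patient"))
  means <- cfg$class_mean_duration_ms["patient", ]
  expect_equal(s$drawn_ms, unname(means[s$class]))
})

test_that("realised per-class mean durations converge to configured means (500+ epochs)", {
  cfg <- synth_config(seed = 8)
  withr::with_seed(21, {
    runs <- dplyr::bind_rows(lapply(1:500, function(i) {
      sample_state_sequence(cfg, "patient")
    }))
  })
  got <- tapply(runs$duration_ms, runs$class, mean)
  want <- cfg$class_mean_duration_ms["patient", names(got)]
  expect_true(all(abs(got - want) / want < 0.05))
})

test_that("noise-free single-state epoch is proportional to its template everywhere", {
  cfg <- synth_config(snr = Inf, seed = 1)
  tm <- prototype_maps()
  s <- tibble::tibble(class = "B", n_samples = 512L,
                      duration_ms = 2560, drawn_ms = 2560)
  withr::with_seed(4, ep <- render_epoch(s, tm, cfg))
  g <- compute_gfp(ep)
  nz <- which(g > 1e-8 * max(g))
  cors <- apply(ep$data[, nz], 2, function(v) spatial_correlation(v, tm["B", ]))
  expect_true(all(abs(abs(cors) - 1) < 1e-9))
})

test_that("rendered epochs are average-referenced, finite, and of configured shape", {
  cfg <- quick_config(snr = 2)
  coh <- generate_cohort(cfg)
  for (eps in coh$epochs) {
    for (ep in eps) {
      expect_equal(dim(ep), c(16L, 512L))
      expect_true(all(is.finite(ep$data)))
      expect_lt(max(abs(colMeans(ep$data))), 1e-10)
    }
  }
})

test_that("noise-free 10 Hz epoch has GFP maxima every ~50 ms (two per cycle)", {
  cfg <- synth_config(snr = Inf, seed = 1)
  tm <- prototype_maps()
  s <- tibble::tibble(class = "D", n_samples = 512L,
                      duration_ms = 2560, drawn_ms = 2560)
  withr::with_seed(6, ep <- render_epoch(s, tm, cfg))
  pk <- find_gfp_peaks(compute_gfp(ep))
  expect_equal(length(pk), 51) # 2.56 s x 10 Hz x 2 per cycle, minus edges
  expect_true(all(abs(diff(pk) - 10) <= 1))
})

test_that("epoch rendering respects the configured SNR", {
  cfg <- synth_config(snr = 4, seed = 1)
  tm <- prototype_maps()
  s <- tibble::tibble(class = "A", n_samples = 512L,
                      duration_ms = 2560, drawn_ms = 2560)
  withr::with_seed(2, {
    clean <- render_epoch(s, tm, synth_config(snr = Inf, seed = 1))
  })
  withr::with_seed(2, noisy <- render_epoch(s, tm, cfg))
  resid <- noisy$data - clean$data
  snr_hat <- sqrt(mean(clean$data^2)) / sqrt(mean(resid^2))
  # average-referencing of the mixed epoch perturbs the ratio only slightly
  expect_equal(snr_hat, 4, tolerance = 0.05)
})

test_that("cohorts are seed-deterministic and vary with seed", {
  cfg <- quick_config(seed = 10)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$epochs[[1]][[1]]$data, c2$epochs[[1]][[1]]$data)
  expect_identical(c1$severity, c2$severity)
  cfg2 <- quick_config(seed = 11)
  c3 <- generate_cohort(cfg2)
  expect_false(identical(c1$epochs[[1]][[1]]$data, c3$epochs[[1]][[1]]$data))
})

test_that("severity is present for patients only, in 1..4, and epoch counts honour the range", {
  cfg <- synth_config(n_subjects_per_group = 5, epochs_per_subject = c(2, 6),
                      seed = 13)
  coh <- generate_cohort(cfg)
  pat <- coh$group == "patient"
  expect_true(all(coh$severity[pat] %in% 1:4))
  expect_true(all(is.na(coh$severity[!pat])))
  expect_true(all(coh$n_epochs >= 2 & coh$n_epochs <= 6))
  expect_equal(coh$n_epochs, vapply(coh$epochs, length, integer(1)))
})
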