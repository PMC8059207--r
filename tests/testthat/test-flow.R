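# Flow-stability pipeline: trace extraction with registration and ring
# background, decay fitting, molecule counting.

test_that("stationary noiseless spots give flat traces at spot minus background", {
  stk <- gen_flow_stack(n_spots = 4, molecules = 3, sample_molecules = FALSE,
                        k_fast = 0, k_slow = 0, fraction_fast = 0,
                        shot_noise = FALSE, n_frames = 12, seed = 31)
  tr <- extract_traces(stk, frame_interval = stk$frame_interval)
  expect_equal(length(unique(tr$condensate_id)), 4)
  for (d in split(tr, interaction(tr$condensate_id, tr$channel))) {
    expect_equal(diff(range(d$intensity)), 0)        # flat in time
    expect_equal(diff(range(d$background)), 0)
  }
  # intensity approximates the programmed center amplitude (ring picks
  # up only the far Gaussian tail)
  first <- tr[tr$frame == 1 & tr$channel == 1, ]
  expect_equal(mean(first$intensity / stk$truth$amp_ch1), 1, tolerance = 0.03)
})

test_that("ring subtraction removes a spatially uniform background exactly", {
  stk <- gen_flow_stack(n_spots = 3, molecules = 4, sample_molecules = FALSE,
                        shot_noise = FALSE, n_frames = 10, seed = 32)
  shifted <- stk
  shifted$channels <- lapply(stk$channels, function(a) a + 123.4)
  t0 <- extract_traces(stk)
  t1 <- extract_traces(shifted)
  expect_equal(t1$intensity, t0$intensity, tolerance = 1e-12)
})

test_that("registration undoes a programmed integer drift", {
  still <- gen_flow_stack(n_spots = 4, shot_noise = FALSE, n_frames = 15,
                          drift_total = c(0, 0), seed = 33)
  drift <- gen_flow_stack(n_spots = 4, shot_noise = FALSE, n_frames = 15,
                          drift_total = c(3, 2), seed = 33)
  t_still <- extract_traces(still)
  t_drift <- extract_traces(drift)
  expect_equal(t_drift$intensity, t_still$intensity, tolerance = 1e-6)
})

test_that("spots present in only one channel are excluded", {
  stk <- gen_flow_stack(n_spots = 3, molecules = 5, sample_molecules = FALSE,
                        shot_noise = FALSE, n_frames = 6, seed = 34)
  # erase one spot from channel 2 everywhere around its center
  tr_all <- extract_traces(stk)
  victim <- stk$truth[1, ]
  xs <- pmax(1, victim$x - 8):pmin(dim(stk$channels[[2]])[1], victim$x + 8)
  ys <- pmax(1, victim$y - 8):pmin(dim(stk$channels[[2]])[2], victim$y + 8)
  stk$channels[[2]][xs, ys, ] <- 20           # background level
  tr <- extract_traces(stk)
  expect_equal(length(unique(tr$condensate_id)),
               length(unique(tr_all$condensate_id)) - 1)
})

test_that("decay fitting recovers noiseless parameters and handles constants", {
  t <- seq(0, 300, by = 2)
  y <- 5 * exp(-0.013 * t)
  ft <- fit_decay(t, y, model = "single")
  expect_equal(ft$amplitudes, 5, tolerance = 1e-6)
  expect_equal(ft$rates, 0.013, tolerance = 1e-6)

  # constant trace under the double model: decaying amplitudes vanish,
  # offset absorbs the constant
  yc <- rep(2.5, 80)
  fc <- fit_decay(seq_along(yc), yc, model = "double", offset = TRUE)
  expect_lt(sum(fc$amplitudes), 1e-6)
  expect_equal(fc$offset, 2.5, tolerance = 1e-6)

  expect_error(fit_decay(1:5, exp(-(1:5))), "at least 10")
})

test_that("model selection prefers the generating model", {
  d2 <- gen_decay_trace(seed = 41)                     # two populations
  cmp2 <- compare_decay_models(d2$time, d2$intensity)
  expect_identical(cmp2$preferred, "double")

  t <- seq(0, 400, by = 2)
  set.seed(42)
  y1 <- exp(-0.005 * t) + rnorm(length(t), sd = 0.02)  # one population
  cmp1 <- compare_decay_models(t, y1)
  expect_identical(cmp1$preferred, "single")
})

test_that("molecule counting is exact arithmetic and linear", {
  expect_equal(count_molecules(1, 1, 1)$n_molecules, 1)
  expect_equal(count_molecules(10, 1, 0.5)$n_molecules, 20)
  expect_equal(count_molecules(2 * 7.7, 1.1, 0.35)$n_molecules,
               2 * count_molecules(7.7, 1.1, 0.35)$n_molecules)
  expect_error(count_molecules(5, 0, 0.5), "positive")
  expect_error(count_molecules(5, 1, 0), "labeled_fraction")
  expect_error(count_molecules(5, 1, 1.5), "labeled_fraction")
  expect_equal(estimate_single_dye(c(9, 10, 14)), 10)
})

test_that("molecule counts are recovered from synthetic stacks", {
  # spans the characteristic 2-4, 5-12 and 20-50 molecule regimes
  for (rng in list(c(2, 4), c(5, 12), c(20, 50))) {
    stk <- gen_flow_stack(n_spots = 6, molecules = rng, dye_intensity = 300,
                          labeled_fraction = c(0.5, 0.5), k_fast = 0,
                          k_slow = 0, fraction_fast = 0, n_frames = 5,
                          shot_noise = TRUE, seed = 50 + rng[2])
    tr <- extract_traces(stk)
    first <- tr[tr$frame == 1 & tr$channel == 1, ]
    est <- count_molecules(first$intensity, 300, 0.5,
                           condensate_id = first$condensate_id)
    map <- match_condensates(tr, stk$truth)
    truth <- stk$truth$n_molecules[
      match(map$truth_id[match(est$condensate_id, map$condensate_id)],
            stk$truth$id)]
    expect_equal(length(est$n_molecules), 6)
    expect_lt(mean(abs(est$n_molecules - truth) / truth), 0.15)
  }
})

test_that("aggregate_decay normalizes to the early baseline and reports SEM", {
  stk <- gen_flow_stack(n_spots = 5, shot_noise = FALSE, n_frames = 20,
                        seed = 60)
  tr <- extract_traces(stk)
  agg <- aggregate_decay(tr[tr$channel == 1, ], n_baseline = 3)
  expect_equal(nrow(agg), 20)
  expect_equal(mean(agg$mean_intensity[1:3]), 1, tolerance = 0.05)
  expect_true(all(agg$n == 5))
  expect_true(all(is.finite(agg$sem)))
})
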