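test_that("background statistics use complete 1-s off bins only", {
  p <- stimulus_protocol(
    list(rotation_segment("polarizer_blue", "cw", 30, start_time = 20, n_turns = 1)),
    off_intervals = list(c(0, 10))
  )
  bg <- background_stats(spike_train(numeric(0)), p)
  expect_equal(bg$mean_rate, 0)
  expect_equal(bg$sd, 0)
  expect_equal(bg$n_bins, 10)

  # 9.5-s interval -> 9 complete bins, partial trailing bin discarded
  p2 <- stimulus_protocol(
    list(rotation_segment("polarizer_blue", "cw", 30, start_time = 20, n_turns = 1)),
    off_intervals = list(c(0, 9.5))
  )
  st <- spike_train(c(0.5, 1.5, 9.25, 9.4)) # the 9.25/9.4 spikes are in the partial bin
  bg2 <- background_stats(st, p2)
  expect_equal(bg2$n_bins, 9)
  expect_equal(bg2$mean_rate, 2 / 9)

  expect_error(
    background_stats(st, stimulus_protocol(
      list(rotation_segment("polarizer_blue", "cw", 30, start_time = 20, n_turns = 1)),
      off_intervals = list(c(0, 1.5))
    )),
    class = "skytuner_insufficient_baseline"
  )
})

test_that("background of a homogeneous Poisson train matches its rate", {
  p <- stimulus_protocol(
    list(rotation_segment("polarizer_blue", "cw", 30, start_time = 70, n_turns = 1)),
    off_intervals = list(c(0, 60))
  )
  set.seed(17)
  n <- rpois(1, 10 * 60)
  st <- spike_train(sort(runif(n, 0, 60)))
  bg <- background_stats(st, p)
  expect_lt(abs(bg$mean_rate - 10), 2 * sqrt(10 / 60) * 3) # Poisson sampling bound
  expect_gt(bg$sd, 0)
})

test_that("binning uses half-open bins, dwell-time rates, and across-pair SD", {
  seg <- rotation_segment("polarizer_blue", "cw", 30, n_turns = 1)
  p <- stimulus_protocol(list(seg), exclude_first_rotation = FALSE)
  # one spike per 15-degree bin -> rate 1 / (15/30) = 2 imp/s everywhere
  st <- spikes_at_angles(seq(0, 345, by = 15), seg)
  b <- bin_spike_angles(trial_angles(st, p), 15)
  expect_equal(unname(b$counts[1, ]), rep(1L, 24))
  expect_equal(unname(b$rates[1, ]), rep(2, 24))
  # spike exactly at a bin edge belongs to the upper bin (half-open convention)
  st2 <- spikes_at_angles(c(14.999, 15), seg)
  b2 <- bin_spike_angles(trial_angles(st2, p), 15)
  expect_equal(unname(b2$counts[1, 1:2]), c(1L, 1L))

  # two identical same-direction trials are singleton pairs -> per-bin SD 0
  seg1 <- rotation_segment("polarizer_blue", "cw", 30, start_time = 0, n_turns = 1)
  seg2 <- rotation_segment("polarizer_blue", "cw", 30, start_time = 12, n_turns = 1)
  p2 <- stimulus_protocol(list(seg1, seg2), exclude_first_rotation = FALSE)
  ang <- c(10, 40, 40, 200)
  st3 <- spike_train(c(spikes_at_angles(ang, seg1)$times,
                       spikes_at_angles(ang, seg2)$times))
  b3 <- bin_spike_angles(trial_angles(st3, p2), 15)
  expect_equal(unname(b3$sd_rate), rep(0, 24))
  expect_equal(b3$n_rotations, 2)
  # one cw + one ccw trial collapse into a single pair: SD undefined
  segc <- rotation_segment("polarizer_blue", "ccw", 30, start_time = 12, n_turns = 1)
  pp <- stimulus_protocol(list(seg1, segc), exclude_first_rotation = FALSE)
  stp <- spike_train(c(spikes_at_angles(ang, seg1)$times,
                       spikes_at_angles(ang, segc)$times))
  bp <- bin_spike_angles(trial_angles(stp, pp), 15)
  expect_equal(nrow(bp$pair_rates), 1)
  expect_true(all(is.na(bp$sd_rate)))

  # same angular pattern at double velocity -> same counts, doubled rates
  segf <- rotation_segment("polarizer_blue", "cw", 60, n_turns = 1)
  pf <- stimulus_protocol(list(segf), exclude_first_rotation = FALSE)
  stf <- spikes_at_angles(ang, segf)
  bf <- bin_spike_angles(trial_angles(stf, pf), 15)
  sts <- spikes_at_angles(ang, seg1)
  bs <- bin_spike_angles(trial_angles(sts, p2 <- stimulus_protocol(list(seg1), exclude_first_rotation = FALSE)), 15)
  expect_equal(bf$counts, bs$counts)
  expect_equal(bf$rates, 2 * bs$rates)

  expect_error(bin_spike_angles(trial_angles(sts, p2), 17),
               class = "skytuner_config_error")
})

test_that("spike counts are conserved from windows through bins", {
  p <- make_protocol(n_turns = 3)
  st <- simulate_spike_train(scenario_library()$PC4, p, seed = 123)
  tr <- trial_angles(st, p, "polarizer_blue", "both")
  b <- bin_spike_angles(tr, 15)
  n_window <- sum(vapply(seq_len(nrow(tr$windows)), function(i) {
    sum(st$times >= tr$windows$t_start[i] & st$times < tr$windows$t_end[i])
  }, numeric(1)))
  expect_equal(sum(b$counts), n_window)
  expect_equal(unname(rowSums(b$counts)), lengths(tr$angles))
})

test_that("compute_tuning reports exactly uniform spikes as untuned", {
  seg <- rotation_segment("polarizer_blue", "cw", 30, n_turns = 1)
  p <- stimulus_protocol(
    list(seg), off_intervals = list(c(15, 25)),
    exclude_first_rotation = FALSE
  )
  st <- spikes_at_angles(seq(0, 345, by = 15), seg)
  res <- compute_tuning(st, p, bin_width = 15)
  expect_lt(res$r, 1e-9)
  expect_false(res$significant)
  expect_true(is.na(res$R2))
  expect_true(is.na(res$phi_max) || res$r < 1e-9)
})

test_that("compute_tuning withholds R2 when not significant and keeps it when tuned", {
  p <- make_protocol(n_turns = 3)
  tuned <- compute_tuning(simulate_spike_train(scenario_library()$PC4, p, seed = 2), p)
  expect_true(tuned$significant)
  expect_false(is.na(tuned$R2))
  expect_equal(tuned$n_samples, 24)
  untuned <- compute_tuning(simulate_spike_train(scenario_library()$TB1c, p, seed = 2), p)
  expect_false(untuned$significant)
  expect_true(is.na(untuned$R2))
})

test_that("opponency classification distinguishes opponent, excitation-only and flat responses", {
  p <- make_protocol(n_turns = 3)
  # opponent preset: trough dips below background - SD
  st_op <- simulate_spike_train(scenario_library()$PC4, p, seed = 9)
  res_op <- compute_tuning(st_op, p)
  expect_equal(res_op$opponency, "opponent")
  # excitation only: non-opponent model never drops below background
  m_exc <- neuron_model(background_rate = 10, modulation_amplitude = 15,
                        harmonic = 2, true_phi_max = 51.8, opponent = FALSE)
  res_exc <- compute_tuning(simulate_spike_train(m_exc, p, seed = 9), p)
  expect_equal(res_exc$opponency, "excitation_only")
  # flat response
  st_fl <- simulate_spike_train(scenario_library()$TB1c, p, seed = 9)
  res_fl <- compute_tuning(st_fl, p)
  expect_equal(res_fl$opponency, "none")
  # undefined preferred angle -> none
  expect_equal(opponency_classification(res_op$binned, res_op$background, NA), "none")
})

test_that("direction mismatch is the smallest axial distance between group tunings", {
  mk <- function(phi, per = 180) {
    structure(list(phi_max = phi, periodicity = per), class = "tuning_result")
  }
  expect_equal(direction_mismatch(mk(107.8), mk(154.4)), 46.6)
  expect_equal(direction_mismatch(mk(77), mk(77)), 0)
  expect_equal(direction_mismatch(mk(5), mk(175)), 10)
  expect_true(is.na(direction_mismatch(mk(NA_real_), mk(100))))
  expect_error(direction_mismatch(mk(10, 180), mk(10, 360)),
               class = "skytuner_domain_error")
})

test_that("moving-average rate tracks homogeneous rates and single spikes", {
  set.seed(3)
  st <- spike_train(sort(runif(rpois(1, 20 * 50), 0, 50)))
  ma <- moving_average_rate(st, window = 1, grid_step = 0.1, t_range = c(0, 50))
  inner <- ma$rate[ma$time > 2 & ma$time < 48]
  expect_lt(abs(mean(inner) - 20), 1.5)
  # empty train -> all zeros
  ma0 <- moving_average_rate(spike_train(numeric(0)), t_range = c(0, 5))
  expect_true(all(ma0$rate == 0))
  # single spike -> bump of height 1 imp/s spanning one window
  ma1 <- moving_average_rate(spike_train(5), window = 1, grid_step = 0.05,
                             t_range = c(0, 10))
  expect_equal(max(ma1$rate), 1)
  expect_equal(sum(ma1$rate > 0) * 0.05, 1, tolerance = 0.1)
})
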