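test_that("make_windows places the 59 min pre/post windows", {
  w <- make_windows(4000)
  expect_equal(w$pre, c(160, 3700))
  expect_equal(w$post, c(6100, 9640))
  expect_equal(diff(w$pre), 3540)
  expect_equal(diff(w$post), 3540)
  expect_error(make_windows(1000), class = "hpdlfp_range_error")
  expect_error(make_windows(4000, recording_duration = 9000),
               class = "hpdlfp_range_error")
})

test_that("assign_groups applies the strict 50 s/h cutoff", {
  df <- data.frame(animal_id = c("m1", "m2", "m3", "m4"),
                   dur_hpds = c(172.8, 50.0, 8.9, 50.1))
  g <- assign_groups(df)
  expect_equal(g$group, c("high_hpds", "low_hpds", "low_hpds", "high_hpds"))
  # pure threshold function: permuting input never changes assignments
  g2 <- assign_groups(df[c(3, 1, 4, 2), ])
  expect_equal(g2$group[g2$animal_id == "m2"], "low_hpds")
  expect_equal(g2$group[g2$animal_id == "m1"], "high_hpds")
  expect_error(assign_groups(data.frame(animal_id = c("m1", "m1"),
                                        dur_hpds = c(1, 2))),
               class = "hpdlfp_validation_error")
})

test_that("occurrence_chisq equals the brute-force formula and edge cases", {
  # arbitrary 2x2
  tab <- data.frame(treatment = c("A", "B"), n_with = c(5, 1), n_without = c(2, 6))
  got <- occurrence_chisq(tab)
  want <- brute_force_chisq(rbind(c(5, 1), c(2, 6)))
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p_value)
  # homogeneous proportions -> statistic 0, p 1
  tab0 <- data.frame(treatment = c("A", "B", "C"), n_with = c(2, 2, 2),
                     n_without = c(5, 5, 5))
  got0 <- occurrence_chisq(tab0)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)
  # randomized parity with the textbook formula
  withr::local_seed(11)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    m <- matrix(rpois(2 * k, 4) + 1, nrow = 2)
    tabr <- data.frame(treatment = paste0("t", 1:k), n_with = m[1, ],
                       n_without = m[2, ])
    expect_equal(occurrence_chisq(tabr)$statistic,
                 brute_force_chisq(t(m))$statistic)
  }
  expect_error(occurrence_chisq(tab[1, , drop = FALSE]),
               class = "hpdlfp_validation_error")
  expect_error(occurrence_chisq(data.frame(treatment = c("A", "B"),
                                           n_with = c(0, 1), n_without = c(0, 5))),
               class = "hpdlfp_validation_error")
})

test_that("sidak_alpha matches the closed form", {
  expect_equal(sidak_alpha(0.05, 8), 1 - 0.95^(1 / 8))
  expect_equal(sidak_alpha(0.05, 8), 0.00639, tolerance = 1e-3)
  expect_equal(sidak_alpha(0.05, 1), 0.05)
})

# one suppressant-like and one vehicle-like session, reused across blocks
local({
  ses_dzp <- simulate_session(treatment_effect(multipliers = c(spike = 0.2, spike_train = 0, hpd = 0)),
                              seed = 9, animal_id = "m1")
  ses_veh <- simulate_session(treatment_effect(), seed = 10, animal_id = "m2")
  res_dzp <- evaluate_session(ses_dzp$recording, 64 * 60,
                              treatment_label = "DZP2.5", animal_id = "m1",
                              session_id = "s1")
  res_veh <- evaluate_session(ses_veh$recording, 64 * 60,
                              treatment_label = "vehicle", animal_id = "m2",
                              session_id = "s2")

  test_that("evaluate_session reproduces the suppressant signature end to end", {
    expect_equal(res_dzp$rates_post$n_hpds, 0)
    expect_equal(res_dzp$rates_post$dur_hpds, 0)
    expect_gt(res_dzp$rates_pre$n_hpds, 0)
    expect_lt(res_dzp$rates_post$n_spike_trains,
              0.1 * res_dzp$rates_pre$n_spike_trains)
    expect_false(res_dzp$excluded_from_events)
    # spectral summaries populated for both windows
    expect_equal(nrow(res_dzp$bands_pre$bands), 5)
    expect_true(all(is.finite(res_dzp$bands_post$bands$log_power)))
  })

  test_that("a vehicle-like session leaves rates and band powers stable", {
    expect_gt(res_veh$rates_post$n_hpds, 0)
    ratio <- res_veh$rates_post$n_spike_trains / res_veh$rates_pre$n_spike_trains
    expect_gt(ratio, 0.6)
    expect_lt(ratio, 1.6)
    dlog <- abs(res_veh$bands_post$bands$log_power -
                  res_veh$bands_pre$bands$log_power)
    expect_lt(mean(dlog), 0.1)
  })

  test_that("paired_prepost_summary separates event and spectral measures", {
    results <- list(res_dzp, res_veh)
    tab <- paired_prepost_summary(results, "dur_hpds")
    expect_equal(nrow(tab), 2)
    # single session per treatment -> non-estimable, no exception
    expect_false(any(tab$estimable))
    expect_equal(tab$alpha_sidak, rep(1 - 0.95^(1 / 2), 2))
    dzp_row <- tab[tab$treatment == "DZP2.5", ]
    expect_equal(dzp_row$mean_post, 0)
    expect_equal(dzp_row$mean_diff, -dzp_row$mean_pre)
    # spectral measure table covers all sessions regardless of exclusions
    tb <- paired_prepost_summary(results, "delta")
    expect_equal(tb$n, c(1, 1))
    expect_error(paired_prepost_summary(results, "nonsense"),
                 class = "hpdlfp_config_error")
  })

  test_that("occurrence_table counts post-window generalized seizures", {
    occ <- occurrence_table(list(res_dzp, res_veh))
    expect_equal(sort(occ$treatment), c("DZP2.5", "vehicle"))
    expect_equal(occ$n_with + occ$n_without, c(1, 1))
  })
})

test_that("a session with a post-window generalized seizure is excluded from events only", {
  # place one seizure deterministically in the post window
  sch <- event_schedule(rates = c(spike_train = 60, generalized_seizure = 0))
  eff <- treatment_effect(multipliers = c(generalized_seizure = 1))
  pw <- apply_treatment_effect(sch, eff, injection_time = 64 * 60,
                               session_end = 64 * 60 + 94 * 60)
  truth <- sample_piecewise_schedule(pw, seed = 3)
  # inject a hand-scheduled seizure at 70-90 min (inside [35, 94] min post)
  gs_on <- 64 * 60 + 70 * 60
  keep <- truth$events$offset < gs_on - 40 | truth$events$onset > gs_on + 1260
  ev <- rbind(truth$events[keep, ],
              event_intervals(gs_on, gs_on + 30, "generalized_seizure",
                              0L, NA_real_, "other"))
  st <- c(truth$spike_times[keep], list(numeric(0)))
  ord <- order(ev$onset)
  truth$events <- ev[ord, ]
  truth$spike_times <- st[ord]
  rec <- synthesize_recording(truth, n_channels = 3, seed = 4)
  res <- evaluate_session(rec, 64 * 60, treatment_label = "LTG10")
  expect_true(res$generalized_in_post)
  expect_true(res$excluded_from_events)
  expect_equal(nrow(res$generalized_post), 1)
  # spectral summaries still populated (never excluded)
  expect_true(all(is.finite(res$bands_post$bands$power)))
})

test_that("post/pre rate ratios recover known multipliers at cohort scale", {
  # schedule-level parameter recovery: 3 treatments x 7 animals, 3 cohorts
  mults <- c(vehicle = 1, DZP = 0, LTG30 = 1.6)
  sch <- event_schedule()
  est <- sapply(names(mults), function(tr) {
    ratios <- vapply(1:3, function(cohort) {
      pre_tot <- 0; post_tot <- 0
      for (a in 1:7) {
        eff <- treatment_effect(multipliers = c(spike_train = mults[[tr]],
                                                hpd = mults[[tr]]))
        pw <- apply_treatment_effect(sch, eff, injection_time = 64 * 60,
                                     session_end = 64 * 60 + 94 * 60)
        truth <- sample_piecewise_schedule(pw, seed = cohort * 1000 + a * 10 +
                                             match(tr, names(mults)))
        ev <- truth$events[truth$events$kind %in% c("spike_train", "hpd"), ]
        pre_tot <- pre_tot + sum(ev$onset >= 0 & ev$onset < 3540)
        post_tot <- post_tot + sum(ev$onset >= 6100 & ev$onset < 9640)
      }
      post_tot / pre_tot
    }, double(1))
    mean(ratios)
  })
  expect_equal(unname(est["DZP"]), 0)
  expect_lt(abs(est["vehicle"] - 1), 0.25)
  expect_lt(abs(est["LTG30"] - 1.6), 0.25 * 1.6)
})
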