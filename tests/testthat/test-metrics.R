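# metric definitions, stratification and the proportion test

toy_outcomes <- function() {
  d <- toy10()
  eps <- build_episodes(d)
  list(d = d, eps = eps, out = rollup_encounters(eps, d))
}

test_that("completion rates on toy10 equal direct hand counts", {
  x <- toy_outcomes()
  ack <- completion_rate(x$out, "ack")
  expect_equal(ack$numerator, 4)
  expect_equal(ack$denominator, 7)
  expect_equal(ack$rate, 4 / 7)
  doc <- completion_rate(x$out, "documented")
  expect_equal(c(doc$numerator, doc$denominator), c(1, 7))
  # brute-force recount of the documented flag over fired encounters
  fired <- x$out[x$out$screening_fired & !is.na(x$out$window_index), ]
  expect_equal(doc$rate, mean(fired$screening_documented))
  disc <- completion_rate(x$out, "discussion")
  expect_equal(c(disc$numerator, disc$denominator), c(1, 2))
  expect_equal(completion_rate(x$out, "referral")$rate, 0.5)
  expect_equal(completion_rate(x$out, "no_postpone")$rate, 0.5)
  # clinic filter
  expect_equal(completion_rate(x$out, "ack", clinic = "C2")$denominator, 1)
})

test_that("zero completions give rate 0 and empty denominators abort", {
  x <- toy_outcomes()
  out <- x$out
  out$screening_ack_completed <- FALSE
  expect_equal(completion_rate(out, "ack")$rate, 0)
  expect_error(completion_rate(out, "ack", clinic = "NOPE"),
               class = "alertmetrics_undefined_rate")
})

test_that("firing rate counts firings per completion over episodes", {
  x <- toy_outcomes()
  fr <- firing_rate(x$eps, "screening")
  expect_equal(c(fr$fired, fr$completed), c(8, 3))
  expect_equal(fr$rate, 8 / 3)
  fr_all <- firing_rate(x$eps, "screening", interruptive_only = FALSE)
  expect_equal(c(fr_all$fired, fr_all$completed), c(10, 4))
  fr_sup <- firing_rate(x$eps, "support")
  expect_equal(fr_sup$rate, 4)
  # every episode completed on first firing -> rate exactly 1
  eps1 <- x$eps
  eps1$n_firings <- 1L
  eps1$completed <- TRUE
  eps1$modality <- "interruptive"
  expect_equal(firing_rate(eps1, "screening")$rate, 1)
  # no completed episode in scope -> undefined flag, not an error
  fr_c2sup <- firing_rate(x$eps, "support", clinic = "C2")
  expect_true(fr_c2sup$undefined)
  expect_true(is.na(fr_c2sup$rate))
  # defined rates are never below 1: a completed episode fired at least once
  expect_true(fr$rate >= 1 && fr_sup$rate >= 1)
})

test_that("handling times average per-encounter sums over the right sets", {
  x <- toy_outcomes()
  ht <- handling_time(x$out, "screening")
  expect_equal(ht$mean_complete_s, (53 + 40 + 40 + 30) / 4)
  expect_equal(ht$n_complete_encounters, 4)
  expect_equal(ht$mean_postpone_s, (52 + 10 + 20) / 3)
  expect_equal(ht$n_postpone_encounters, 3)
  hs <- handling_time(x$out, "support")
  expect_equal(hs$mean_complete_s, 50)
  expect_equal(hs$mean_postpone_s, 67)

  # independent recomputation from raw instance durations on simulated data
  sim <- simulate_alerts(random_sim_config(55))
  d <- sim$dataset
  eps <- build_episodes(d)
  out <- rollup_encounters(eps, d)
  ht2 <- handling_time(out, "screening")
  ev <- d$alert_events[d$alert_events$alert_name == "screening", ]
  ev$dur <- as.numeric(difftime(ev$response_time, ev$firing_time,
                                units = "secs"))
  ev$action <- ifelse(ev$subsequent_action == "none", "no_response",
                      unname(d$vocabulary[trimws(ev$override_reason)]))
  comp_enc <- unique(ev$encounter_id[ev$action == "ack_complete_screening"])
  comp_enc <- intersect(comp_enc,
                        out$encounter_id[!is.na(out$window_index)])
  brute <- vapply(comp_enc, function(e) {
    sum(ev$dur[ev$encounter_id == e & ev$action != "defer"], na.rm = TRUE)
  }, 0)
  expect_equal(ht2$mean_complete_s, mean(brute))
  post_enc <- unique(ev$encounter_id[ev$action == "defer"])
  post_enc <- intersect(post_enc,
                        out$encounter_id[!is.na(out$window_index)])
  brute_p <- vapply(post_enc, function(e) {
    sum(ev$dur[ev$encounter_id == e & ev$action == "defer"], na.rm = TRUE)
  }, 0)
  expect_equal(ht2$mean_postpone_s, mean(brute_p))
  expect_equal(ht2$n_postpone_encounters, length(post_enc))

  # per-instance aggregation switch
  ht_i <- handling_time(out, "screening", aggregate = "instance")
  k <- out$screening_complete_k[out$screening_ack_completed &
                                  !is.na(out$window_index)]
  expect_equal(ht_i$mean_complete_s, sum(brute) / sum(k))
})

test_that("strata partition the encounters: sums match the totals", {
  sim <- simulate_alerts(random_sim_config(77))
  out <- rollup_encounters(build_episodes(sim$dataset), sim$dataset)
  total <- completion_rate(out, "ack")
  for (keys in list("sex", "race", c("sex", "race"), "relevance", "clinic")) {
    st <- stratify_completion(out, "ack", keys)
    expect_equal(sum(st$numerator), total$numerator)
    expect_equal(sum(st$denominator), total$denominator)
    expect_true(all(st$rate >= 0 & st$rate <= 1))
  }
  # a single-stratum key equals the unstratified rate
  out1 <- out
  out1$sex <- "female"
  st1 <- stratify_completion(out1, "ack", "sex")
  expect_equal(nrow(st1), 1)
  expect_equal(st1$rate, total$rate)
})

test_that("trend rows are additive and windows beyond the data are absent", {
  x <- toy_outcomes()
  tr <- completion_trend(x$out, "ack")
  all_rows <- tr[tr$clinic_id == "ALL", ]
  for (w in all_rows$window_index) {
    clin <- tr[tr$clinic_id != "ALL" & tr$window_index == w, ]
    expect_equal(sum(clin$numerator),
                 all_rows$numerator[all_rows$window_index == w])
    expect_equal(sum(clin$denominator),
                 all_rows$denominator[all_rows$window_index == w])
  }
  # window denominators per clinic sum to that clinic's 12-month denominator
  for (cid in c("C1", "C2")) {
    expect_equal(sum(tr$denominator[tr$clinic_id == cid]),
                 completion_rate(x$out, "ack", clinic = cid)$denominator)
  }
  # all events in the first quarter -> only window 0 present
  out0 <- x$out[x$out$window_index %in% 0L, ]
  tr0 <- completion_trend(out0, "ack")
  expect_equal(unique(tr0$window_index), 0L)
})

test_that("appending a completed-fired encounter never lowers completion", {
  sim <- simulate_alerts(random_sim_config(91))
  out <- rollup_encounters(build_episodes(sim$dataset), sim$dataset)
  r0 <- completion_rate(out, "ack")$rate
  extra <- out[1, ]
  extra$encounter_id <- "E-NEW"
  extra$window_index <- 0L
  extra$screening_fired <- TRUE
  extra$screening_ack_completed <- TRUE
  r1 <- completion_rate(dplyr::bind_rows(out, extra), "ack")$rate
  expect_gte(r1, r0)
})

test_that("the two-proportion chi-square matches its reference behavior", {
  # the published relevance contingency is decisively significant
  res <- two_proportion_test(2793, 4425, 24, 696)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$df, 1L)
  # identical proportions: statistic 0, p = 1
  same <- two_proportion_test(30, 100, 15, 50)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # degenerate margins
  expect_equal(two_proportion_test(0, 10, 0, 20)$p_value, 1)
  expect_equal(two_proportion_test(10, 10, 20, 20)$statistic, 0)
  # p matches the chi-square upper tail at df 1
  r <- two_proportion_test(30, 100, 50, 100)
  expect_equal(r$p_value, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
})

test_that("reported rounding follows the presentation conventions", {
  expect_equal(round_metric(0.5501, "rate"), 0.55)
  expect_equal(round_metric(2.7217, "firing"), 2.7)
  expect_equal(round_metric(52.6, "seconds"), 53)
  expect_equal(round_metric(87.337, "percent"), 87.3)
})
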