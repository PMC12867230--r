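test_that("eligibility requires five responding candidates at the program", {
  g4 <- make_group(1:4, c("N", "N", "N", "Y"), ts_min("10:00"))
  expect_equal(label_transplant(g4, "P04")$label, "NTP")
  g5 <- make_group(1:5, c("N", "N", "N", "N", "Y"),
                   c(rep(ts_min("10:00"), 4), ts_min("09:55")))
  expect_equal(label_transplant(g5, "P05")$label, "TP")
  expect_equal(label_transplant(g5, "P05")$rule_id, 1L)
})

test_that("the three criteria and Rule 1 match the worked example", {
  # ranks 1-4 share "N" at 10:00, rank 5 declined earlier, rank 6 accepted
  # at 09:55 -> batch of 4 at/after the recipient's response: TP by Rule 1
  g <- make_group(1:6, c("N", "N", "N", "N", "N", "Y"),
                  c(rep(ts_min("10:00"), 4), ts_min("09:40"), ts_min("09:55")))
  res <- label_transplant(g, "P06", threshold = 4)
  expect_equal(res$label, "TP")
  expect_equal(res$rule_id, 1L)
  expect_setequal(res$skipped_ptr_ids, sprintf("P%02d", 1:4))
  expect_equal(res$batch_size, 4L)

  # only three share the batch time: NTP at threshold 4, TP at threshold 3
  g3 <- make_group(1:6, c("N", "N", "N", "N", "N", "Y"),
                   c(rep(ts_min("10:00"), 3), ts_min("09:30"), ts_min("09:40"),
                     ts_min("09:55")))
  expect_equal(label_transplant(g3, "P06", threshold = 4)$label, "NTP")
  res3 <- label_transplant(g3, "P06", threshold = 3)
  expect_equal(res3$label, "TP")
  expect_equal(res3$batch_size, 3L)

  # batch earlier than the recipient's response violates criterion (3)
  ge <- make_group(1:6, c("N", "N", "N", "N", "N", "Y"),
                   c(rep(ts_min("09:50"), 4), ts_min("09:30"), ts_min("09:55")))
  expect_equal(label_transplant(ge, "P06", threshold = 4)$label, "NTP")
})

test_that("rules 2 and 3 distinguish provisional-yes patterns", {
  it <- c(rep(ts_min("10:00"), 4), ts_min("09:55"))
  # Z-batch, recipient accepted outright -> Rule 2
  g2 <- make_group(1:5, c("Z", "Z", "Z", "Z", "Y"), it)
  expect_equal(label_transplant(g2, "P05")$rule_id, 2L)
  # Z-batch, recipient Z finalized at the same minute -> Rule 2
  g2b <- make_group(1:5, c("Z", "Z", "Z", "Z", "Z"), it,
                    fin = c("N", "N", "N", "N", "Y"),
                    fin_t = c(rep(ts_min("12:00"), 4), ts_min("09:55")))
  expect_equal(label_transplant(g2b, "P05")$rule_id, 2L)
  # Z-batch, recipient Z finalized later, batch finals after recipient's
  # final -> Rule 3
  g3 <- make_group(1:5, c("Z", "Z", "Z", "Z", "Z"), it,
                   fin = c("N", "N", "N", "N", "Y"),
                   fin_t = c(rep(ts_min("13:00"), 4), ts_min("11:00")))
  expect_equal(label_transplant(g3, "P05")$rule_id, 3L)
  # ... but batch finalized before the recipient's final and before the
  # transplant day fails Rule 3
  g3b <- make_group(1:5, c("Z", "Z", "Z", "Z", "Z"), it,
                    fin = c("N", "N", "N", "N", "Y"),
                    fin_t = c(rep(ts_min("10:30"), 4), ts_min("11:00")))
  expect_equal(label_transplant(g3b, "P05",
                                transplant_date = as.Date("2016-05-03"))$label,
               "NTP")
  # same-day batch finals count via the transplant-day clause
  expect_equal(label_transplant(g3b, "P05",
                                transplant_date = as.Date("2016-05-01"))$rule_id,
               3L)
})

test_that("accepted candidate outside the group is an argument error", {
  g <- make_group(1:5, c("N", "N", "N", "N", "Y"), ts_min("10:00"))
  expect_error(label_transplant(g, "P99"), "accepted_ptr")
})

test_that("labeler agrees with the brute-force subset oracle", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:200) {
    rg <- random_group()
    got <- label_transplant(rg$group, rg$accepted, threshold = 4,
                            transplant_date = rg$transplant_date)
    want <- brute_force_label(rg$group, rg$accepted, threshold = 4,
                              transplant_date = rg$transplant_date)
    expect_equal(got$label, want$label,
                 info = paste("fixture", i))
    expect_equal(got$rule_id, want$rule_id, info = paste("fixture", i))
    n_checked <- n_checked + (want$label == "TP")
  }
  expect_gt(n_checked, 10) # the fixtures must actually exercise TP paths
})

test_that("noiseless synthetic cohorts are recovered perfectly", {
  sc <- simulate_cohort(clean_sim(n_donors = 500, seed = 30))
  co <- apply_prep_pipeline(normalize_responses(sc$cohort))
  lab <- label_cohort(co, threshold = 4)
  m <- dplyr::inner_join(lab$labels, sc$truth$true_tp,
                         by = c("donor_id", "ptr_id"))
  expect_gt(sum(m$true_tp), 10)
  expect_equal(m$label == "TP", m$true_tp)
  expect_equal(m$rule_id.x[m$true_tp], m$rule_id.y[m$true_tp])
})

test_that("timestamp jitter degrades recovery monotonically", {
  recall <- vapply(c(0, 1, 5), function(j) {
    sc <- simulate_cohort(clean_sim(n_donors = 300, seed = 31, jitter_sd = j))
    lab <- label_cohort(sc$cohort, threshold = 4)
    m <- dplyr::inner_join(lab$labels, sc$truth$true_tp,
                           by = c("donor_id", "ptr_id"))
    sum(m$label == "TP" & m$true_tp) / sum(m$true_tp)
  }, numeric(1))
  expect_equal(recall[1], 1)
  expect_true(all(diff(recall) <= 0))
  expect_lt(recall[3], recall[1])
})

test_that("the TP set shrinks as the threshold grows", {
  sc <- simulate_cohort(clean_sim(n_donors = 400, seed = 32,
                                  btd_sizes = 3:8,
                                  btd_size_probs = c(3, 3, 2, 1, 1, 1)))
  co <- sc$cohort
  sets <- lapply(3:5, function(th) {
    lb <- label_cohort(co, threshold = th)$labels
    paste(lb$donor_id, lb$ptr_id)[lb$label == "TP"]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_gt(length(sets[[1]]), length(sets[[2]])) # 3-batches exist
  expect_gt(length(sets[[2]]), length(sets[[3]]))
})

test_that("labels partition transplants and rule counts sum to the TP count", {
  sc <- simulate_cohort(sim_config(n_donors = 300, n_candidates = 1800, seed = 33))
  co <- apply_prep_pipeline(normalize_responses(sc$cohort))
  lab <- label_cohort(co)
  expect_equal(nrow(lab$labels), nrow(co$transplants))
  expect_true(all(lab$labels$label %in% c("TP", "NTP")))
  expect_equal(sum(table(lab$labels$rule_id)), sum(lab$labels$label == "TP"))
  expect_true(all(is.na(lab$labels$rule_id[lab$labels$label == "NTP"])))
})

test_that("entity classification follows the at-least-once definitions", {
  sc <- simulate_cohort(clean_sim(n_donors = 400, seed = 34))
  co <- sc$cohort
  lab <- label_cohort(co)
  cls <- classify_entities(lab, co)
  lb <- lab$labels
  # donor is TP iff >= 1 of its kidneys is a TP
  for (d in cls$donors$donor_id[seq_len(min(50, nrow(cls$donors)))]) {
    expect_equal(cls$donors$donor_class[cls$donors$donor_id == d],
                 if (any(lb$label[lb$donor_id == d] == "TP")) "TP" else "NTP")
  }
  # BTD candidates are exactly the skipped ids
  expect_setequal(cls$candidates$ptr_id[cls$candidates$btd_candidate],
                  unique(lab$btd_members$ptr_id))
  # BTD recipients were skipped strictly before their own transplant
  rec <- cls$recipients[cls$recipients$btd_recipient, ]
  for (p in rec$ptr_id) {
    own <- co$transplants$transplant_date[co$transplants$ptr_id == p]
    skips <- lab$btd_members$batch_time[lab$btd_members$ptr_id == p]
    expect_true(any(as.Date(skips, tz = "UTC") < own))
  }
})

test_that("a zero-TP cohort yields no TP donors and no BTD candidates", {
  cfg <- clean_sim(n_donors = 100, seed = 35,
                   tp_propensity = c(intercept = -50, age = 0, kdpi = 0, epts = 0))
  sc <- simulate_cohort(cfg)
  lab <- label_cohort(sc$cohort)
  cls <- classify_entities(lab, sc$cohort)
  expect_true(all(cls$donors$donor_class == "NTP"))
  expect_false(any(cls$candidates$btd_candidate))
  expect_false(any(cls$recipients$btd_recipient))
})
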