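# Virtual-cell cohort machinery: sampling, outcomes, survival analysis,
# ROC, synergy.

test_that("cohort sampling is seeded, unique and in range", {
  co <- sample_cohort(n = 200, seed = 42)
  co2 <- sample_cohort(n = 200, seed = 42)
  expect_identical(co, co2)
  expect_equal(nrow(co), 200)
  expect_equal(anyDuplicated(co[, -1]), 0)
  rg <- default_ranges()
  expect_true(all(co$apaf1 >= rg$APAF1[1] & co$apaf1 <= rg$APAF1[2]))
  expect_true(all(co$smac >= rg$SMAC[1] & co$smac <= rg$SMAC[2]))
  co_log <- sample_cohort(n = 50, seed = 1, log_scale = TRUE)
  expect_true(all(co_log$xiap >= rg$XIAP[1] & co_log$xiap <= rg$XIAP[2]))
  expect_false(identical(co_log$xiap, sample_cohort(n = 50, seed = 1)$xiap))
})

test_that("variant ordering holds across outcomes of a small cohort", {
  co <- sample_cohort(n = 12, seed = 3)
  oc <- run_conditions(co, momp_fraction = 1, horizon = 240)
  wide <- reshape(oc[, c("id", "variant", "cleav60", "cleav240")],
                  direction = "wide", idvar = "id", timevar = "variant")
  tol <- 1e-6
  for (cp in c("cleav60", "cleav240")) {
    expect_true(all(wide[[paste0(cp, ".no_timer")]] >=
                      wide[[paste0(cp, ".normal")]] - tol))
    expect_true(all(wide[[paste0(cp, ".no_xiap")]] >=
                      wide[[paste0(cp, ".normal")]] - tol))
    expect_true(all(wide[[paste0(cp, ".no_xiap_no_timer")]] >=
                      wide[[paste0(cp, ".no_xiap")]] - tol))
  }
  # checkpoint cleavage nondecreasing in time
  expect_true(all(oc$cleav30 >= oc$cleav15 - 1e-9))
  expect_true(all(oc$cleav240 >= oc$cleav60 - 1e-9))
  # when both die, joint removal kills no later than normal
  both <- merge(oc[oc$variant == "normal" & oc$died,
                   c("id", "event_time")],
                oc[oc$variant == "no_xiap_no_timer" & oc$died,
                   c("id", "event_time")], by = "id")
  expect_true(all(both$event_time.y <= both$event_time.x + 1e-6))
})

test_that("non-cleavable PC9 sensitises at least as much as timer removal", {
  co <- sample_cohort(n = 40, seed = 8)
  oc <- run_conditions(co, momp_fraction = 1, horizon = 60,
                       variants = c("no_timer", "noncleavable"))
  wide <- reshape(oc[, c("id", "variant", "cleav60")], direction = "wide",
                  idvar = "id", timevar = "variant")
  # wherever XIAP is fully neutralised by released SMAC the two variants
  # are near-equivalent (slack covers the inactive-monomer partitioning of
  # the non-cleavable zymogen at very low PC9)
  ok <- wide$id %in% co$id[co$xiap <= co$smac]
  expect_true(all(wide$cleav60.noncleavable[ok] >=
                    wide$cleav60.no_timer[ok] - 0.03))
  # with XIAP in excess the non-cleavable zymogen escapes inhibition and is
  # strictly more dangerous (the C9 pool of the timer-off variant instead
  # gets sequestered)
  fx <- data.frame(id = 1, apaf1 = 0.4, pc9 = 0.02, pc3 = 0.6,
                   xiap = 0.5, smac = 0.1)
  oc_fx <- run_conditions(fx, momp_fraction = 1, horizon = 60,
                          variants = c("no_timer", "noncleavable"))
  expect_gt(oc_fx$cleav60[oc_fx$variant == "noncleavable"],
            oc_fx$cleav60[oc_fx$variant == "no_timer"])
})

test_that("no release leaves every cell censored", {
  co <- sample_cohort(n = 4, seed = 1)
  oc <- run_conditions(co, momp_fraction = 0, horizon = 60,
                       variants = "normal")
  expect_true(all(!oc$died))
  expect_true(all(oc$event_time == 60))
})

test_that("Kaplan-Meier matches a hand product-limit computation", {
  oc <- data.frame(id = 1:5, variant = "normal",
                   died = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                   event_time = c(10, 20, 240, 20, 240))
  class(oc) <- c("condition_outcomes", "data.frame")
  fit <- survival_curve(oc, "normal")
  hand <- km_oracle(oc$event_time, oc$died)
  # hand: S(10) = 4/5, S(20) = 4/5 * 2/4 = 0.4
  expect_equal(hand$surv, c(0.8, 0.4))
  expect_equal(summary(fit, times = hand$time)$surv, hand$surv)
  expect_equal(survival_fraction(oc, "normal", 15), 0.8)
  expect_equal(survival_fraction(oc, "normal", 240), 0.4)
  expect_error(survival_curve(oc, "no_xiap"), "no outcomes")
})

test_that("logrank test agrees with a permutation oracle and is symmetric", {
  set.seed(77)
  a <- data.frame(event_time = rexp(30, 1 / 40), died = TRUE)
  a$died <- a$event_time < 100
  a$event_time <- pmin(a$event_time, 100)
  b <- data.frame(event_time = rexp(30, 1 / 80), died = TRUE)
  b$died <- b$event_time < 100
  b$event_time <- pmin(b$event_time, 100)
  lr <- logrank_test(a, b)
  p_perm <- logrank_perm_oracle(c(a$event_time, b$event_time),
                                c(a$died, b$died),
                                rep(c("A", "B"), c(30, 30)), n_perm = 1000)
  expect_lt(abs(lr$p - p_perm), 0.05)
  expect_equal(logrank_test(b, a)$p, lr$p)
  # identical groups: no signal
  expect_equal(logrank_test(a, a)$chisq, 0, tolerance = 1e-12)
  expect_equal(logrank_test(a, a)$p, 1)
  # disjoint supports separate decisively
  a2 <- data.frame(event_time = seq(1, 20, length.out = 100), died = TRUE)
  b2 <- data.frame(event_time = seq(100, 200, length.out = 100),
                   died = TRUE)
  expect_lt(logrank_test(a2, b2)$p, 1e-6)
  # no events at all: warned, p = 1
  c1 <- data.frame(event_time = rep(240, 5), died = FALSE)
  expect_warning(lr0 <- logrank_test(c1, c1), "no events")
  expect_equal(lr0$p, 1)
})

test_that("classification follows the cleavage thresholds exactly", {
  oc <- data.frame(id = rep(1:3, 2),
                   variant = rep(c("normal", "no_timer"), each = 3),
                   died = FALSE, event_time = 60,
                   cleav15 = 0, cleav30 = 0,
                   cleav60 = c(0.30, 0.20, 0.20, 0.35, 0.30, 0.20),
                   cleav240 = 0)
  cls <- classify_cells(oc, threshold = 0.25, t_eval = 60)
  expect_equal(cls$capable, c(TRUE, FALSE, FALSE))
  expect_true(is.na(cls$timer_dependent[1]))
  expect_true(cls$timer_dependent[2])   # 0.20 normal, 0.30 without timer
  expect_false(cls$timer_dependent[3])  # resistant either way
  # boundary: cleavage exactly at threshold is resistant
  oc$cleav60[1] <- 0.25
  expect_false(classify_cells(oc)$capable[1])
  expect_error(classify_cells(oc, t_eval = 45), "checkpoint")
})

test_that("XIAP-SMAC balance is a log-ratio, zero at equimolarity", {
  expect_equal(xiap_smac_balance(0.3, 0.3), 0)
  expect_equal(xiap_smac_balance(1, 0.1), 1)
  expect_equal(xiap_smac_balance(0.2, 0.5), -xiap_smac_balance(0.5, 0.2))
  expect_error(xiap_smac_balance(0, 1), "positive")
})

test_that("ROC AUC equals the pair-counting oracle, with ties", {
  set.seed(5)
  scores <- round(rnorm(200), 1)  # rounding forces ties
  labels <- runif(200) < plogis(scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  # against an established implementation
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))),
               tolerance = 1e-12)
  # perfect separation and orientation flip
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  lo <- roc_auc(c(10, 11, 12, 1, 2), c(0, 0, 0, 1, 1))
  expect_equal(lo$auc, 1)
  expect_equal(lo$orientation, "-")
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("uninformative scores give AUC near one half", {
  set.seed(11)
  scores <- rnorm(10000)
  labels <- runif(10000) < 0.5
  raw <- roc_auc(scores, labels)
  # reported AUC is folded above 0.5; the raw statistic is near 0.5
  r <- rank(scores)
  auc_raw <- (sum(r[labels]) - sum(labels) * (sum(labels) + 1) / 2) /
    (sum(labels) * sum(!labels))
  expect_lt(abs(auc_raw - 0.5), 0.02)
  expect_lt(raw$auc, 0.52)
})

test_that("Webb synergy formula, strict flag and degenerate inputs", {
  s <- webb_synergy(t = 60, s_normal = 1, s_no_xiap = 0.5,
                    s_no_timer = 0.5, s_both = 0.25)
  expect_equal(s$score, 1.0)
  expect_false(s$synergistic)
  s2 <- webb_synergy(t = 60, s_normal = 0.8, s_no_xiap = 0.4,
                     s_no_timer = 0.6, s_both = 0.1)
  expect_equal(s2$score, 1 / 3, tolerance = 1e-9)
  expect_true(s2$synergistic)
  # exactly 0.9 is not synergistic (strict inequality)
  s3 <- webb_synergy(t = 60, s_normal = 1, s_no_xiap = 1, s_no_timer = 1,
                     s_both = 0.9)
  expect_equal(s3$score, 0.9)
  expect_false(s3$synergistic)
  expect_warning(s4 <- webb_synergy(t = 60, s_normal = 1, s_no_xiap = 0,
                                    s_no_timer = 0.5, s_both = 0),
                 "undefined")
  expect_true(is.na(s4$score))
})

test_that("timer contribution is nonnegative and grows with weaker C9
           binding", {
  co <- sample_cohort(n = 8, seed = 21)
  oc <- run_conditions(co, momp_fraction = 1, horizon = 60,
                       variants = c("normal", "no_timer"))
  tc <- timer_contribution(oc, 60)
  expect_true(all(tc$delta >= -1e-6))
  # faster C9 dissociation strengthens the timer's brake on cleavage
  p_hi <- default_parameters(koff_C9 = 10 * default_parameters()[["koff_C9"]])
  oc_hi <- run_conditions(co[1, ], momp_fraction = 1, horizon = 60,
                          params = p_hi,
                          variants = c("normal", "no_timer"))
  tc_hi <- timer_contribution(oc_hi, 60)
  expect_gt(tc_hi$delta[1], tc$delta[tc$id == co$id[1]] - 1e-9)
})
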