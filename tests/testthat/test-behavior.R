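test_that("stage schedules satisfy the free-block and balance rules", {
  for (seed in c(1, 2, 3, 10)) {
    sch <- makeSchedule("CD", seed = seed)
    free <- sch[sch$type == "free", ]
    expect_identical(nrow(free), 4L)
    expect_identical(anyDuplicated(free[, c("pairing", "rewarded_side")]),
                     0L)
    closed <- sch[sch$type == "closed", ]
    expect_identical(nrow(closed), 30L)
    expect_identical(unname(table(closed$rewarded_side)["left"]), 15L)
    expect_identical(unname(table(closed$rewarded_side)["right"]), 15L)
  }
  expect_error(makeSchedule("SD", n_closed = 31), "even")
  expect_error(makeSchedule("SD", max_run = 1), "max_run")
})

test_that("no schedule ever exceeds the side-run cap", {
  for (seed in 1:500) {
    sch <- makeSchedule("SD", seed = seed, max_run = 3)
    runs <- rle(sch$rewarded_side[sch$type == "closed"])$lengths
    expect_lte(max(runs), 3L)
  }
})

test_that("schedules are deterministic given the seed", {
  expect_identical(makeSchedule("CDR", seed = 42),
                   makeSchedule("CDR", seed = 42))
})

test_that("criterion detection handles the canonical cases", {
  C <- "correct"; E <- "incorrect"; O <- "omission"
  expect_identical(detectCriterion(rep(C, 8)), 8L)
  expect_identical(detectCriterion(c(E, E, rep(C, 8))), 10L)
  expect_identical(detectCriterion(rep(c(C, E), 15)), NA_integer_)
  # omissions are non-correct
  expect_identical(detectCriterion(c(O, rep(C, 8))), 9L)
  # criterion never before the 8th trial of a session
  for (n in 1:7)
    expect_identical(detectCriterion(rep(C, n)), NA_integer_)
  # windows never span sessions
  expect_identical(
    detectCriterion(rep(C, 8), sessions = c(1, 1, 1, 1, 2, 2, 2, 2)),
    NA_integer_)
  expect_identical(
    detectCriterion(c(rep(C, 4), rep(C, 8)),
                    sessions = c(rep(1, 4), rep(2, 8))), 12L)
})

test_that("criterion detection equals the window-enumeration oracle", {
  # all single-session outcome sequences up to length 11 (subset here;
  # the exhaustive length-12 sweep runs in the acceptance suite)
  for (n in c(8, 9, 10, 11)) {
    for (bits in 0:(2^n - 1)) {
      outc <- ifelse(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0,
                     "correct", "incorrect")
      expect_identical(detectCriterion(outc), criterionOracle(outc))
    }
  }
})

test_that("strict-run reading requires 8 consecutive corrects", {
  C <- "correct"; E <- "incorrect"
  expect_identical(detectCriterion(rep(C, 8), mode = "run"), 8L)
  # 8-in-10 window patterns with interleaved errors never satisfy a run
  expect_identical(detectCriterion(c(C, C, C, C, E, C, C, C, C, C),
                                   mode = "run"), NA_integer_)
  expect_identical(detectCriterion(c(E, E, rep(C, 8)), mode = "run"), 10L)
})

test_that("stage scoring applies the trial/error/latency rules", {
  C <- "correct"; E <- "incorrect"; O <- "omission"
  mklog <- function(outcomes, sessions = rep(1L, length(outcomes)),
                    lat = 10) {
    data.frame(mouse = "m", group = "g", stage = "SD",
               session = sessions,
               trial_index = as.integer(ave(sessions, sessions,
                                            FUN = seq_along)),
               trial_type = "closed", outcome = outcomes,
               latency_s = ifelse(outcomes == O, NA_real_, lat))
  }
  # 8 straight correct: 8 trials, 0 errors
  s <- scoreStage(mklog(rep(C, 8)))
  expect_identical(c(s$total_trials, s$total_errors), c(8L, 0L))
  expect_true(s$criterion_reached)

  # E,E then 8 correct: 10 trials, 2 errors
  s2 <- scoreStage(mklog(c(E, E, rep(C, 8))))
  expect_identical(c(s2$total_trials, s2$total_errors), c(10L, 2L))

  # omission-first: 9 trials, 1 error (omission counted as error)
  s3 <- scoreStage(mklog(c(O, rep(C, 8))))
  expect_identical(c(s3$total_trials, s3$total_errors), c(9L, 1L))
  expect_identical(s3$median_latency_s, 10)   # omission latency excluded

  # failed 30-trial session then next-day 8 straight: 38 total trials,
  # errors carried over from session 1, criterion at session 2 trial 8
  sess1 <- rep(c(C, E), 15)
  log <- mklog(c(sess1, rep(C, 8)),
               sessions = c(rep(1L, 30), rep(2L, 8)))
  s4 <- scoreStage(log)
  expect_identical(s4$total_trials, 38L)
  expect_identical(s4$total_errors, sum(sess1 != C))
  expect_identical(s4$criterion_session, 2L)
  expect_identical(s4$criterion_trial, 8L)

  # criterion never reached: totals cover all closed trials
  s5 <- scoreStage(mklog(rep(c(C, E), 15)))
  expect_false(s5$criterion_reached)
  expect_identical(s5$total_trials, 30L)

  # free trials are excluded from scores
  free <- data.frame(mouse = "m", group = "g", stage = "SD", session = 1L,
                     trial_index = 1:4, trial_type = "free",
                     outcome = c(C, E, O, C), latency_s = c(5, 5, NA, 5))
  s6 <- scoreStage(rbind(free, mklog(rep(C, 8))))
  expect_identical(c(s6$total_trials, s6$total_errors), c(8L, 0L))

  expect_error(scoreStage(rbind(mklog(rep(C, 8)),
                                transform(mklog(rep(C, 8)),
                                          stage = "CD"))), "mixes stages")
})

test_that("appending pre-criterion errors never lowers the totals", {
  C <- "correct"; E <- "incorrect"
  base <- c(E, rep(C, 8))
  mk <- function(o) data.frame(mouse = "m", group = "g", stage = "SD",
                               session = 1L,
                               trial_index = seq_along(o),
                               trial_type = "closed", outcome = o,
                               latency_s = 10)
  s_base <- scoreStage(mk(base))
  s_more <- scoreStage(mk(c(E, E, base)))
  expect_gte(s_more$total_trials, s_base$total_trials)
  expect_gte(s_more$total_errors, s_base$total_errors)
})

test_that("simulated perfect learners reach criterion at trial 8", {
  for (seed in 1:10) {
    sim <- simulateBehavior(p0 = 1, pinf = 1, p_omit = 0, seed = seed)
    s <- scoreStage(sim$log)
    expect_identical(c(s$total_trials, s$total_errors), c(8L, 0L))
  }
})

test_that("chance-level mice need more trials than perfect learners", {
  trials_chance <- vapply(1:200, function(seed) {
    sim <- simulateBehavior(p0 = 0.5, pinf = 0.5, p_omit = 0,
                            max_sessions = 3, seed = seed)
    scoreStage(sim$log)$total_trials
  }, numeric(1))
  expect_gt(mean(trials_chance), 8)
})

test_that("behavior simulation is deterministic and well-formed", {
  a <- simulateBehavior(seed = 99)
  b <- simulateBehavior(seed = 99)
  expect_identical(a$log, b$log)
  cl <- a$log[a$log$trial_type == "closed", ]
  expect_true(all(cl$trial_index <= 30))
  free <- a$log[a$log$trial_type == "free", ]
  expect_identical(nrow(free), 4L * max(a$log$session))
  # free trials precede closed trials within each session
  for (s in unique(a$log$session)) {
    ss <- a$log[a$log$session == s, ]
    expect_identical(ss$trial_type,
                     c(rep("free", 4),
                       rep("closed", nrow(ss) - 4L)))
  }
})

test_that("scoreSessions scores every mouse x stage cell", {
  logs <- rbind(simulateBehavior(mouse = "m1", stage = "SD", seed = 1)$log,
                simulateBehavior(mouse = "m1", stage = "CD", seed = 2)$log,
                simulateBehavior(mouse = "m2", stage = "SD", seed = 3)$log)
  sc <- scoreSessions(logs)
  expect_identical(nrow(sc), 3L)
  expect_setequal(paste(sc$mouse, sc$stage),
                  c("m1 SD", "m1 CD", "m2 SD"))
})
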