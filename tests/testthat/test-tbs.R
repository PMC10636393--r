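test_that("iTBS defaults give 40 trains x 30 pulses = 1200 over a 325.7-s span", {
  p <- buildITBS()
  expect_equal(p@totalPulses, 1200L)
  expect_equal(p@duration, 40 * 2 + 39 * 6.3)
  expect_true(all(diff(p@pulseTimes) > 0))
  one <- buildITBS(tbsParams(nTrains = 1))
  expect_equal(one@totalPulses, 30L)
  expect_equal(one@duration, 2)
})

test_that("cTBS paper mode gives 1800 pulses over 120 s; conventional mode 600", {
  p <- buildCTBS()
  expect_equal(p@totalPulses, 1800L)
  expect_equal(p@duration, 600 * 0.2)
  expect_equal(p@pulseTimes[1:3], c(0, 0.02, 0.04))
  conv <- buildCTBS(tbsParams(ctbsMode = "conventional"))
  expect_equal(conv@totalPulses, 600L)
  expect_equal(conv@duration, 40)
  single <- buildCTBS(tbsParams(nBurstsCtbs = 1))
  expect_equal(single@pulseTimes, c(0, 0.02, 0.04))
})

test_that("pulse totals follow the symbolic identities for arbitrary valid parameters", {
  for (seed in 1:5) {
    set.seed(seed)
    ppb <- sample(2:5, 1)
    bp <- sample(c(0.2, 0.25, 0.5), 1)
    nb <- round(sample(5:12, 1))
    nt <- sample(2:8, 1)
    pars <- tbsParams(pulsesPerBurst = ppb, intraBurstFrequency = 50,
                      burstPeriod = bp, trainDuration = nb * bp,
                      nTrains = nt, nBurstsCtbs = sample(50:300, 1))
    it <- buildITBS(pars)
    expect_equal(it@totalPulses, as.integer(nt * nb * ppb))
    ct <- buildCTBS(pars)
    expect_equal(ct@totalPulses, as.integer(pars$nBurstsCtbs * ppb))
  }
})

test_that("intra-burst spacing is exactly 20 ms and burst onsets 200 ms apart", {
  p <- buildCTBS()
  d <- diff(p@pulseTimes)
  expect_equal(unique(round(d[seq_along(d) %% 3 != 0], 10)), 0.02)
  expect_equal(unique(round(d[seq_along(d) %% 3 == 0], 10)), 0.2 - 0.04)
  expect_error(tbsParams(pulsesPerBurst = 11),   # burst would outlast period
               "fit inside")
  expect_error(tbsParams(trainDuration = 2.05), "whole number")
  expect_error(tbsParams(intensity = 1.2), "RMT")
})

test_that("sessions concatenate target protocols with pauses and add their pulses", {
  tg <- data.frame(parcel_id = c("P001", "P002", "P003"),
                   protocol = c("iTBS", "iTBS", "iTBS"),
                   hyper_count = 0L, hypo_count = 3L, total_burden = 3L,
                   depth_mm = 20, network = "CEN", rank = 1:3)
  rx <- new("TargetPrescription", targets = tg,
            parameters = list(max_targets = 3, depth_max = 30), reason = "")
  s <- buildSession(rx)
  expect_equal(s$duration, 3 * 325.7 + 2 * 60)
  expect_equal(s$totalPulses, 3 * 1200L)
  one <- rx
  one@targets <- tg[1, , drop = FALSE]
  one@targets$protocol <- "cTBS"
  expect_equal(buildSession(one)$duration, 120)
  empty <- new("TargetPrescription", targets = tg[0, ],
               parameters = list(max_targets = 3), reason = "no_candidates")
  expect_error(buildSession(empty), "empty")
})

test_that("the accelerated course gives 25 sessions with hour gaps", {
  course <- buildCourse(sessionSchedule(), sessionDuration = 1097.1)
  expect_equal(nrow(course), 25)
  expect_equal(length(unique(course$day)), 5)
  day1 <- course$start_s[course$day == 1]
  expect_equal(unique(diff(day1)), 1097.1 + 3600)
  expect_error(buildCourse(sessionSchedule(dayLengthH = 2), 3600),
               "too short")
})
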