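make_log <- function(..., duration = 60) {
  ev <- data.frame(...)
  attr(ev, "duration") <- duration
  ev
}

test_that("interval_check finds bite/breath events inside mouth-locks (half-open)", {
  ev <- make_log(
    pair_id = "p", fish_id = c(1, 1, 2, 1),
    behavior = c("mouth_lock", "bite_strike", "bite_strike", "surface_breath"),
    start_min = c(4, 5, 6, 3.9),
    duration_min = c(2, 0, 0, 0)
  )
  v <- interval_check(ev)
  expect_equal(nrow(v), 1)                 # bite at 5 inside [4, 6)
  expect_equal(v$start_min, 5)             # bite at 6 and breath at 3.9 pass
  expect_error(interval_check(ev[, 1:3]), "missing column")
  bad <- ev; bad$start_min[2] <- NA
  expect_error(interval_check(bad), "line 2")
})

test_that("first occurrences take the minimum start, NA when absent", {
  ev <- make_log(pair_id = "p", fish_id = 1,
                 behavior = c("surface_breath", "surface_breath", "bite_strike"),
                 start_min = c(2.1, 0.9, 3.5), duration_min = 0)
  fo <- first_occurrences(ev)
  expect_equal(unname(fo["surface_breath"]), 0.9)
  expect_equal(unname(fo["bite_strike"]), 3.5)
  expect_true(is.na(fo["mouth_lock"]))
  expect_error(first_occurrences(ev[0, ]), "empty")
})

test_that("simulated logs show the observed onset ordering on average", {
  fo <- withr::with_seed(77, sapply(1:40, function(i) {
    first_occurrences(simulate_behavior("x", behavior_params())$events)
  }))
  m <- rowMeans(fo)
  expect_lt(m["surface_breath"], m["bite_strike"])
  expect_lt(m["bite_strike"], m["mouth_lock"])
})

test_that("mouth-lock summary computes count, mean duration, time fraction", {
  ev <- make_log(pair_id = "p", fish_id = 1,
                 behavior = rep("mouth_lock", 12),
                 start_min = seq(2, 46, by = 4), duration_min = 1.29)
  s <- mouthlock_summary(ev, duration = 60)
  expect_equal(s$count, 12)
  expect_equal(s$mean_duration, 1.29)
  expect_equal(s$fraction_time, 12 * 1.29 / 60)      # 25.8%
  # durations summing to 16.128 min of 60 give the 26.88% fraction
  ev2 <- make_log(pair_id = "p", fish_id = 1, behavior = "mouth_lock",
                  start_min = 10, duration_min = 16.128)
  expect_equal(mouthlock_summary(ev2, 60)$fraction_time, 0.2688)
  empty <- mouthlock_summary(make_log(pair_id = character(0),
                                      fish_id = integer(0),
                                      behavior = character(0),
                                      start_min = numeric(0),
                                      duration_min = numeric(0)))
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$mean_duration))
  expect_equal(empty$fraction_time, 0)
  # duplicated per-fish mouth-lock rows count once
  ev3 <- make_log(pair_id = "p", fish_id = c(1, 2), behavior = "mouth_lock",
                  start_min = 10, duration_min = 2)
  expect_equal(mouthlock_summary(ev3, 60)$count, 1)
})

test_that("window grids follow floor((T - width)/step) + 1 and half-open starts", {
  ev <- make_log(pair_id = "p", fish_id = 1, behavior = "bite_strike",
                 start_min = 1.5, duration_min = 0)
  ws <- window_series(ev, 1, "bite_strike", width = 2, step = 1, duration = 60)
  expect_equal(nrow(ws), 59)
  expect_equal(ws$frequency[1:3], c(1, 1, 0))   # in [0,2) and [1,3) only
  expect_equal(sum(ws$frequency), 2)
  empty <- window_series(ev, 2, "bite_strike", duration = 60)
  expect_true(all(empty$frequency == 0))
  expect_warning(window_series(ev, 1, "bite_strike", width = 1, step = 2,
                               duration = 60), "gaps")
  expect_error(window_series(ev, 1, "bite_strike", width = 100,
                             duration = 60), "wider")
})

test_that("non-overlapping windows partition the event count; translation invariance", {
  set.seed(2)
  ev <- make_log(pair_id = "p", fish_id = 1, behavior = "bite_strike",
                 start_min = runif(100, 0, 60), duration_min = 0)
  ws <- window_series(ev, 1, "bite_strike", width = 2, step = 2, duration = 60)
  expect_equal(sum(ws$frequency), 100)
  # shifting all events and the observation by delta leaves the series unchanged
  delta <- 8
  ev2 <- ev; ev2$start_min <- ev2$start_min + delta
  ws2 <- window_series(ev2, 1, "bite_strike", width = 2, step = 2,
                       duration = 60 + delta)
  expect_equal(ws2$frequency[-(1:(delta / 2))], ws$frequency)
})

test_that("behavioral synchrony is Pearson r, symmetric, and guards degeneracy", {
  a <- data.frame(window_start = 0:9, frequency = c(1:5, 5:1),
                  total_duration = 0)
  b <- a; b$frequency <- a$frequency * 2 + 3
  expect_equal(behavior_synchrony(a, b), 1)
  expect_equal(behavior_synchrony(b, a), behavior_synchrony(a, b))
  neg <- a; neg$frequency <- max(a$frequency) + min(a$frequency) - a$frequency
  expect_equal(behavior_synchrony(a, neg), -1)
  flat <- a; flat$frequency <- 4
  expect_error(behavior_synchrony(a, flat), "zero-variance")
  short <- a[1:2, ]
  expect_error(behavior_synchrony(short, short), "3 windows")
  off <- a; off$window_start <- off$window_start + 1
  expect_error(behavior_synchrony(a, off), "grids")
})
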