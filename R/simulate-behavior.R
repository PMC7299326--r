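#' Parameters for the dyadic behavior simulator
#'
#' Defaults reproduce the observed fight structure: surface-breathing starts
#' around 0.94 min, biting/striking around 3.49 min and mouth-locking around
#' 10.60 min into the fight; over a 60-min bout there are on average 12.12
#' mouth-locking episodes of 1.29 min each. Bite/strike and surface-breath
#' rates and the intensity-modulation sds are simulator conventions (the
#' source observations report onsets and mouth-lock structure, not rates).
#'
#' @param duration Observation duration in minutes.
#' @param first_breath_mean,first_breath_sd Lognormal moments (min) of the
#'   first surface-breathing event.
#' @param first_bite_mean,first_bite_sd Lognormal moments of the first
#'   bite/strike.
#' @param first_mouthlock_mean,first_mouthlock_sd Lognormal moments of the
#'   first mouth-locking onset.
#' @param mouthlock_count_mean Target expected number of mouth-lock episodes
#'   within `duration`; the exponential inter-episode gap is calibrated to
#'   hit it (see [simulate_behavior()]).
#' @param mouthlock_duration_mean,mouthlock_duration_sd Lognormal moments of
#'   episode durations (min).
#' @param bite_rate,breath_rate Baseline event rates (events/min).
#' @param shared_intensity_sd Sd of the pair-shared log-rate modulation per
#'   block; this is what makes the two opponents' activity co-fluctuate.
#' @param fish_noise_sd Sd of the fish-specific log-rate noise per block.
#' @param block_width Width (min) of the rate-modulation blocks.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A validated list of class `"pibs_behavior_params"`.
#' @export
behavior_params <- function(duration = 60,
                            first_breath_mean = 0.94, first_breath_sd = 0.24,
                            first_bite_mean = 3.49, first_bite_sd = 0.60,
                            first_mouthlock_mean = 10.60, first_mouthlock_sd = 1.12,
                            mouthlock_count_mean = 12.12,
                            mouthlock_duration_mean = 1.29,
                            mouthlock_duration_sd = 0.24,
                            bite_rate = 6, breath_rate = 3,
                            shared_intensity_sd = 0.8, fish_noise_sd = 0.2,
                            block_width = 2, seed = NULL) {
  p <- list(duration = duration,
            first_breath_mean = first_breath_mean, first_breath_sd = first_breath_sd,
            first_bite_mean = first_bite_mean, first_bite_sd = first_bite_sd,
            first_mouthlock_mean = first_mouthlock_mean,
            first_mouthlock_sd = first_mouthlock_sd,
            mouthlock_count_mean = mouthlock_count_mean,
            mouthlock_duration_mean = mouthlock_duration_mean,
            mouthlock_duration_sd = mouthlock_duration_sd,
            bite_rate = bite_rate, breath_rate = breath_rate,
            shared_intensity_sd = shared_intensity_sd,
            fish_noise_sd = fish_noise_sd, block_width = block_width,
            seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(x) is.finite(x) && x >= 0, logical(1))))
    stop("behavior parameters must be finite and non-negative")
  stopifnot(p$duration > 0, p$block_width > 0,
            p$first_breath_mean > 0, p$first_bite_mean > 0,
            p$first_mouthlock_mean > 0, p$mouthlock_count_mean > 0,
            p$mouthlock_duration_mean > 0, p$bite_rate >= 0, p$breath_rate >= 0)
  if (!(p$first_breath_mean < p$first_bite_mean &&
        p$first_bite_mean < p$first_mouthlock_mean))
    stop("onset means must be ordered: breath < bite < mouth-lock")
  class(p) <- "pibs_behavior_params"
  p
}

# Exponential gap mean such that the expected number of episode onsets in
# [first onset, duration] hits the target, using the second-order renewal
# expansion E N(t) = t/mu + sigma^2/(2 mu^2) - 1/2 for the cycle
# C = duration + gap (exact for zero-duration episodes).
calibrate_gap <- function(p) {
  t <- p$duration - p$first_mouthlock_mean
  if (t <= 0) stop("duration must exceed the mean mouth-lock onset")
  f <- function(g) {
    mu <- g + p$mouthlock_duration_mean
    s2 <- g^2 + p$mouthlock_duration_sd^2
    1 + t / mu + s2 / (2 * mu^2) - 0.5 - p$mouthlock_count_mean
  }
  stats::uniroot(f, c(1e-3, 10 * p$duration))$root
}

#' Simulate a dyadic fighting event log
#'
#' Mouth-lock episodes follow an alternating renewal process: the first
#' onset is lognormal, episode durations are lognormal (truncated to the
#' observation window), and inter-episode gaps are exponential with mean
#' calibrated so the expected episode count matches
#' `mouthlock_count_mean`. Bite/strike and surface-breath events of each
#' fish are Poisson within blocks whose log-rate is a pair-shared draw plus
#' fish-specific noise; events falling inside a mouth-lock interval or
#' before the behavior's (fish-specific) first-occurrence time are deleted,
#' so these behaviors happen only between mouth-locks, as observed.
#'
#' @param pair_id Identifier written into the log.
#' @param params Parameters from [behavior_params()].
#' @return A list of class `"pibs_behavior"` with `events` (data frame
#'   `pair_id`, `fish_id`, `behavior`, `start_min`, `duration_min`;
#'   mouth-lock rows duplicated for both fish), `truth` (block log-rates and
#'   episode table) and `params`. Bite/breath rows have `duration_min = 0`.
#' @export
simulate_behavior <- function(pair_id = "pair1", params = behavior_params()) {
  stopifnot(inherits(params, "pibs_behavior_params"))
  p <- params
  with_seed(p$seed, {
    gap_mean <- calibrate_gap(p)
    mp <- lnorm_params(p$first_mouthlock_mean, p$first_mouthlock_sd)
    dp <- lnorm_params(p$mouthlock_duration_mean, p$mouthlock_duration_sd)
    onset <- stats::rlnorm(1, mp[1], mp[2])
    ml_start <- numeric(0); ml_dur <- numeric(0)
    s <- onset
    while (s < p$duration) {
      d <- min(stats::rlnorm(1, dp[1], dp[2]), p$duration - s)
      ml_start <- c(ml_start, s); ml_dur <- c(ml_dur, d)
      s <- s + d + stats::rexp(1, 1 / gap_mean)
    }

    n_blocks <- ceiling(p$duration / p$block_width)
    block_start <- (seq_len(n_blocks) - 1L) * p$block_width
    rates <- list(bite_strike = p$bite_rate, surface_breath = p$breath_rate)
    shared <- lapply(rates, function(.) stats::rnorm(n_blocks, 0, p$shared_intensity_sd))
    onset_means <- c(bite_strike = p$first_bite_mean,
                     surface_breath = p$first_breath_mean)
    onset_sds <- c(bite_strike = p$first_bite_sd,
                   surface_breath = p$first_breath_sd)

    in_mouthlock <- function(t) {
      if (!length(ml_start)) return(rep(FALSE, length(t)))
      vapply(t, function(x) any(x >= ml_start & x < ml_start + ml_dur),
             logical(1))
    }

    rows <- list()
    truth_rates <- list()
    for (beh in names(rates)) {
      # the behavior's first occurrence is a pair-level event at a lognormal
      # onset (this is the quantity reported for real fights); later events
      # follow the block-modulated Poisson processes of each fish
      op <- lnorm_params(onset_means[[beh]], max(onset_sds[[beh]], 1e-9))
      first <- stats::rlnorm(1, op[1], op[2])
      first_fish <- sample(1:2, 1)
      if (first < p$duration && !in_mouthlock(first))
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = pair_id, fish_id = first_fish, behavior = beh,
          start_min = first, duration_min = 0, stringsAsFactors = FALSE)
      for (fish in 1:2) {
        noise <- stats::rnorm(n_blocks, 0, p$fish_noise_sd)
        lr <- log(rates[[beh]]) + shared[[beh]] + noise
        truth_rates[[paste(fish, beh, sep = ".")]] <- lr
        times <- unlist(lapply(seq_len(n_blocks), function(b) {
          k <- stats::rpois(1, exp(lr[b]) * p$block_width)
          if (k == 0) return(numeric(0))
          sort(stats::runif(k, block_start[b],
                            min(block_start[b] + p$block_width, p$duration)))
        }))
        # gating: drop events before the onset or inside a mouth-lock
        times <- times[times > first & !in_mouthlock(times)]
        if (length(times))
          rows[[length(rows) + 1L]] <- data.frame(
            pair_id = pair_id, fish_id = fish, behavior = beh,
            start_min = times, duration_min = 0, stringsAsFactors = FALSE)
      }
    }
    if (length(ml_start))
      for (fish in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = pair_id, fish_id = fish, behavior = "mouth_lock",
          start_min = ml_start, duration_min = ml_dur, stringsAsFactors = FALSE)
    events <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pair_id = character(0), fish_id = integer(0),
                 behavior = character(0), start_min = numeric(0),
                 duration_min = numeric(0))
    events <- events[order(events$start_min, events$fish_id), ]
    rownames(events) <- NULL
    attr(events, "duration") <- p$duration
    structure(
      list(events = events,
           truth = list(block_log_rates = truth_rates,
                        mouthlock = data.frame(start = ml_start, duration = ml_dur),
                        gap_mean = gap_mean),
           params = p),
      class = "pibs_behavior"
    )
  })
}

#' Write a behavioral event log to CSV
#'
#' @param behavior Result of [simulate_behavior()], or a bare event data
#'   frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_event_log <- function(behavior, path) {
  ev <- if (inherits(behavior, "pibs_behavior")) behavior$events else behavior
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioral event log from CSV
#'
#' @param path CSV with columns `pair_id`, `fish_id`, `behavior`,
#'   `start_min`, `duration_min`.
#' @param duration Observation duration in minutes attached to the log.
#' @return Event data frame with a `duration` attribute.
#' @export
read_event_log <- function(path, duration = 60) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "fish_id", "behavior", "start_min", "duration_min")
  if (!all(need %in% names(ev)))
    stop("event log must have columns: ", paste(need, collapse = ", "))
  attr(ev, "duration") <- duration
  ev
}
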