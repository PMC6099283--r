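# Shared fixture builders; all randomness is driven by the caller's seed.

# Small censored sample with ties (rounded times) and ~70% events.
random_censored_sample <- function(n = sample(3:50, 1L), event_prob = 0.7,
                                   digits = 2L) {
  tm <- round(rexp(n, rate = 0.5), digits)
  ev <- runif(n) < event_prob
  censored_sample(tm, ev)
}

# A sample guaranteed to have at least one event.
random_censored_sample_with_event <- function(...) {
  repeat {
    s <- random_censored_sample(...)
    if (any(s$event)) return(s)
  }
}

# Bundle assembled by hand from constant replicate curves: each replicate i
# holds value[i] on [p_star[i], 1] and is undefined below.
constant_bundle <- function(values, p_stars) {
  reps <- Map(function(v, ps) {
    if (is.na(ps)) NULL else list(levels = ps, values = v, p0 = ps)
  }, values, p_stars)
  obs <- difference_curve(km_estimate(censored_sample(1, TRUE)),
                          km_estimate(censored_sample(1, TRUE)))
  structure(list(replicates = reps, p_stars = as.numeric(p_stars),
                 B = length(values), seed = 1L, n = 1L, m = 1L,
                 observed = obs, n_no_events = sum(is.na(p_stars))),
            class = "qdiff_bootstrap")
}

# Independent left-continuous empirical quantile oracle: smallest order
# statistic whose index i satisfies i/B >= q.
order_stat_quantile <- function(x, q) {
  sx <- sort(x)
  sx[which(seq_along(sx) / length(sx) >= q - 1e-12)[1L]]
}

# Write a two-group sample pair as a survival CSV for io/cli tests.
write_survival_csv <- function(s1, s2, path, status_codes = c(event = "1",
                                                              cens = "0")) {
  df <- data.frame(
    time = c(s1$time, s2$time),
    status = ifelse(c(s1$event, s2$event),
                    status_codes[["event"]], status_codes[["cens"]]),
    group = rep(1:2, c(length(s1$time), length(s2$time))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
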