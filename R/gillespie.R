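#' Exact stochastic simulation of a single channel
#'
#' Simulates one continuous-time Markov chain path of the gating-and-block
#' scheme by the Gillespie (direct) method: the waiting time in state `j`
#' is exponential with rate `-A[j, j]` (total outflow under the
#' column-generator convention) and the next state is drawn proportional to
#' the outgoing rates `A[i, j]`. A state with zero outflow is absorbing and
#' the path legally halts there.
#'
#' @param generator Generator matrix from [build_generator()].
#' @param initial_state State index (1-based, leftmost closed state = 1) or
#'   state label.
#' @param duration Simulated time, > 0.
#' @param seed Integer RNG seed; the path is reproducible given the seed.
#' @return A tibble of class `channel_path` with columns `time` (jump
#'   times, starting at 0), `state` (index) and `state_label`; attribute
#'   `seed` records the seed, `duration` the horizon.
#' @examples
#' A <- build_generator(rate_set(3, 0, 1, 1))
#' simulate_channel(A, 1, duration = 5, seed = 42)
#' @export
simulate_channel <- function(generator, initial_state = 1L, duration, seed) {
  A <- check_generator(generator)
  n <- nrow(A)
  labels <- state_labels(A)
  if (is.character(initial_state)) {
    initial_state <- match(initial_state, labels)
  }
  if (is.na(initial_state) || initial_state < 1L || initial_state > n) {
    stop("invalid `initial_state`", call. = FALSE)
  }
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0) {
    stop("`duration` must be a single positive time", call. = FALSE)
  }
  set.seed(as.integer(seed))

  out_rate <- -diag(unclass(A))
  jumps <- lapply(seq_len(n), function(j) {
    r <- unclass(A)[, j]
    r[j] <- 0
    idx <- unname(which(r > 0))
    list(idx = idx, cum = cumsum(r[idx]) / sum(r[idx]))
  })

  t_now <- 0
  s_now <- as.integer(initial_state)
  times <- t_now
  states <- s_now
  while (TRUE) {
    rate <- out_rate[s_now]
    if (rate <= 0) break  # absorbing
    t_next <- t_now + stats::rexp(1, rate)
    if (t_next > duration) break
    jl <- jumps[[s_now]]
    s_now <- jl$idx[findInterval(stats::runif(1), jl$cum,
                                 rightmost.closed = TRUE) + 1L]
    t_now <- t_next
    times <- c(times, t_now)
    states <- c(states, s_now)
  }
  out <- tibble::tibble(time = times, state = states,
                        state_label = labels[states])
  structure(out, class = c("channel_path", class(out)),
            seed = as.integer(seed), duration = duration)
}

state_at <- function(path_times, path_states, query_times) {
  path_states[findInterval(query_times, path_times)]
}

#' Monte Carlo estimate of the open probability of a channel ensemble
#'
#' Simulates `n_channels` independent channels (initial states drawn from
#' `x0`) and estimates the open probability at each grid time as the
#' fraction of channels open, with the binomial standard error
#' `sqrt(p(1-p)/N)`. Each channel uses its own deterministic RNG stream
#' seeded with `seed + channel index`, so ensembles are reproducible and
#' embarrassingly parallel.
#'
#' @param generator Generator matrix.
#' @param x0 Initial-state distribution (default: all channels in the
#'   leftmost closed state).
#' @param times Nonnegative time grid.
#' @param n_channels Number of channels, >= 1.
#' @param seed Base integer seed.
#' @return A tibble of class `ensemble_estimate` with columns `time`,
#'   `open_prob`, `stderr`; attributes `n_channels` and `seed`.
#' @examples
#' A <- build_generator(rate_set(3, 0, 1, 1))
#' ensemble_open_probability(A, times = c(0, log(2), 5),
#'                           n_channels = 200, seed = 1)
#' @export
ensemble_open_probability <- function(generator, x0 = NULL, times,
                                      n_channels, seed) {
  A <- check_generator(generator)
  n <- nrow(A)
  if (is.null(x0)) x0 <- c(1, rep(0, n - 1L))
  check_prob_vector(x0, n)
  if (length(n_channels) != 1L || !is.finite(n_channels) || n_channels < 1) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  if (length(times) == 0 || any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be nonnegative", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  seed <- as.integer(seed)
  o <- n - 1L
  horizon <- max(times, .Machine$double.eps)

  out_rate <- -diag(unclass(A))
  jumps <- lapply(seq_len(n), function(j) {
    r <- unclass(A)[, j]
    r[j] <- 0
    idx <- unname(which(r > 0))
    list(idx = idx, cum = cumsum(r[idx]) / sum(r[idx]))
  })
  x0_cum <- cumsum(x0)

  open_count <- numeric(length(times))
  for (ch in seq_len(n_channels)) {
    set.seed(seed + ch)
    s_now <- findInterval(stats::runif(1), x0_cum,
                          rightmost.closed = TRUE) + 1L
    t_now <- 0
    path_t <- t_now
    path_s <- s_now
    while (TRUE) {
      rate <- out_rate[s_now]
      if (rate <= 0) break
      t_next <- t_now + stats::rexp(1, rate)
      if (t_next > horizon) break
      jl <- jumps[[s_now]]
      s_now <- jl$idx[findInterval(stats::runif(1), jl$cum,
                                   rightmost.closed = TRUE) + 1L]
      t_now <- t_next
      path_t <- c(path_t, t_now)
      path_s <- c(path_s, s_now)
    }
    open_count <- open_count + (state_at(path_t, path_s, times) == o)
  }
  p_hat <- open_count / n_channels
  out <- tibble::tibble(
    time = times,
    open_prob = p_hat,
    stderr = sqrt(p_hat * (1 - p_hat) / n_channels)
  )
  structure(out, class = c("ensemble_estimate", class(out)),
            n_channels = n_channels, seed = seed)
}
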