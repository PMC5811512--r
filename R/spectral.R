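#' Exact spectral solution of the master equation
#'
#' Diagonalises the generator so that the state distribution is the sum of
#' exponential relaxation modes
#' \deqn{x(t) = \sum_i c_i V_i e^{r_i t}}
#' with real eigenvalues `r_i <= 0` and coefficient vectors `c_i V_i` fixed
#' by the initial condition. For a voltage-clamp step from a strongly
#' hyperpolarised holding potential all channels start in the most-closed
#' state, which is the default `x0`.
#'
#' Tridiagonal generators with nonnegative off-diagonals are similar to
#' symmetric matrices, so the spectrum is real; imaginary parts below
#' `1e-10` times the spectral range are truncated (anything larger signals a
#' numerical bug and raises an error). Exactly one eigenvalue is zero (the
#' stationary mode); eigenvalues are returned sorted descending, zero first,
#' then slowest to fastest.
#'
#' @param generator Generator matrix from [build_generator()].
#' @param x0 Initial probability vector; default puts all mass on the
#'   leftmost (most closed) state.
#' @return An object of class `spectral_solution`: list with `values`
#'   (sorted eigenvalues), `coef` (matrix whose column `i` is `c_i V_i`),
#'   `x0`, and `state_labels`.
#' @examples
#' sol <- spectral_solve(build_generator(rate_set(3, 0, 1, 1)))
#' sol$values  # 0, -2, -3
#' @export
spectral_solve <- function(generator, x0 = NULL) {
  A <- check_generator(generator)
  n <- nrow(A)
  if (is.null(x0)) x0 <- c(1, rep(0, n - 1L))
  check_prob_vector(x0, n)

  e <- eigen(unclass(A))
  spread <- max(abs(Re(e$values)), max(abs(A)))
  if (max(abs(Im(e$values))) > 1e-10 * spread) {
    stop("complex eigenvalues beyond tolerance: generator is not a valid ",
         "tridiagonal birth-death scheme or is numerically degenerate",
         call. = FALSE)
  }
  values <- Re(e$values)
  V <- Re(e$vectors)

  zero_tol <- 1e-10 * max(abs(A))
  is_zero <- abs(values) < zero_tol
  if (sum(is_zero) != 1L) {
    stop("expected exactly one zero eigenvalue, found ", sum(is_zero),
         call. = FALSE)
  }
  values[is_zero] <- 0

  ord <- order(values, decreasing = TRUE)
  values <- values[ord]
  V <- V[, ord, drop = FALSE]

  cc <- solve(V, x0)
  coef <- V * rep(cc, each = n)
  dimnames(coef) <- list(state_labels(A), paste0("mode", seq_len(n)))

  structure(
    list(values = values, coef = coef, x0 = x0,
         state_labels = state_labels(A)),
    class = "spectral_solution"
  )
}

#' @export
print.spectral_solution <- function(x, ...) {
  cat("<spectral_solution> ", length(x$values), " states\n", sep = "")
  cat("  eigenvalues:", paste(signif(x$values, 6), collapse = ", "), "\n")
  invisible(x)
}

reconstruct_states <- function(solution, times) {
  # rows: times, cols: states; x(t) = sum_i coef[, i] exp(r_i t)
  E <- exp(outer(times, solution$values))  # length(times) x n
  E %*% t(solution$coef)
}

#' Open probability at given times
#'
#' Evaluates the open-state component of a spectral solution,
#' `O(t) = sum_i (c_i V_i)_O e^{r_i t}`.
#'
#' @param solution A [spectral_solve()] result.
#' @param t Nonnegative time(s).
#' @return Numeric vector of open probabilities, same length as `t`.
#' @examples
#' sol <- spectral_solve(build_generator(rate_set(3, 0, 1, 1)))
#' open_probability(sol, log(2))  # 0.625
#' @export
open_probability <- function(solution, t) {
  stopifnot(inherits(solution, "spectral_solution"))
  if (length(t) == 0 || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and nonnegative", call. = FALSE)
  }
  o <- length(solution$values) - 1L  # open state is second to last
  drop(exp(outer(t, solution$values)) %*% solution$coef[o, ])
}

#' Full state trajectory on a time grid
#'
#' Evaluates all state probabilities of a spectral solution on an increasing
#' nonnegative time grid and returns them in long (tidy) format, one row per
#' time point and state.
#'
#' @param solution A [spectral_solve()] result.
#' @param times Increasing, nonnegative time grid.
#' @return A tibble of class `channel_trajectory` with columns `time`,
#'   `state` (factor, `C_m, ..., O, B`) and `probability`.
#' @examples
#' sol <- spectral_solve(build_generator(rate_set(3, 0, 1, 1)))
#' trajectory(sol, c(0, log(2), 5))
#' @export
trajectory <- function(solution, times) {
  stopifnot(inherits(solution, "spectral_solution"))
  if (length(times) == 0 || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = FALSE)) {
    stop("`times` must be a nondecreasing nonnegative grid", call. = FALSE)
  }
  X <- reconstruct_states(solution, times)
  lb <- solution$state_labels
  out <- tibble::tibble(
    time = rep(times, times = length(lb)),
    state = factor(rep(lb, each = length(times)), levels = lb),
    probability = as.vector(X)
  )
  class(out) <- c("channel_trajectory", class(out))
  out
}

#' Matrix-exponential solution (independent oracle)
#'
#' Computes `exp(A t) x0` by scaling-and-squaring of the truncated Taylor
#' series, with no reference to the eigendecomposition. Used as an
#' independent oracle for the spectral and Putzer solvers.
#'
#' @param generator Generator matrix.
#' @param x0 Initial probability vector.
#' @param t Single nonnegative time.
#' @return The state probability vector at time `t`.
#' @examples
#' A <- build_generator(rate_set(3, 0, 1, 1))
#' matrix_exp_solve(A, c(1, 0, 0), log(2))
#' @export
matrix_exp_solve <- function(generator, x0, t) {
  A <- check_generator(generator)
  n <- nrow(A)
  check_prob_vector(x0, n)
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single nonnegative time", call. = FALSE)
  }
  if (t == 0) return(stats::setNames(as.numeric(x0), state_labels(A)))
  nrm <- max(colSums(abs(A))) * t
  s <- max(0L, ceiling(log2(max(nrm, 1))))
  B <- unclass(A) * (t / 2^s)
  E <- diag(n)
  term <- diag(n)
  for (k in 1:40) {
    term <- term %*% B / k
    E <- E + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) E <- E %*% E
  stats::setNames(drop(E %*% x0), state_labels(A))
}

distinct_eigen_check <- function(values, context) {
  spread <- max(diff(range(values)), max(abs(values)), .Machine$double.xmin)
  if (min(diff(sort(values))) < 1e-8 * spread) {
    stop("near-degenerate eigenvalues: ", context,
         " requires pairwise distinct eigenvalues", call. = FALSE)
  }
  invisible(values)
}

generator_eigenvalues <- function(A) {
  e <- eigen(unclass(A), only.values = TRUE)$values
  spread <- max(abs(Re(e)), max(abs(A)))
  if (max(abs(Im(e))) > 1e-10 * spread) {
    stop("complex eigenvalues beyond tolerance", call. = FALSE)
  }
  v <- Re(e)
  zero_tol <- 1e-10 * max(abs(A))
  if (sum(abs(v) < zero_tol) != 1L) {
    stop("expected exactly one zero eigenvalue", call. = FALSE)
  }
  v[abs(v) < zero_tol] <- 0
  sort(v, decreasing = TRUE)
}

#' Putzer-recursion solution (independent oracle)
#'
#' Evaluates `x(t) = (sum_i p_i(t) M_i) x0` where `M_1 = I`,
#' `M_i = (A - r_{i-1} I) M_{i-1}`, and the `p_i` solve the triangular
#' cascade `p_1' = r_1 p_1`, `p_i' = r_i p_i + p_{i-1}` with
#' `p_1(0) = 1`, `p_{i>1}(0) = 0`. For pairwise distinct eigenvalues the
#' cascade has the closed partial-fraction form
#' `p_i(t) = sum_{j<=i} e^{r_j t} / prod_{k<=i, k!=j} (r_j - r_k)`.
#' Refuses near-degenerate spectra rather than silently losing precision.
#'
#' @inheritParams matrix_exp_solve
#' @return The state probability vector at time `t`.
#' @examples
#' A <- build_generator(rate_set(3, 0, 1, 1))
#' putzer_solve(A, c(1, 0, 0), log(2))
#' @export
putzer_solve <- function(generator, x0, t) {
  A <- check_generator(generator)
  n <- nrow(A)
  check_prob_vector(x0, n)
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single nonnegative time", call. = FALSE)
  }
  r <- generator_eigenvalues(A)
  distinct_eigen_check(r, "the Putzer closed form")

  p <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) {
      denom <- prod(r[j] - r[seq_len(i)][-j])
      if (i == 1L) denom <- 1
      acc <- acc + exp(r[j] * t) / denom
    }
    p[i] <- acc
  }

  Ad <- unclass(A)
  M <- diag(n)
  x <- p[1] * (M %*% x0)
  for (i in 2:n) {
    M <- (Ad - r[i - 1L] * diag(n)) %*% M
    x <- x + p[i] * (M %*% x0)
  }
  stats::setNames(drop(x), state_labels(A))
}

#' Pre-exponential factor of the slowest relaxation mode
#'
#' Closed form for the coefficient of `e^{r_n t}` in the open-probability
#' component of the solution, where `r_n` is the slowest (least negative)
#' nonzero eigenvalue:
#' \deqn{(n-2)!\,\alpha^{n-2}\,(\delta + r_n) \big/ \prod_{i<n}(r_n - r_i)}
#' with `r_1 = 0`. Its sign decides peak existence: the slow mode decays
#' from above (a peak) exactly when the factor is positive, i.e. when
#' `delta + r_n < 0`.
#'
#' @param rates A [rate_set()] with `gamma > 0`.
#' @return A single number, the coefficient of the slowest exponential in
#'   `O(t)` for the all-closed initial condition.
#' @examples
#' slowest_preexponential(rate_set(3, 0, 1, 1))  # 1.5
#' @export
slowest_preexponential <- function(rates) {
  rates <- as_rate_set(rates)
  if (rates$gamma <= 0) {
    stop("`gamma` must be positive (blocker present)", call. = FALSE)
  }
  A <- build_generator(rates)
  r <- generator_eigenvalues(A)  # descending: 0, r_n, ..., r_2
  distinct_eigen_check(r, "the slowest-mode closed form")
  n <- length(r)
  r_slow <- r[2]
  others <- r[-2]
  factorial(n - 2) * rates$alpha^(n - 2) * (rates$delta + r_slow) /
    prod(r_slow - others)
}
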