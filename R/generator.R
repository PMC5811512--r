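#' Build the generator (Q-) matrix of the gating-and-block scheme
#'
#' Constructs the tridiagonal transition-rate matrix `A` governing
#' `x'(t) = A x(t)` over the states `C_m, ..., C_1, O, B` (leftmost = all
#' gates closed, blocked state last). Columns sum to zero, so probability is
#' conserved. With `j` open gates the forward (opening) rate is
#' `(m - j) * alpha` and the backward (closing) rate is `j * beta`;
#' the open state binds blocker at rate `gamma` and the blocked state
#' unbinds at rate `delta`.
#'
#' For `m = 1` this is the familiar three-state matrix
#' \deqn{A = \begin{pmatrix} -\alpha & \beta & 0 \\
#'   \alpha & -(\beta+\gamma) & \delta \\ 0 & \gamma & -\delta \end{pmatrix}}
#'
#' @param rates A [rate_set()].
#' @return An `n x n` numeric matrix (`n = m + 2`) with dimnames
#'   `C_m, ..., C_1, O, B` on both margins, class `c("generator_matrix",
#'   "matrix", "array")`.
#' @examples
#' build_generator(rate_set(3, 0, 1, 1))
#' build_generator(rate_set(1, 1, 1, 1, m = 2))
#' @export
build_generator <- function(rates) {
  rates <- as_rate_set(rates)
  m <- rates$m
  n <- m + 2L
  A <- matrix(0, n, n)
  # gating chain: state i (1..m+1) has j = i - 1 open gates
  for (i in seq_len(m)) {
    j <- i - 1L
    A[i + 1L, i] <- (m - j) * rates$alpha  # opening, j -> j + 1
  }
  for (i in 2L:(m + 1L)) {
    j <- i - 1L
    A[i - 1L, i] <- j * rates$beta         # closing, j -> j - 1
  }
  A[n, m + 1L] <- rates$gamma              # O -> B
  A[m + 1L, n] <- rates$delta              # B -> O
  diag(A) <- -colSums(A)
  labels <- c(paste0("C", seq(m, 1)), "O", "B")
  dimnames(A) <- list(labels, labels)
  class(A) <- c("generator_matrix", class(A))
  A
}

open_index <- function(A) nrow(A) - 1L

state_labels <- function(A) {
  lb <- rownames(A)
  if (is.null(lb)) c(paste0("C", seq(nrow(A) - 2L, 1L)), "O", "B") else lb
}

check_generator <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || nrow(A) < 3L) {
    stop("generator must be a square matrix with at least 3 states",
         call. = FALSE)
  }
  if (any(!is.finite(A))) stop("generator has non-finite entries", call. = FALSE)
  cs <- colSums(A)
  if (max(abs(cs)) > 1e-8 * max(1, max(abs(A)))) {
    stop("generator columns must sum to zero", call. = FALSE)
  }
  invisible(A)
}

check_prob_vector <- function(x0, n) {
  if (length(x0) != n || any(!is.finite(x0)) || any(x0 < -1e-12) ||
      abs(sum(x0) - 1) > 1e-8) {
    stop("`x0` must be a probability vector of length ", n, call. = FALSE)
  }
  invisible(x0)
}

#' Stationary distribution of a generator matrix
#'
#' Solves `A x = 0`, `sum(x) = 1`, `x >= 0` by least squares on the augmented
#' system `[A; 1'] x = [0; 1]`, which stays robust when eigenvalues are
#' nearly degenerate. Errors when the null space is not one-dimensional
#' (e.g. the all-zero matrix), because then no unique stationary
#' distribution exists.
#'
#' @param generator A generator matrix from [build_generator()].
#' @return A named probability vector over the states.
#' @examples
#' steady_state(build_generator(rate_set(3, 0, 1, 1)))
#' @export
steady_state <- function(generator) {
  A <- check_generator(generator)
  n <- nrow(A)
  sv <- svd(unclass(A), nu = 0, nv = 0)$d
  tol <- max(sv) * n * .Machine$double.eps * 100
  if (max(sv) == 0 || sum(sv < tol) != 1L) {
    stop("stationary distribution is not unique (null space dimension != 1)",
         call. = FALSE)
  }
  M <- rbind(unclass(A), rep(1, n))
  x <- qr.solve(M, c(rep(0, n), 1))
  x[abs(x) < 1e-15] <- 0
  names(x) <- state_labels(A)
  x
}

#' Blocked steady-state open probability, closed form
#'
#' For the m-gate scheme with blocker present the stationary open probability
#' is `O_ss = alpha^m * delta / (delta * (alpha + beta)^m + gamma * alpha^m)`.
#' Cross-validated in the test suite against the numeric null space.
#'
#' @param rates A [rate_set()].
#' @return Stationary open probability, a single number in `[0, 1]`.
#' @examples
#' steady_state_open(rate_set(3, 0, 1, 1))  # 0.5
#' @export
steady_state_open <- function(rates) {
  rates <- as_rate_set(rates)
  with(rates, alpha^m * delta / (delta * (alpha + beta)^m + gamma * alpha^m))
}

#' Stationary open probability without blocker
#'
#' With no blocking agent the `m` independent gates are each open with
#' probability `alpha / (alpha + beta)` at stationarity, so the channel is
#' open with probability `(alpha / (alpha + beta))^m`.
#'
#' @param alpha Gate opening rate, >= 0.
#' @param beta Gate closing rate, >= 0.
#' @param m Number of gates, integer >= 1.
#' @return A probability.
#' @examples
#' no_block_steady_open(1, 1, m = 2)  # 0.25
#' @export
no_block_steady_open <- function(alpha, beta, m = 1L) {
  check_rate(alpha, "alpha")
  check_rate(beta, "beta")
  if (alpha + beta == 0) stop("alpha + beta must be positive", call. = FALSE)
  (alpha / (alpha + beta))^m
}
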