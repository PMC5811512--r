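#' Kinetic rate set for an open-channel-block scheme
#'
#' Bundles the four rate constants of the linear gating-and-block scheme
#' `C_m <-> ... <-> C_1 <-> O <-> B` together with the gate count `m`.
#' The scheme has `m` closed states (one per combination of open gates under
#' the Hodgkin-Huxley convention of `m` equal and independent gates), one
#' open state and one blocked state, so `n = m + 2` states in total.
#'
#' Rates are in reciprocal milliseconds by convention; the mathematics is
#' unit-agnostic. The association rate `gamma` is the product of the binding
#' rate constant and the blocker concentration; pass `kappa` and
#' `concentration` instead of `gamma` to have it computed.
#'
#' @param alpha Gate opening rate (per gate), >= 0.
#' @param beta Gate closing rate (per gate), >= 0.
#' @param gamma Blocker association rate O -> B (kappa * concentration), >= 0.
#' @param delta Blocker dissociation rate B -> O, >= 0.
#' @param m Number of closed states (independent gates), integer >= 1.
#' @param kappa Optional binding rate constant; used with `concentration`
#'   when `gamma` is not given.
#' @param concentration Optional blocker concentration, used with `kappa`.
#'
#' @return An object of class `rate_set`: a named list with elements
#'   `alpha`, `beta`, `gamma`, `delta`, `m`.
#' @examples
#' rate_set(3, 0, 1, 1)
#' rate_set(2, 1, delta = 0.5, m = 2, kappa = 10, concentration = 0.1)
#' @export
rate_set <- function(alpha, beta, gamma = NULL, delta, m = 1L,
                     kappa = NULL, concentration = NULL) {
  if (is.null(gamma)) {
    if (is.null(kappa) || is.null(concentration)) {
      stop("supply either `gamma` or both `kappa` and `concentration`",
           call. = FALSE)
    }
    check_rate(kappa, "kappa")
    check_rate(concentration, "concentration")
    gamma <- kappa * concentration
  }
  check_rate(alpha, "alpha")
  check_rate(beta, "beta")
  check_rate(gamma, "gamma")
  check_rate(delta, "delta")
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         m = as.integer(m)),
    class = "rate_set"
  )
}

check_rate <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single finite nonnegative number",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>  C_", x$m, " <-> ... <-> O <-> B   (n = ", x$m + 2,
      " states)\n", sep = "")
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, delta = %g  [1/ms]\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' @export
format.rate_set <- function(x, ...) {
  sprintf("rate_set(alpha=%g, beta=%g, gamma=%g, delta=%g, m=%d)",
          x$alpha, x$beta, x$gamma, x$delta, x$m)
}

as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) return(x)
  stop("expected a `rate_set`", call. = FALSE)
}

#' Read / write a rate-set configuration file
#'
#' A flat key-value (YAML) file with keys `alpha`, `beta`, `gamma`, `delta`,
#' `m` and optionally `kappa` and `concentration` (in which case `gamma` may
#' be omitted and is computed as `kappa * concentration`). Unknown keys are
#' rejected so that typos do not silently change a run.
#'
#' @param path File path.
#' @param rates A [rate_set()].
#' @return `read_rate_config()` returns a [rate_set()];
#'   `write_rate_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' write_rate_config(rate_set(3, 0, 1, 1), p)
#' read_rate_config(p)
#' @export
read_rate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("alpha", "beta", "gamma", "delta", "m", "kappa", "concentration")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rate_set(alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma,
           delta = cfg$delta, m = if (is.null(cfg$m)) 1L else cfg$m,
           kappa = cfg$kappa, concentration = cfg$concentration)
}

#' @rdname read_rate_config
#' @export
write_rate_config <- function(rates, path) {
  rates <- as_rate_set(rates)
  yaml::write_yaml(unclass(rates), path)
  invisible(path)
}
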