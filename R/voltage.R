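#' Eyring-Polanyi voltage-dependence parameters for the gating rates
#'
#' The gating rates follow transition-state theory:
#' `alpha(V) = k exp((V - V_half)/s)` and `beta(V) = k exp(-(V - V_half)/s)`,
#' so `alpha(V) * beta(V) = k^2` at every potential. `k` is the
#' characteristic frequency (rate at `V = V_half`, in reciprocal ms),
#' `V_half` the potential where opening and closing rates are equal (mV),
#' and `s` the slope factor (mV per e-fold change). Defaults
#' (`k = 1` ms^-1, `V_half = 0` mV, `s = 10` mV) are conventional for Kv
#' gating steepness.
#'
#' @param k Characteristic frequency factor, > 0 (1/ms).
#' @param v_half Half-activation potential (mV).
#' @param s Slope factor, > 0 (mV).
#' @return An object of class `eyring_params`.
#' @examples
#' eyring_params()
#' @export
eyring_params <- function(k = 1, v_half = 0, s = 10) {
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (length(v_half) != 1L || !is.finite(v_half)) {
    stop("`v_half` must be a single finite number", call. = FALSE)
  }
  if (length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("`s` must be a single positive number", call. = FALSE)
  }
  structure(list(k = k, v_half = v_half, s = s), class = "eyring_params")
}

#' @export
print.eyring_params <- function(x, ...) {
  cat(sprintf("<eyring_params> k = %g /ms, v_half = %g mV, s = %g mV\n",
              x$k, x$v_half, x$s))
  invisible(x)
}

#' Voltage-dependent gating rates
#'
#' `alpha_of_v()` is the opening rate `k exp((V - V_half)/s)`, increasing
#' with depolarisation; `beta_of_v()` the closing rate
#' `k exp(-(V - V_half)/s)`, decreasing with depolarisation.
#'
#' @param params An [eyring_params()].
#' @param v Membrane potential(s), mV.
#' @return Rate(s), 1/ms.
#' @examples
#' p <- eyring_params(k = 1, v_half = 0, s = 10)
#' alpha_of_v(p, 10)  # e
#' beta_of_v(p, 10)   # 1/e
#' @export
alpha_of_v <- function(params, v) {
  stopifnot(inherits(params, "eyring_params"))
  params$k * exp((v - params$v_half) / params$s)
}

#' @rdname alpha_of_v
#' @export
beta_of_v <- function(params, v) {
  stopifnot(inherits(params, "eyring_params"))
  params$k * exp(-(v - params$v_half) / params$s)
}

#' Relative peak amplitude at the dissociation-constant concentration
#'
#' Peak open probability relative to the unblocked steady state
#' `(alpha/(alpha+beta))^m`, with the gating rates at potential `v` and the
#' blocker held at its dissociation-constant concentration (`gamma =
#' delta`). When no peak exists the blocked steady state is used instead and
#' the result carries `has_peak = FALSE`.
#'
#' @param params An [eyring_params()].
#' @param delta Dissociation rate, > 0 (the association rate is set equal).
#' @param v Membrane potential, mV.
#' @param m Gate count.
#' @return A single number in `(0, 1]` with attribute `has_peak` (logical).
#' @examples
#' relative_amplitude(eyring_params(), delta = 0.05, v = 60)
#' @export
relative_amplitude <- function(params, delta, v, m = 1L) {
  if (length(delta) != 1L || !is.finite(delta) || delta <= 0) {
    stop("`delta` must be a single positive rate", call. = FALSE)
  }
  a <- alpha_of_v(params, v)
  b <- beta_of_v(params, v)
  rep_ <- analyze_peak(rate_set(a, b, delta, delta, m = m))
  denom <- no_block_steady_open(a, b, m)
  if (rep_$exists) {
    structure(rep_$o_p / denom, has_peak = TRUE)
  } else {
    structure(rep_$o_ss / denom, has_peak = FALSE)
  }
}

#' Classify a point of the dissociation-rate / voltage plane
#'
#' Three behaviours partition the `delta`-`V` plane at the
#' dissociation-constant concentration: `A1` — no open-probability peak
#' (for `m = 1`, where `alpha(V) <= delta`); `A2` — a peak whose relative
#' amplitude decreases with potential; `A3` — a peak whose relative
#' amplitude increases with potential, approaching one. Monotonicity is
#' judged by a central finite difference of [relative_amplitude()] over
#' `v +/- dv`; cells whose stencil straddles the no-peak border are
#' labelled `A1` (no peak is the verifiable statement at the boundary).
#'
#' @inheritParams relative_amplitude
#' @param dv Half-width of the finite-difference stencil, mV.
#' @return One of `"A1"`, `"A2"`, `"A3"`.
#' @examples
#' classify_point(eyring_params(), delta = 0.01, v = 80)  # "A3"
#' @export
classify_point <- function(params, delta, v, m = 1L, dv = 0.5) {
  if (dv <= 0) stop("`dv` must be positive", call. = FALSE)
  has_peak_at <- function(vv) {
    if (m == 1L) {
      alpha_of_v(params, vv) > delta
    } else {
      peak_exists_spectral(rate_set(alpha_of_v(params, vv),
                                    beta_of_v(params, vv),
                                    delta, delta, m = m))
    }
  }
  if (!has_peak_at(v)) return("A1")
  if (!has_peak_at(v - dv) || !has_peak_at(v + dv)) return("A1")
  ra_lo <- relative_amplitude(params, delta, v - dv, m)
  ra_hi <- relative_amplitude(params, delta, v + dv, m)
  slope <- as.numeric(ra_hi) - as.numeric(ra_lo)
  if (slope > 0) "A3" else "A2"
}

#' Map peak behaviour over the dissociation-rate / voltage plane
#'
#' Classifies every cell of a `delta x V` grid with [classify_point()]
#' (blocker at its dissociation-constant concentration). Classification is
#' deterministic: identical inputs give identical maps.
#'
#' @inheritParams classify_point
#' @param delta_grid Positive dissociation rates (1/ms).
#' @param v_grid Membrane potentials (mV).
#' @return A tibble of class `region_map` with columns `delta`, `v`,
#'   `label`; attributes carry the parameters used.
#' @examples
#' scan_delta_v_plane(eyring_params(),
#'                    delta_grid = c(0.01, 0.3, 3),
#'                    v_grid = seq(-20, 100, by = 40))
#' @export
scan_delta_v_plane <- function(params, delta_grid, v_grid, m = 1L, dv = 0.5) {
  if (length(delta_grid) == 0 || length(v_grid) == 0 || any(delta_grid <= 0)) {
    stop("grids must be nonempty with positive `delta_grid`", call. = FALSE)
  }
  cells <- tidyr::expand_grid(delta = delta_grid, v = v_grid)
  labels <- purrr::map2_chr(cells$delta, cells$v,
                            ~ classify_point(params, .x, .y, m = m, dv = dv))
  out <- dplyr::mutate(cells, label = factor(labels, levels = c("A1", "A2", "A3")))
  structure(out,
            class = c("region_map", class(out)),
            params = params, m = m, dv = dv,
            axes = c("delta", "v"))
}

#' Map peak existence over the closing-rate / dissociation-rate plane
#'
#' Labels every `(beta, delta)` cell `peak` or `no_peak` from the spectral
#' criterion at fixed `alpha`. The criterion does not involve `gamma`; the
#' map is computed for every association rate in `gamma_list` and an error
#' is raised if the labellings ever differ. For `m = 1` the boundary is the
#' horizontal line `delta = alpha`, independent of `beta`.
#'
#' @param alpha Opening rate, > 0.
#' @param m Gate count.
#' @param beta_grid Nonnegative closing rates.
#' @param delta_grid Positive dissociation rates.
#' @param gamma_list Association rates over which invariance is verified.
#' @return A tibble of class `region_map` with columns `beta`, `delta`,
#'   `label` (`peak` / `no_peak`).
#' @examples
#' scan_beta_delta_plane(1, 1, beta_grid = c(0, 1), delta_grid = c(0.5, 2))
#' @export
scan_beta_delta_plane <- function(alpha, m, beta_grid, delta_grid,
                                  gamma_list = c(0.1, 1, 10)) {
  check_rate(alpha, "alpha")
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (length(beta_grid) == 0 || length(delta_grid) == 0 ||
      any(beta_grid < 0) || any(delta_grid <= 0) || any(gamma_list <= 0)) {
    stop("grids must be nonempty with valid rates", call. = FALSE)
  }
  cells <- tidyr::expand_grid(beta = beta_grid, delta = delta_grid)
  per_gamma <- purrr::map(gamma_list, function(g) {
    purrr::map2_lgl(cells$beta, cells$delta,
                    ~ peak_exists_spectral(rate_set(alpha, .x, g, .y, m = m)))
  })
  ref <- per_gamma[[1]]
  same <- purrr::map_lgl(per_gamma, ~ identical(.x, ref))
  if (!all(same)) {
    stop("peak-existence map changed with gamma; this should be impossible",
         call. = FALSE)
  }
  out <- dplyr::mutate(
    cells,
    label = factor(ifelse(ref, "peak", "no_peak"), levels = c("peak", "no_peak"))
  )
  structure(out,
            class = c("region_map", class(out)),
            alpha = alpha, m = m, gamma_list = gamma_list,
            axes = c("beta", "delta"))
}
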