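#' Build the one-step transition matrix of the discretised model
#'
#' Translates the compartmental equations into the forward-finite-difference
#' update `u[t + dt] = A u[t]` over the state vector
#' `(n1, nS(age 0), ..., nS(age T_S), n2, nM)`:
#'
#' * G1 keeps `1 - (k1 + mu_g1) dt` of its cells and gains `2 b dt` from M
#'   (each division yields two daughters);
#' * `k1 dt n1` enters the first S age bin; age bins shift by one per step
#'   (times the survival factor `1 - mu_s dt`); the last bin flows wholly
#'   into G2;
#' * G2 keeps `1 - (k2 + mu_g2) dt`; M gains `k2 dt n2` and keeps
#'   `1 - (b + mu_m) dt`.
#'
#' With all death rates zero every column sums to 1 except the M column,
#' which sums to `1 + b dt`: division is the only source of growth.
#'
#' @param rates A [rate_params()] object.
#' @param dt Time step in hours. Must satisfy the stability guard: no
#'   diagonal coefficient may go negative, i.e. `dt * (k1 + mu_g1) <= 1` and
#'   likewise for `k2`, `b` and `mu_s`.
#'
#' @return An object of class `transition_matrix`: a list with the dense
#'   matrix `entries`, the `dt` it was built for, `n_age_bins`, and the
#'   `rates`.
#' @examples
#' tm <- build_transition_matrix(rate_params(0.0496, 0.0740, 0.2272, 3.2577), dt = 0.05)
#' tm$n_age_bins
#' @export
build_transition_matrix <- function(rates, dt) {
  stopifnot(is_rate_params(rates))
  if (dt <= 0) abort("`dt` must be > 0")
  diag_coefs <- c(k1 = 1 - (rates$k1 + rates$mu_g1) * dt,
                  mu_s = 1 - rates$mu_s * dt,
                  k2 = 1 - (rates$k2 + rates$mu_g2) * dt,
                  b = 1 - (rates$b + rates$mu_m) * dt)
  if (any(diag_coefs < 0)) {
    bad <- names(diag_coefs)[which.min(diag_coefs)]
    abort(sprintf(
      "stability violation: dt = %g is too large for rate `%s` (a diagonal coefficient of the transition matrix would be negative); reduce dt or the rate", dt, bad))
  }
  nb <- n_age_bins(rates$g, dt)
  n <- nb + 3L
  surv_s <- 1 - rates$mu_s * dt
  A <- matrix(0, n, n)
  A[1, 1] <- 1 - (rates$k1 + rates$mu_g1) * dt
  A[1, n] <- 2 * rates$b * dt
  A[2, 1] <- rates$k1 * dt
  if (nb > 1) {
    for (j in seq_len(nb - 1L)) A[2L + j, 1L + j] <- surv_s
  }
  A[n - 1L, nb + 1L] <- surv_s
  A[n - 1L, n - 1L] <- 1 - (rates$k2 + rates$mu_g2) * dt
  A[n, n - 1L] <- rates$k2 * dt
  A[n, n] <- 1 - (rates$b + rates$mu_m) * dt
  structure(list(entries = A, dt = dt, n_age_bins = nb, rates = rates),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d (dt = %g h, %d S age bins)\n",
              nrow(x$entries), ncol(x$entries), x$dt, x$n_age_bins))
  invisible(x)
}

#' Advance the population by one time step
#'
#' Applies the transition matrix to the state vector and advances model time
#' by `dt`. Non-negativity is preserved because all matrix entries are
#' non-negative under the stability guard.
#'
#' @param state An [age_state()].
#' @param matrix A [build_transition_matrix()] result, dimensioned
#'   consistently with `state`.
#' @return The updated `age_state`.
#' @export
step_population <- function(state, matrix) {
  stopifnot(inherits(state, "age_state"), inherits(matrix, "transition_matrix"))
  u <- state_vector(state)
  if (length(u) != nrow(matrix$entries)) {
    abort(sprintf("dimension mismatch: state has %d entries, matrix is %d x %d",
                  length(u), nrow(matrix$entries), ncol(matrix$entries)))
  }
  state_from_vector(as.numeric(matrix$entries %*% u), state$t + matrix$dt)
}
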