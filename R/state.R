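#' Age-structured population state
#'
#' Cell counts per compartment: `n1` cells in G1, a vector `ns` of cells per
#' S-phase age bin (age 0 to `T_S = 1/g` in steps of `dt`), `n2` in G2 and
#' `nm` in M, plus the current model time. The number of S bins is
#' `round(T_S / dt) + 1`, so a cell entering S reaches G2 after `T_S` hours.
#'
#' @param n1 Cells in G1 (scalar, >= 0).
#' @param ns Numeric vector of cells per S-phase age bin.
#' @param n2 Cells in G2.
#' @param nm Cells in M.
#' @param t Model time in hours (default 0).
#'
#' @return An object of class `age_state`.
#' @seealso [initial_state_g1()] for the canonical all-in-G1 start.
#' @export
age_state <- function(n1, ns, n2, nm, t = 0) {
  vals <- c(n1, ns, n2, nm)
  if (any(!is.finite(vals))) abort("state entries must be finite")
  if (any(vals < 0)) abort("state entries must be >= 0")
  structure(list(n1 = n1, ns = as.numeric(ns), n2 = n2, nm = nm, t = t),
            class = "age_state")
}

#' Number of S-phase age bins for a synthesis rate
#'
#' @param g DNA synthesis rate (1/h).
#' @param dt Time step (h).
#' @return Integer bin count `round((1/g)/dt) + 1`.
#' @export
n_age_bins <- function(g, dt) {
  if (g <= 0) abort("`g` must be > 0")
  as.integer(round(1 / (g * dt)) + 1)
}

#' All-cells-in-G1 initial state
#'
#' The canonical initial condition: the whole population synchronised in G1
#' (one cell-equivalent by default; phase fractions are scale invariant).
#'
#' @param rates A [rate_params()] object (sizes the S delay line via `g`).
#' @param dt Time step in hours.
#' @param n_total Total initial cell count (default 1).
#' @return An `age_state`.
#' @export
initial_state_g1 <- function(rates, dt, n_total = 1) {
  stopifnot(is_rate_params(rates))
  age_state(n1 = n_total, ns = numeric(n_age_bins(rates$g, dt)), n2 = 0, nm = 0, t = 0)
}

state_vector <- function(state) {
  c(state$n1, state$ns, state$n2, state$nm)
}

state_from_vector <- function(u, t) {
  n <- length(u)
  age_state(n1 = u[1], ns = u[2:(n - 2)], n2 = u[n - 1], nm = u[n], t = t)
}

#' Total cell count of a state
#'
#' @param state An `age_state`.
#' @return Sum of all compartment counts.
#' @export
total_cells <- function(state) {
  state$n1 + sum(state$ns) + state$n2 + state$nm
}

#' Phase fractions of a state
#'
#' Collapses the S-phase age bins and normalises by the total cell count.
#'
#' @param state An `age_state`.
#' @return Named numeric vector `c(g1, s, g2, m)` summing to 1.
#' @export
phase_fractions <- function(state) {
  tot <- total_cells(state)
  if (tot <= 0) abort("cannot compute phase fractions of an empty population")
  c(g1 = state$n1, s = sum(state$ns), g2 = state$n2, m = state$nm) / tot
}

#' @export
print.age_state <- function(x, ...) {
  f <- phase_fractions(x)
  cat(sprintf("<age_state> t = %.2f h, %d S age bins, total = %.4g cells\n",
              x$t, length(x$ns), total_cells(x)))
  cat(sprintf("  fractions: G1 %.3f  S %.3f  G2 %.3f  M %.4f\n",
              f["g1"], f["s"], f["g2"], f["m"]))
  invisible(x)
}
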