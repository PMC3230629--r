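#' @importFrom rlang .data
NULL

# Core response algebra on saturations s_i = tc_i/C_i and bound-target
# fractions f_i = tc_i/T.  Shared by the single-binding (sigma factor) and
# multiple-binding (translation) front ends so that the reduction law
# between the two is exact by construction.
response_core <- function(s, f) {
  denom <- 1 - sum(f * s)
  if (denom <= 0) {
    heavy <- which(f * s > 0)
    stop_degenerate(
      "degenerate state: all target is bound to fully saturated competitors",
      " (denominator = ", format(denom), "; contributing competitors: ",
      paste(heavy, collapse = ", "), ")"
    )
  }
  (1 - s) / denom
}

state_s <- function(state) {
  if (any(state$C <= 0)) {
    stop_validation("all competitor totals C must be > 0 to define saturations")
  }
  state$tc / state$C
}

state_f <- function(state) {
  T <- total_target(state)
  if (T <= 0) stop_validation("total target must be > 0")
  state$tc / T
}

#' Competitor saturation
#'
#' Fraction of competitor `i` occupied by target, `tc_i / C_i`.
#'
#' @param state A [competition_state()].
#' @param i Competitor label or index; default all competitors.
#' @return Numeric vector of saturations in `[0, 1]`.
#' @examples
#' saturation(sigma_factor_state(), "sigma70") # 545/700
#' @export
saturation <- function(state, i = NULL) {
  if (is.null(i)) {
    return(state_s(state))
  }
  idx <- vapply(i, match_competitor, integer(1), state = state)
  if (any(state$C[idx] <= 0)) {
    stop_validation("saturation undefined for competitor with C = 0")
  }
  unname(state$tc[idx] / state$C[idx])
}

#' Flux response coefficient with respect to the total target
#'
#' The relative steady-state change of the flux through competitor `i` per
#' relative change in the total target amount:
#' `R_i^T = (1 - tc_i/C_i) / (1 - sum_j (tc_j/T)(tc_j/C_j))`.
#' The numerator is the free fraction of competitor `i`; the denominator is
#' one minus the saturation-weighted fraction of bound target.  Values above
#' 1 are ultrasensitive responses.
#'
#' @inheritParams saturation
#' @return Numeric vector of non-negative coefficients.
#' @examples
#' response_to_target(sigma_factor_state(), "sigma28") # about 2.3
#' @export
response_to_target <- function(state, i = NULL) {
  s <- state_s(state)
  f <- state_f(state)
  R <- response_core(s, f)
  if (is.null(i)) return(R)
  idx <- vapply(i, match_competitor, integer(1), state = state)
  unname(R[idx])
}

#' Flux response coefficient with respect to the competitor's own total
#'
#' `R_i^{C_i} = 1 - R_i^T * tc_i/T`; always in `[0, 1]`.
#'
#' @inheritParams saturation
#' @return Numeric vector of coefficients in `[0, 1]`.
#' @export
response_to_own_total <- function(state, i = NULL) {
  R_T <- response_to_target(state)
  f <- state_f(state)
  R <- 1 - R_T * f
  if (is.null(i)) return(R)
  idx <- vapply(i, match_competitor, integer(1), state = state)
  unname(R[idx])
}

#' Cross response: flux of one competitor versus another's total
#'
#' `R_i^{C_k} = -R_i^T * tc_k/T` for `k != i`; never positive, and never
#' larger in magnitude than the response to the target itself.
#'
#' @inheritParams saturation
#' @param i Competitor whose flux responds.
#' @param k Competitor whose total amount is perturbed; must differ from `i`.
#' @return A single non-positive coefficient.
#' @export
response_to_competitor_total <- function(state, i, k) {
  ii <- match_competitor(state, i, "i")
  kk <- match_competitor(state, k, "k")
  if (ii == kk) {
    stop_validation("i and k refer to the same competitor; ",
                    "use response_to_own_total() for the self response")
  }
  R_T <- response_to_target(state)[ii]
  f <- state_f(state)
  unname(-R_T * f[kk])
}

#' Full response matrix
#'
#' Assembles, for every competitor flux, the response coefficients with
#' respect to the total target and every competitor total.
#'
#' @inheritParams saturation
#' @return A tibble of class `response_matrix`: one row per flux, columns
#'   `flux`, `R_T`, then `R_<label>` for each competitor total.  Attributes
#'   `free_target`, `total_target` and `saturations` carry the state summary.
#' @examples
#' response_matrix(sigma_factor_state())
#' @export
response_matrix <- function(state) {
  s <- state_s(state)
  f <- state_f(state)
  R_T <- response_core(s, f)
  n <- nrow(state)
  # cross terms -R_i^T f_k everywhere, then overwrite the diagonal
  mat <- -outer(R_T, f)
  diag(mat) <- 1 - R_T * f
  colnames(mat) <- paste0("R_", state$label)
  out <- tibble::tibble(flux = state$label, R_T = R_T)
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  structure(
    out,
    total_target = total_target(state),
    free_target = free_target(state),
    saturations = stats::setNames(s, state$label),
    class = c("response_matrix", class(tibble::tibble()))
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> free target t = ", format(attr(x, "free_target")),
      " of T = ", format(attr(x, "total_target")), "\n", sep = "")
  NextMethod()
}

#' Saturation fraction ratio
#'
#' Relative saturation of competitor `j` with respect to competitor `i`,
#' `rho_ij = (tc_j/C_j) / (tc_i/C_i)`.  Governs the free-target threshold
#' for ultrasensitivity.
#'
#' @inheritParams saturation
#' @param i,j Competitor labels or indices.
#' @return A single positive ratio; 1 when `i == j`.
#' @export
saturation_ratio <- function(state, i, j) {
  ii <- match_competitor(state, i, "i")
  jj <- match_competitor(state, j, "j")
  s <- state_s(state)
  if (s[ii] == 0) {
    stop_degenerate("saturation ratio undefined: competitor ",
                    state$label[ii], " holds no target")
  }
  unname(s[jj] / s[ii])
}

#' Ultrasensitivity threshold on the free target
#'
#' The flux through competitor `i` responds ultrasensitively to the total
#' target (coefficient above 1) exactly when the free target `t` lies below
#' `sum_{j != i} tc_j (rho_ij - 1)`.  The predicate is evaluated in the
#' division-free form `sum_j tc_j s_j > s_i T`, so competitors that hold no
#' target are handled without special-casing; for those the threshold value
#' itself is reported as `NA`.
#'
#' @inheritParams saturation
#' @return A tibble with one row per requested competitor: `label`,
#'   `threshold` (free-target units), `free_target`, `ultrasensitive`.
#' @examples
#' ultrasensitivity_threshold(sigma_factor_state())
#' @export
ultrasensitivity_threshold <- function(state, i = NULL) {
  s <- state_s(state)
  T <- total_target(state)
  if (T <= 0) stop_validation("total target must be > 0")
  t_free <- free_target(state)
  idx <- if (is.null(i)) seq_len(nrow(state)) else
    vapply(i, match_competitor, integer(1), state = state)
  rows <- lapply(idx, function(ii) {
    ultra <- sum(state$tc * s) > s[ii] * T
    thr <- if (s[ii] > 0) {
      sum(state$tc[-ii] * (s[-ii] / s[ii] - 1))
    } else {
      NA_real_
    }
    tibble::tibble(label = state$label[ii], threshold = thr,
                   free_target = t_free, ultrasensitive = ultra)
  })
  dplyr::bind_rows(rows)
}

#' Ratio of two target-response coefficients
#'
#' `R_i^T / R_j^T` equals the ratio of the free competitor fractions,
#' `(1 - tc_i/C_i) / (1 - tc_j/C_j)`: the denominators of the response
#' formula cancel.  The less saturated competitor always responds more.
#'
#' @inheritParams saturation_ratio
#' @return A single ratio.
#' @export
target_response_ratio <- function(state, i, j) {
  ii <- match_competitor(state, i, "i")
  jj <- match_competitor(state, j, "j")
  s <- state_s(state)
  if (s[jj] >= 1) {
    stop_degenerate("competitor ", state$label[jj],
                    " is fully saturated; ratio diverges")
  }
  unname((1 - s[ii]) / (1 - s[jj]))
}

#' Relative competitor strength
#'
#' The ratio of cross responses of any third flux to competitors `k` and
#' `l` is `tc_k / tc_l`: competitor strength is set by the absolute amount
#' of target bound, not by saturation.
#'
#' @inheritParams saturation
#' @param k,l Competitor labels or indices.
#' @return A single ratio.
#' @export
competitor_strength_ratio <- function(state, k, l) {
  kk <- match_competitor(state, k, "k")
  ll <- match_competitor(state, l, "l")
  if (state$tc[ll] == 0) {
    stop_degenerate("competitor ", state$label[ll],
                    " holds no target; strength ratio undefined")
  }
  unname(state$tc[kk] / state$tc[ll])
}
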