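#' Parameters of the n-competitor mass-action binding model
#'
#' The validation model behind the closed-form theory: each competitor `i`
#' reversibly binds free target (`k_f`, `k_r`) and the complex is consumed
#' and recycled by a production step with apparent first-order constant
#' `k_cat` (substrate subsumed).  Mass balance of the complexes
#' `d(tc_i)/dt = k_f_i * t * c_i - (k_r_i + k_cat_i) * tc_i`, with free
#' amounts substituted through the conservation relations
#' `t = T - sum(tc)` and `c_i = C_i - tc_i`.  Steady-state fluxes are
#' `J_i = k_cat_i * tc_i`.
#'
#' @param k_f Binding rate constants (amount^-1 time^-1), length n.
#' @param k_r Unbinding rate constants (time^-1), length n.
#' @param k_cat Apparent production constants (time^-1), length n.
#' @param C Total competitor amounts, length n.
#' @param total_target Total target amount `T`.
#' @param labels Competitor labels (default `"comp1"`, ...).
#' @return A tibble of class `mass_action_params` with attribute
#'   `total_target`.
#' @examples
#' sigma_network_params()
#' @export
mass_action_params <- function(k_f, k_r, k_cat, C, total_target,
                               labels = NULL) {
  n <- length(C)
  k_cat <- rep_len(k_cat, n)
  k_f <- rep_len(k_f, n)
  k_r <- rep_len(k_r, n)
  if (is.null(labels)) labels <- paste0("comp", seq_len(n))
  if (any(c(k_f, k_r, k_cat) <= 0)) {
    stop_validation("all rate constants must be > 0")
  }
  if (any(C < 0) || total_target < 0) {
    stop_validation("totals must be non-negative")
  }
  structure(
    tibble::tibble(label = as.character(labels), k_f = k_f, k_r = k_r,
                   k_cat = k_cat, C = C),
    total_target = total_target,
    class = c("mass_action_params", class(tibble::tibble()))
  )
}

#' Three-competitor parameter set mimicking sigma-factor competition
#'
#' Rate constants chosen so that at `T = 700` molecules/cell the model's
#' steady state reproduces the bound/total pattern of the sigma-factor
#' example: `k_f = 24, 8, 11` (molecules^-1 min^-1), `k_r = 3, 6, 30`
#' (min^-1), `k_cat = 5` (min^-1), totals 700/370/110 molecules/cell.
#'
#' @param total_target Total target amount (default 700 molecules/cell).
#' @return A [mass_action_params()] object.
#' @export
sigma_network_params <- function(total_target = 700) {
  mass_action_params(
    k_f = c(24, 8, 11), k_r = c(3, 6, 30), k_cat = c(5, 5, 5),
    C = c(700, 370, 110), total_target = total_target
  )
}

#' Right-hand side of the mass-action complex ODEs
#'
#' @param params A [mass_action_params()].
#' @param tc Current complex amounts, length n, within conservation bounds.
#' @return Time derivatives `d(tc)/dt`, length n.
#' @export
mass_action_rhs <- function(params, tc) {
  t_free <- attr(params, "total_target") - sum(tc)
  params$k_f * t_free * (params$C - tc) - (params$k_r + params$k_cat) * tc
}

#' Steady state of the mass-action model
#'
#' The closed-form steady state satisfies
#' `tc_i = K_i t C_i / (1 + K_i t)` with `K_i = k_f_i / (k_r_i + k_cat_i)`,
#' and the free target `t` is the unique root of the strictly increasing
#' constraint `t + sum_i tc_i(t) = T` on `[0, T]` (`method = "analytic"`,
#' the default, solved by bisection-safe root finding to near machine
#' precision).  `method = "ode"` instead integrates the complex ODEs from
#' empty pools with a stiff solver until the derivative norm is below
#' `ss_tol`, as an independent numerical route.
#'
#' @param params A [mass_action_params()].
#' @param method `"analytic"` or `"ode"`.
#' @param ss_tol Relative derivative norm defining steady state for the ODE
#'   route.
#' @param max_time Integration horizon (time units of the rate constants)
#'   before non-convergence is reported.
#' @return A [competition_state()] with an extra `flux` column
#'   (`J_i = k_cat_i tc_i`) and attribute `method`.
#' @export
mass_action_steady_state <- function(params, method = c("analytic", "ode"),
                                     ss_tol = 1e-10, max_time = 1e7) {
  method <- match.arg(method)
  T <- attr(params, "total_target")
  tc <- if (method == "analytic") {
    steady_tc_analytic(params)
  } else {
    steady_tc_ode(params, ss_tol = ss_tol, max_time = max_time)
  }
  out <- competition_state(
    tibble::tibble(label = params$label, C = params$C, tc = tc),
    total_target = T
  )
  out$flux <- params$k_cat * tc
  attr(out, "method") <- method
  out
}

steady_tc_analytic <- function(params) {
  T <- attr(params, "total_target")
  if (T == 0) return(rep(0, nrow(params)))
  K <- params$k_f / (params$k_r + params$k_cat)
  g <- function(t) t + sum(K * t * params$C / (1 + K * t)) - T
  # g is strictly increasing, g(0) = -T <= 0, g(T) >= 0: bracketed root
  t_free <- stats::uniroot(g, c(0, T), tol = .Machine$double.eps * max(T, 1),
                           maxiter = 200)$root
  K * t_free * params$C / (1 + K * t_free)
}

steady_tc_ode <- function(params, ss_tol = 1e-10, max_time = 1e7) {
  T <- attr(params, "total_target")
  n <- nrow(params)
  if (T == 0) return(rep(0, n))
  rhs <- function(time, y, p) list(mass_action_rhs(params, y))
  # geometric checkpoints: fast binding transient, then slow exchange
  t0 <- 1 / max(params$k_f * T + params$k_r + params$k_cat)
  times <- c(0, t0 * 2^(0:ceiling(log2(max_time / t0))))
  times <- times[times <= max_time]
  sol <- deSolve::lsoda(y = rep(0, n), times = times, func = rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-12 * max(T, 1))
  for (r in seq_len(nrow(sol))[-1]) {
    tc <- sol[r, -1]
    scale <- pmax(abs(tc), 1e-30)
    if (max(abs(mass_action_rhs(params, tc)) /
            ((params$k_r + params$k_cat) * scale)) <= ss_tol) {
      return(unname(tc))
    }
  }
  stop_convergence("mass-action integration did not reach steady state",
                   last_state = unname(sol[nrow(sol), -1]))
}

#' Finite-perturbation response coefficient from the mass-action model
#'
#' Numerical analogue of the closed-form coefficients: the steady-state
#' flux is computed at a reference parameter value `p` and at `p (1 + delta)`
#' and the coefficient approximated as `[ln J' - ln J] / ln(1 + delta)`
#' (forward), or symmetrically about `p` (central).  Converges to the
#' analytical coefficient as `delta -> 0`.
#'
#' @param params A [mass_action_params()].
#' @param parameter `"T"` for the total target, or a competitor label/index
#'   for that competitor's total amount.
#' @param delta Fractional perturbation (default 0.01, i.e. 1 percent).
#' @param scheme `"forward"` or `"central"` log-difference.
#' @param method Steady-state engine passed to
#'   [mass_action_steady_state()].
#' @return A tibble with columns `flux`, `parameter`, `coefficient`.
#' @export
mass_action_numerical_response <- function(params, parameter, delta = 0.01,
                                           scheme = c("forward", "central"),
                                           method = "analytic") {
  scheme <- match.arg(scheme)
  if (delta <= 0) stop_validation("`delta` must be > 0")
  flux_at <- function(factor) {
    mass_action_steady_state(perturb_params(params, parameter, factor),
                             method = method)$flux
  }
  J_hi <- flux_at(1 + delta)
  if (scheme == "forward") {
    J_lo <- flux_at(1)
    width <- log(1 + delta)
  } else {
    J_lo <- flux_at(1 / (1 + delta))
    width <- 2 * log(1 + delta)
  }
  if (any(J_lo <= 0) || any(J_hi <= 0)) {
    stop_degenerate("zero flux at the reference state; response undefined")
  }
  tibble::tibble(
    flux = params$label,
    parameter = parameter_label(params, parameter),
    coefficient = (log(J_hi) - log(J_lo)) / width
  )
}

perturb_params <- function(params, parameter, factor) {
  T <- attr(params, "total_target")
  if (identical(parameter, "T")) {
    return(mass_action_params(params$k_f, params$k_r, params$k_cat,
                              params$C, T * factor, params$label))
  }
  idx <- match_competitor(params, parameter, "parameter")
  C <- params$C
  C[idx] <- C[idx] * factor
  mass_action_params(params$k_f, params$k_r, params$k_cat, C, T,
                     params$label)
}

parameter_label <- function(params, parameter) {
  if (identical(parameter, "T")) "T" else
    params$label[match_competitor(params, parameter, "parameter")]
}

#' Scan the mass-action model over total target levels
#'
#' For each level of the total target the steady state is solved, the
#' closed-form coefficients are evaluated on it, and finite-perturbation
#' coefficients are measured from the simulator -- the numerical/analytical
#' comparison as a tidy table.
#'
#' @param params A [mass_action_params()]; its `total_target` is replaced by
#'   each grid value in turn.
#' @param T_grid Positive total-target levels.
#' @param delta Fractional perturbation for the numerical route.
#' @param scheme Log-difference scheme, see
#'   [mass_action_numerical_response()].
#' @return A tibble of class `target_scan`: one row per (T, competitor) with
#'   saturation, free target, flux, analytic and numerical response to `T`,
#'   numerical response to the first competitor total, and the numerical
#'   response of the free target amount to `T`.
#' @export
scan_target <- function(params, T_grid, delta = 0.01,
                        scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  if (any(T_grid <= 0)) stop_validation("T grid values must be > 0")
  rows <- purrr::map(T_grid, function(Tval) {
    p <- perturb_params(params, "T", Tval / attr(params, "total_target"))
    st <- mass_action_steady_state(p)
    num_T <- mass_action_numerical_response(p, "T", delta, scheme)
    num_C1 <- mass_action_numerical_response(p, params$label[1], delta,
                                             scheme)
    st_hi <- mass_action_steady_state(perturb_params(p, "T", 1 + delta))
    t_ref <- free_target(st)
    R_free <- if (t_ref > 0) {
      (log(free_target(st_hi)) - log(t_ref)) / log(1 + delta)
    } else {
      NA_real_
    }
    tibble::tibble(
      total_target = Tval,
      flux = p$label,
      saturation = saturation(st),
      free_target = t_ref,
      flux_value = st$flux,
      R_T_analytic = response_to_target(st),
      R_T_numeric = num_T$coefficient,
      R_C1_analytic = purrr::map_dbl(seq_len(nrow(p)), function(i) {
        if (i == 1) response_to_own_total(st, 1) else
          response_to_competitor_total(st, i, 1)
      }),
      R_C1_numeric = num_C1$coefficient,
      free_target_response = R_free
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("target_scan", class(tibble::tibble())))
}
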