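#' Draw a random valid competition state
#'
#' Used for property checks: competitor totals are log-normal, saturations
#' uniform on `[0, s_max]`, and the free target a uniform fraction of the
#' bound amount, which guarantees every conservation invariant by
#' construction.
#'
#' @param n Number of competitors.
#' @param s_max Upper bound on the drawn saturations.
#' @return A [competition_state()].
#' @export
random_competition_state <- function(n = 3, s_max = 0.95) {
  C <- stats::rlnorm(n, log(100), 1)
  s <- stats::runif(n, 0, s_max)
  tc <- s * C
  t_free <- stats::runif(1, 0, 1) * sum(tc)
  competition_state(
    tibble::tibble(label = paste0("c", seq_len(n)), C = C, tc = tc),
    total_target = sum(tc) + t_free
  )
}

#' Draw a random mass-action parameter set
#'
#' Rate constants span several orders of magnitude (log-uniform), totals
#' are log-normal; exercises the steady-state solvers over stiff regimes.
#'
#' @param n Number of competitors.
#' @return A [mass_action_params()].
#' @export
random_mass_action_params <- function(n = 3) {
  lu <- function(lo, hi, k = n) exp(stats::runif(k, log(lo), log(hi)))
  mass_action_params(
    k_f = lu(1e-3, 10), k_r = lu(0.1, 100), k_cat = lu(0.1, 100),
    C = stats::rlnorm(n, log(300), 0.7),
    total_target = stats::rlnorm(1, log(300), 0.7)
  )
}

#' Run the oracle-equivalence and identity suites end to end
#'
#' Re-derives, on freshly randomized inputs, the core guarantees of the
#' framework: the row identity of the response matrix, the equivalence of
#' the ultrasensitivity threshold with a target response above 1, the ratio
#' identities, and the agreement of the closed-form coefficients with
#' finite-perturbation coefficients measured on the mass-action simulator.
#'
#' @param seed Integer seed.
#' @param n_cases Randomized states/parameter sets per check.
#' @param identity_tol Tolerance for the exact algebraic identities.
#' @param oracle_tol Relative tolerance for the small-perturbation
#'   (`delta = 1e-4`) oracle comparison.
#' @return A tibble with one row per check: `check`, `n`, `max_error`,
#'   `pass`.
#' @export
run_validation_suite <- function(seed = 1L, n_cases = 50,
                                 identity_tol = 1e-12, oracle_tol = 1e-3) {
  withr::with_seed(seed, {
    row_err <- ultra_ok <- ratio_err <- numeric(n_cases)
    for (i in seq_len(n_cases)) {
      st <- random_competition_state(n = sample(2:6, 1))
      rm <- response_matrix(st)
      coefs <- as.matrix(rm[, -1])
      lhs <- rowSums(coefs)
      rhs <- 1 + rm$R_T * free_target(st) / total_target(st)
      row_err[i] <- max(abs(lhs - rhs) / pmax(abs(rhs), 1))
      ultra <- ultrasensitivity_threshold(st)
      ultra_ok[i] <- all(ultra$ultrasensitive == (rm$R_T > 1))
      r5 <- target_response_ratio(st, 1, 2) -
        response_to_target(st, 1) / response_to_target(st, 2)
      r6 <- if (st$tc[2] > 0 && nrow(st) >= 3) {
        competitor_strength_ratio(st, 1, 2) -
          response_to_competitor_total(st, 3, 1) /
          response_to_competitor_total(st, 3, 2)
      } else 0
      ratio_err[i] <- max(abs(c(r5, r6)))
    }
    oracle_err <- numeric(n_cases)
    for (i in seq_len(n_cases)) {
      pars <- random_mass_action_params(3)
      st <- mass_action_steady_state(pars)
      if (any(st$flux <= 0)) {
        oracle_err[i] <- 0
        next
      }
      num <- mass_action_numerical_response(pars, "T", delta = 1e-4,
                                            scheme = "central")
      ana <- response_to_target(st)
      oracle_err[i] <- max(abs(num$coefficient - ana) / pmax(abs(ana), 1e-6))
    }
  })
  tibble::tibble(
    check = c("row identity", "ultrasensitivity predicate",
              "ratio identities", "mass-action oracle (delta 1e-4)"),
    n = n_cases,
    max_error = c(max(row_err), as.numeric(!all(ultra_ok == 1)),
                  max(ratio_err), max(oracle_err)),
    pass = c(max(row_err) <= identity_tol, all(ultra_ok == 1),
             max(ratio_err) <= identity_tol, max(oracle_err) <= oracle_tol)
  )
}
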