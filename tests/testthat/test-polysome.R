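coarse_params <- function(total_ribosome = 10, n_codons = 60) {
  polysome_params(
    n_codons = c(n_codons, n_codons), k_init = c(0.2, 5),
    k_elong = c(50, 20), k_term = c(50, 20),
    abundance = c(0.2, 2), total_ribosome = total_ribosome, footprint = 12
  )
}

test_that("initiation, elongation and termination rates follow the kinetic scheme", {
  pars <- coarse_params(total_ribosome = 10)
  n <- 60

  empty <- polysome_state(pars, list(numeric(n), numeric(n)))
  expect_equal(initiation_rate(empty, 1), 0.2 * 10)
  expect_equal(termination_rate(empty, 1), 0)

  blocked <- polysome_state(pars, list(c(1, numeric(n - 1)), numeric(n)))
  expect_equal(initiation_rate(blocked, 1), 0)

  # isolated ribosome: no downstream occupancy within a footprint
  p <- numeric(n); p[20] <- 0.3
  iso <- polysome_state(pars, list(p, numeric(n)))
  expect_equal(elongation_rate(iso, 1, 20), 50 * 0.3)

  # fully blocked step: the next footprint ends exactly where a front sits
  q <- numeric(n); q[20] <- 0.2; q[20 + 12] <- 1
  jam <- polysome_state(pars, list(q, numeric(n)))
  expect_equal(elongation_rate(jam, 1, 20), 0)

  expect_error(elongation_rate(iso, 1, n),
               class = "fluxcompete_validation_error")
})

test_that("state validation rejects exclusion violations and over-bound pools", {
  pars <- coarse_params(total_ribosome = 10)
  bad <- numeric(60); bad[1] <- 0.7; bad[5] <- 0.7
  expect_error(polysome_state(pars, list(bad, numeric(60))),
               class = "fluxcompete_validation_error")
  over <- rep(0.06, 60)  # within exclusion, but 2 uM * 3.6 ribosomes > pool
  expect_error(polysome_state(coarse_params(total_ribosome = 1),
                              list(numeric(60), over)),
               class = "fluxcompete_validation_error")
})

test_that("recursion and ODE engines find the same steady state", {
  pars <- coarse_params(total_ribosome = 10)
  a <- simulate_polysome(pars)
  b <- simulate_polysome(pars, engine = "ode")
  expect_lt(max(abs(a$P - b$P) / a$P), 1e-6)
  expect_lt(max(abs(a$flux - b$flux) / a$flux), 1e-6)
})

test_that("steady states balance fluxes, conserve ribosomes and stay feasible", {
  for (Tval in c(0.5, 10, 60)) {
    st <- simulate_polysome(coarse_params(total_ribosome = Tval))
    for (sp in 1:2) {
      init <- initiation_rate(st, sp)
      term <- termination_rate(st, sp)
      expect_lt(abs(init - term) / max(term, 1e-12), 1e-6)
      # per-species synthesis flux is C * termination rate
      expect_equal(st$flux[[sp]], st$params$abundance[sp] * term,
                   tolerance = 1e-12)
      win <- max(vapply(seq_along(st$profiles[[sp]]), function(j) {
        sum(st$profiles[[sp]][j:min(j + 11, length(st$profiles[[sp]]))])
      }, numeric(1)))
      expect_lte(win, 1 + 1e-9)
    }
    bound <- sum(st$params$abundance * st$P)
    expect_lt(abs(Tval - st$free_ribosome - bound), 1e-9 * Tval)
  }
})

test_that("limiting regimes: starvation, packing bound, initiation-limited flux", {
  tiny <- simulate_polysome(coarse_params(total_ribosome = 1e-6))
  expect_true(all(tiny$flux < 1e-5))

  glut <- simulate_polysome(coarse_params(total_ribosome = 1e4))
  expect_true(all(glut$P < 60 / 12))          # below the packing limit
  expect_true(all(glut$P > 0.5 * 60 / 12))    # but close to capacity

  # single weakly initiating mRNA: flux ~ k_init * r_free * C
  weak <- polysome_params(n_codons = 60, k_init = 1e-4, k_elong = 50,
                          k_term = 50, abundance = 0.5, total_ribosome = 10,
                          footprint = 12)
  st <- simulate_polysome(weak)
  expect_equal(st$flux[[1]], 1e-4 * st$free_ribosome * 0.5, tolerance = 1e-3)
})

test_that("symmetric species receive identical response coefficients", {
  pars <- polysome_params(n_codons = c(60, 60), k_init = c(1, 1),
                          k_elong = c(30, 30), k_term = c(30, 30),
                          abundance = c(1, 1), total_ribosome = 8,
                          footprint = 12)
  num <- polysome_numerical_response(pars, "T", delta = 0.01)
  expect_equal(num$coefficient[1], num$coefficient[2], tolerance = 1e-8)
  cross <- polysome_numerical_response(pars, 1, delta = 0.01)
  cross2 <- polysome_numerical_response(pars, 2, delta = 0.01)
  expect_equal(cross$coefficient[2], cross2$coefficient[1],
               tolerance = 1e-8)
})

test_that("closed-form translation coefficients track the simulator when dilute", {
  pars <- coarse_params(total_ribosome = 2)
  sc <- polysome_scan(pars, T_grid = c(0.5, 2), delta = 0.01)
  expect_true(all(sc$saturation < 0.3))
  expect_lt(max(abs(sc$formula - sc$numeric)), 0.05)
})

test_that("non-convergence within the horizon is reported with the last state", {
  pars <- coarse_params(total_ribosome = 10)
  err <- tryCatch(
    simulate_polysome(pars, engine = "ode", max_time = 1e-3),
    fluxcompete_convergence_error = function(e) e
  )
  expect_s3_class(err, "fluxcompete_convergence_error")
  expect_length(err$last_state, 2)
})
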