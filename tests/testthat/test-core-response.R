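test_that("saturation is the bound fraction of a competitor", {
  st <- sigma_state()
  expect_equal(saturation(st, "sigma70"), 545 / 700)
  zero <- competition_state(
    tibble::tibble(label = c("a", "b"), C = c(5, 4), tc = c(0, 4)), 10
  )
  expect_equal(saturation(zero, "a"), 0)
  expect_equal(saturation(zero, "b"), 1)
  bad <- competition_state(
    tibble::tibble(label = c("a", "b"), C = c(0, 4), tc = c(0, 4)), 10
  )
  expect_error(saturation(bad, "a"), class = "fluxcompete_validation_error")
})

test_that("sigma-factor state reproduces the published coefficients at 2 s.f.", {
  rm <- response_matrix(sigma_state())
  got <- signif(as.matrix(rm[, -1]), 2)
  dimnames(got) <- dimnames(SIGMA_TABLE)
  expect_equal(got, SIGMA_TABLE)
})

test_that("unbound and degenerate corner cases behave as the theory says", {
  # no target bound anywhere: first-order response in everything
  empty <- competition_state(
    tibble::tibble(label = c("a", "b"), C = c(5, 9), tc = c(0, 0)), 10
  )
  expect_equal(response_to_target(empty), c(1, 1))
  expect_equal(response_to_own_total(empty), c(1, 1))
  expect_equal(response_to_competitor_total(empty, 1, 2), 0)

  # single unbound competitor: matrix [[1, 1]]
  one <- competition_state(tibble::tibble(label = "a", C = 3, tc = 0), 10)
  m <- response_matrix(one)
  expect_equal(unname(as.matrix(m[, -1])), matrix(c(1, 1), 1))

  # all target exhausted by a single saturated competitor: self-response 0
  full <- competition_state(tibble::tibble(label = "a", C = 10, tc = 5), 5)
  expect_equal(response_to_target(full, 1), (1 - 0.5) / (1 - 0.5))
  expect_equal(response_to_own_total(full, 1), 1 - 1 * (5 / 5) * 0.5 / 0.5,
               tolerance = 1e-12)

  # denominator collapse: everything bound to fully saturated competitors
  degen <- competition_state(tibble::tibble(label = "a", C = 5, tc = 5), 5)
  expect_error(response_to_target(degen),
               class = "fluxcompete_degenerate_error")

  # self cross-response is a misuse
  expect_error(response_to_competitor_total(empty, 1, 1),
               class = "fluxcompete_validation_error")
})

test_that("ratio relations evaluate to the worked sigma-factor numbers", {
  st <- sigma_state()
  expect_equal(saturation_ratio(st, "sigma28", "sigma70"),
               (545 / 700) / (100 / 370))
  expect_equal(signif(saturation_ratio(st, "sigma28", "sigma70"), 3), 2.88)
  expect_equal(saturation_ratio(st, "sigma70", "sigma70"), 1)

  # sensitivity of sigma54- vs sigma70-directed flux to a third competitor
  expect_equal(target_response_ratio(st, "sigma54", "sigma70"),
               (1 - 55 / 110) / (1 - 545 / 700))
  expect_equal(signif(target_response_ratio(st, "sigma54", "sigma70"), 2),
               2.3)
  expect_equal(target_response_ratio(st, "sigma54", "sigma54"), 1)

  # competitor strength from absolute bound amounts: 100 vs 55
  expect_equal(competitor_strength_ratio(st, "sigma28", "sigma54"),
               100 / 55)
  expect_equal(competitor_strength_ratio(st, "sigma54", "sigma54"), 1)
})

test_that("ultrasensitivity threshold matches the published consistency case", {
  st <- sigma_state()
  u <- ultrasensitivity_threshold(st)
  expect_equal(u$free_target, rep(0, 3))
  # free target 0 lies below the positive thresholds of the two less
  # saturated factors, matching their responses above 1
  expect_equal(u$ultrasensitive, c(FALSE, TRUE, TRUE))
  expect_equal(u$ultrasensitive, response_to_target(st) > 1)

  # equal saturations: thresholds 0, never ultrasensitive
  eq <- competition_state(
    tibble::tibble(label = c("a", "b"), C = c(10, 20), tc = c(5, 10)), 30
  )
  expect_equal(ultrasensitivity_threshold(eq)$threshold, c(0, 0))
  expect_false(any(ultrasensitivity_threshold(eq)$ultrasensitive))
})

test_that("sign, range, ordering and identity properties hold on random states", {
  set.seed(42)
  for (rep in 1:200) {
    st <- random_competition_state(n = sample(2:6, 1))
    rm <- response_matrix(st)
    R_T <- rm$R_T
    coefs <- as.matrix(rm[, -1])
    own <- diag(coefs[, -1, drop = FALSE])
    cross <- coefs[, -1, drop = FALSE]
    diag(cross) <- 0

    expect_true(all(R_T >= 0))
    expect_true(all(own >= 0 & own <= 1))
    expect_true(all(cross <= 1e-15))
    expect_true(all(abs(cross) <= R_T + 1e-12))

    # row identity R_T + sum(R_C) = 1 + R_T * t/T
    rhs <- 1 + R_T * free_target(st) / total_target(st)
    expect_true(max(abs(rowSums(coefs) - rhs) / abs(rhs)) < 1e-12)

    # less saturated competitor responds more to the target
    s <- saturation(st)
    expect_equal(order(s), order(-R_T))

    # predicate equivalence
    expect_equal(ultrasensitivity_threshold(st)$ultrasensitive, R_T > 1)

    # ratio identities against direct evaluation
    i <- 1; j <- 2
    expect_equal(target_response_ratio(st, i, j),
                 response_to_target(st, i) / response_to_target(st, j),
                 tolerance = 1e-12)
    if (nrow(st) >= 3 && st$tc[2] > 0) {
      expect_equal(competitor_strength_ratio(st, 1, 2),
                   response_to_competitor_total(st, 3, 1) /
                     response_to_competitor_total(st, 3, 2),
                   tolerance = 1e-12)
      expect_equal(response_to_competitor_total(st, 1, 3) /
                     response_to_competitor_total(st, 2, 3),
                   response_to_target(st, 1) / response_to_target(st, 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold form handles zero-saturation competitors without division", {
  st <- competition_state(
    tibble::tibble(label = c("a", "b"), C = c(5, 10), tc = c(0, 8)), 9
  )
  u <- ultrasensitivity_threshold(st)
  expect_true(is.na(u$threshold[1]))
  expect_equal(u$ultrasensitive, response_to_target(st) > 1)
  expect_true(u$ultrasensitive[1])
})
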