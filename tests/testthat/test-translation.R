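test_that("effective saturation and pool fraction are the documented ratios", {
  st <- translation_state(
    tibble::tibble(id = c("a", "b"), abundance = c(2, 1),
                   orf_codons = c(240, 240), P = c(10, 0)),
    total_ribosome = 79, footprint = 12
  )
  expect_equal(effective_saturation(st, "a"), 10 * 12 / 240)
  expect_equal(effective_saturation(st, "b"), 0)
  expect_equal(ribosome_fraction(st, "a"), 2 * 10 / 79)
  expect_equal(ribosome_fraction(st, "b"), 0)
  expect_lte(sum(ribosome_fraction(st)), 1)
})

test_that("construction enforces packing, pool and length invariants", {
  expect_error(
    translation_state(tibble::tibble(id = "a", abundance = 1,
                                     orf_codons = 6, P = 0.1),
                      footprint = 12),
    class = "fluxcompete_validation_error"
  )
  expect_error(
    translation_state(tibble::tibble(id = "a", abundance = 1,
                                     orf_codons = 120, P = 11),
                      footprint = 12),
    class = "fluxcompete_validation_error"
  )
  expect_error(
    translation_state(tibble::tibble(id = "a", abundance = 10,
                                     orf_codons = 120, P = 9),
                      total_ribosome = 79, footprint = 12),
    class = "fluxcompete_validation_error"
  )
  expect_error(
    translation_state(tibble::tibble(id = "a", abundance = 1,
                                     orf_codons = 120),
                      total_ribosome = 79),
    class = "fluxcompete_validation_error"
  )
})

test_that("single-site transcripts reduce exactly to the single-binding theory", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    L <- sample(c(1, 12), 1)
    s <- runif(n, 0, 0.9)
    C <- rlnorm(n, log(1), 0.5)
    ts <- translation_state(
      tibble::tibble(id = paste0("g", seq_len(n)), abundance = C,
                     orf_codons = rep(L, n), P = s),
      total_ribosome = sum(C * s) * runif(1, 1.05, 2), footprint = L
    )
    cs <- as_competition_state(ts)
    expect_identical(cs$tc, ts$abundance * ts$P)
    expect_equal(response_to_ribosome(ts), response_to_target(cs))
    expect_equal(response_to_own_mrna(ts), response_to_own_total(cs))
    expect_equal(response_to_other_mrna(ts, 1, 2),
                 response_to_competitor_total(cs, 1, 2))
  }
})

test_that("density conversion applies the physical cap and unit conventions", {
  tbl <- tibble::tibble(id = c("a", "b", "c"), abundance = 1,
                        orf_codons = c(120, 240, 300),
                        density = c(8.4, 0, 2))
  expect_warning(out <- ribosomes_from_density(tbl, footprint = 12),
                 "clamped")
  expect_equal(attr(out, "n_clamped"), 1)
  expect_equal(out$density[1], 100 / 12 - 0.005)
  expect_equal(out$P, out$density * tbl$orf_codons / 100)
  expect_equal(out$P[2], 0)

  # below the cap the density -> P -> density round trip is the identity
  expect_equal(out$P[3] * 100 / tbl$orf_codons[3], 2)

  # per-1000-nt densities: 1 per 1000 nt = 10/3 per 100 codons
  nt <- ribosomes_from_density(
    tibble::tibble(id = "a", abundance = 1, orf_codons = 300, density = 1),
    footprint = 12, unit = "per1000nt"
  )
  expect_equal(nt$density, 10 / 3)

  expect_error(
    ribosomes_from_density(tibble::tibble(id = "a", abundance = 1,
                                          orf_codons = 120, density = -1)),
    class = "fluxcompete_validation_error"
  )
})

test_that("missing occupancies are filled and P recomputed", {
  tbl <- tibble::tibble(id = c("a", "b", "c"), abundance = 1,
                        orf_codons = 240,
                        occupancy = c(0.5, NA, NA), polysome_size = c(4, 4, 8))
  out <- fill_occupancy(tbl, default = 0.75)
  expect_equal(attr(out, "n_filled"), 2)
  expect_equal(out$occupancy, c(0.5, 0.75, 0.75))
  expect_equal(out$P, c(2, 3, 6))

  same <- fill_occupancy(out, default = 0.75)
  expect_equal(attr(same, "n_filled"), 0)
  expect_equal(same$P, out$P)
})

test_that("forcing full occupancy recovers polysome-size bound counts", {
  tbl <- tibble::tibble(id = c("a", "b"), abundance = c(3, 1),
                        orf_codons = 240,
                        occupancy = c(0.5, 0.8), polysome_size = c(6, 10))
  st <- translation_state(fill_occupancy(tbl), total_ribosome = 79,
                          footprint = 12)
  full <- force_full_occupancy(st)
  expect_equal(full$P, c(6, 10))
  expect_true(all(full$occupancy == 1))
})

test_that("ratio identities and the ultrasensitivity predicate hold genome-wide", {
  set.seed(19)
  for (rep in 1:20) {
    st <- random_translation_state(n = 15)
    R_T <- response_to_ribosome(st)

    expect_equal(translation_ultrasensitive(st), R_T > 1)

    # relative sensitivity to a third competitor = ratio of pool responses
    expect_equal(crosstalk_ratio(st, 1, 2, 3), R_T[1] / R_T[2],
                 tolerance = 1e-12)
    expect_equal(response_to_other_mrna(st, 1, 3) /
                   response_to_other_mrna(st, 2, 3),
                 R_T[1] / R_T[2], tolerance = 1e-12)

    # competitor strength = relative bound ribosome amount, whichever flux
    expect_equal(strength_ratio(st, 4, 5),
                 (st$abundance[4] * st$P[4]) / (st$abundance[5] * st$P[5]))
    for (i in c(1, 2)) {
      expect_equal(response_to_other_mrna(st, i, 4) /
                     response_to_other_mrna(st, i, 5),
                   strength_ratio(st, 4, 5), tolerance = 1e-12)
    }

    # the less saturated of any two transcripts responds more to the pool
    s <- effective_saturation(st)
    expect_equal(order(s), order(-R_T))
  }
})

test_that("transcriptome TSV round trips through the dialect", {
  st <- tiny_translation_state()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transcriptome_tsv(st, path)
  back <- read_transcriptome_tsv(path)
  expect_equal(attr(back, "total_ribosome"), 79)
  expect_equal(attr(back, "footprint"), 12)
  expect_equal(back$P, st$P)
  expect_equal(response_to_ribosome(back), response_to_ribosome(st))
})
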