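# Shared fixtures built in code.

sigma_state <- function() sigma_factor_state()

# frozen from the printed sigma-factor table (2 significant figures)
SIGMA_TABLE <- rbind(
  sigma70 = c(T = 0.70, sigma70 = 0.45, sigma54 = -0.055, sigma28 = -0.10),
  sigma54 = c(T = 1.6, sigma70 = -1.2, sigma54 = 0.88, sigma28 = -0.23),
  sigma28 = c(T = 2.3, sigma70 = -1.8, sigma54 = -0.18, sigma28 = 0.67)
)

# small transcript table with exact arithmetic (no randomness)
tiny_translation_state <- function(total_ribosome = 79, footprint = 12) {
  translation_state(
    tibble::tibble(
      id = c("g1", "g2", "g3"),
      abundance = c(2, 0.5, 1),
      orf_codons = c(240, 120, 600),
      P = c(5, 8, 10)
    ),
    total_ribosome = total_ribosome, footprint = footprint
  )
}

# random multi-site transcript table satisfying all invariants
random_translation_state <- function(n = 20, total_ribosome = 79,
                                     footprint = 12) {
  orf <- pmax(footprint, round(stats::rlnorm(n, log(300), 0.6)))
  s <- stats::runif(n, 0.01, 0.9)
  P <- s * orf / footprint
  C <- stats::rlnorm(n, log(0.01), 1)
  scale <- 0.9 * total_ribosome / sum(C * P)
  if (scale < 1) C <- C * scale
  translation_state(
    tibble::tibble(id = sprintf("g%03d", seq_len(n)), abundance = C,
                   orf_codons = orf, P = P),
    total_ribosome = total_ribosome, footprint = footprint
  )
}
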