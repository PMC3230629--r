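#' Configuration for the synthetic transcriptome generator
#'
#' Defaults emulate the statistical structure of the yeast genome-scale
#' tables the translation analysis is designed for: 4621 genes, a 79 uM
#' ribosome pool, a 12-codon footprint, log-normal ORF lengths (median 400
#' codons) and mRNA abundances (positive skew), log-normal ribosome
#' densities capped at the physical maximum `100/L`, and Beta-distributed
#' ribosome occupancies with mean 0.75, a small fraction of which are
#' missing and later filled at the 0.75 default.  The abundance scale is
#' calibrated so that the expected engaged share of the ribosome pool is
#' `1 - free_fraction`; draws that overshoot the pool are rescaled down to
#' exactly that share.
#'
#' @param n_genes Number of genes.
#' @param total_ribosome Ribosome pool `T` (uM-equivalent).
#' @param footprint Ribosome footprint `L` in codons.
#' @param orf_meanlog,orf_sdlog Log-normal ORF length parameters (codons);
#'   draws are clamped to `[footprint, orf_max]`.
#' @param orf_max Upper ORF length bound (codons).
#' @param density_meanlog,density_sdlog Log-normal ribosome density
#'   parameters (ribosomes per 100 codons); draws above `100/L` are clamped.
#' @param occupancy_mean,occupancy_kappa Mean and concentration of the Beta
#'   occupancy distribution (`alpha = mean * kappa`, `beta = (1-mean) * kappa`).
#' @param missing_occupancy_fraction Fraction of genes with missing
#'   occupancy, to be completed by [fill_occupancy()].
#' @param abundance_sdlog Log-normal spread of mRNA abundances.
#' @param free_fraction Free-ribosome share targeted by the calibration and
#'   enforced from above by rescaling.
#' @return A list of class `transcriptome_config`.
#' @export
transcriptome_config <- function(n_genes = 4621,
                                 total_ribosome = 79,
                                 footprint = 12,
                                 orf_meanlog = log(400),
                                 orf_sdlog = 0.65,
                                 orf_max = 5000,
                                 density_meanlog = log(1),
                                 density_sdlog = 0.6,
                                 occupancy_mean = 0.75,
                                 occupancy_kappa = 12,
                                 missing_occupancy_fraction = 0.02,
                                 abundance_sdlog = 1,
                                 free_fraction = 0.05) {
  if (n_genes < 1) stop_validation("n_genes must be >= 1")
  if (free_fraction < 0 || free_fraction >= 1) {
    stop_validation("free_fraction must be in [0, 1)")
  }
  if (occupancy_mean <= 0 || occupancy_mean > 1) {
    stop_validation("occupancy_mean must be in (0, 1]")
  }
  if (missing_occupancy_fraction < 0 || missing_occupancy_fraction > 1) {
    stop_validation("missing_occupancy_fraction must be in [0, 1]")
  }
  structure(as.list(environment()), class = "transcriptome_config")
}

#' Generate a synthetic genome-scale transcript table
#'
#' Draws ORF lengths, abundances, ribosome densities and occupancies from
#' the configured distributions, converts densities to bound-ribosome
#' counts with physical-cap clamping ([ribosomes_from_density()]), blanks a
#' configured fraction of occupancies and fills them at the default
#' ([fill_occupancy()]), and finally enforces ribosome conservation: if the
#' drawn `sum(C * P)` exceeds the engaged share `(1 - free_fraction) * T`,
#' all `P` are rescaled by a common factor.  Reproducible given `seed`.
#'
#' @param config A [transcriptome_config()].
#' @param seed Integer seed.
#' @return A [translation_state()]; attributes `n_clamped`, `n_filled` and
#'   `rescale_factor` record the cleaning steps.
#' @export
generate_transcriptome <- function(config = transcriptome_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "transcriptome_config"))
  cfg <- config
  withr::with_seed(seed, {
    n <- cfg$n_genes
    orf <- round(stats::rlnorm(n, cfg$orf_meanlog, cfg$orf_sdlog))
    orf <- pmin(pmax(orf, cfg$footprint), cfg$orf_max)
    density <- stats::rlnorm(n, cfg$density_meanlog, cfg$density_sdlog)
    a <- cfg$occupancy_mean * cfg$occupancy_kappa
    b <- (1 - cfg$occupancy_mean) * cfg$occupancy_kappa
    occupancy <- if (b > 0) stats::rbeta(n, a, b) else rep(1, n)
    occupancy <- pmin(pmax(occupancy, 1e-3), 1)
    occupancy[stats::runif(n) < cfg$missing_occupancy_fraction] <- NA_real_

    # abundance scale chosen so the expected engaged pool share is
    # (1 - free_fraction): E[C] * n * E[P] ~= (1 - free_fraction) * T
    mean_P_expected <- cfg$occupancy_mean *
      exp(cfg$density_meanlog + cfg$density_sdlog^2 / 2) / 100 *
      exp(cfg$orf_meanlog + cfg$orf_sdlog^2 / 2)
    mean_C <- (1 - cfg$free_fraction) * cfg$total_ribosome /
      (n * mean_P_expected)
    abundance <- stats::rlnorm(
      n, log(mean_C) - cfg$abundance_sdlog^2 / 2, cfg$abundance_sdlog
    )

    tbl <- tibble::tibble(
      id = sprintf("gene%04d", seq_len(n)),
      abundance = abundance,
      orf_codons = as.numeric(orf),
      density = density,
      occupancy = occupancy
    )
  })
  tbl <- suppressWarnings(
    ribosomes_from_density(tbl, footprint = cfg$footprint)
  )
  n_clamped <- attr(tbl, "n_clamped")
  tbl$polysome_size <- tbl$P   # density-derived mean ribosomes per bound mRNA
  tbl <- fill_occupancy(tbl, default = cfg$occupancy_mean)
  n_filled <- attr(tbl, "n_filled")

  engaged_cap <- (1 - cfg$free_fraction) * cfg$total_ribosome
  bound <- sum(tbl$abundance * tbl$P)
  rescale <- if (bound > engaged_cap) engaged_cap / bound else 1
  if (rescale < 1) {
    tbl$P <- tbl$P * rescale
    tbl$polysome_size <- tbl$polysome_size * rescale
    tbl$density <- tbl$density * rescale
  }
  if (cfg$total_ribosome == 0 && bound > 0) {
    stop_validation("cannot place bound ribosomes with a zero pool")
  }
  out <- translation_state(tbl, total_ribosome = cfg$total_ribosome,
                           footprint = cfg$footprint)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_filled") <- n_filled
  attr(out, "rescale_factor") <- rescale
  out
}

#' Genome-wide distribution of ribosome-pool response coefficients
#'
#' Evaluates the translation response to the total ribosome pool for every
#' gene and summarises the distribution: fraction of ultrasensitive genes
#' (coefficient above 1), quantiles, and histogram counts.
#'
#' @param state A [translation_state()].
#' @param breaks Histogram break points (passed to [graphics::hist()]
#'   semantics via [base::cut()]); default 0 to the observed maximum in
#'   steps of 0.1.
#' @return A list of class `genome_response` with elements `per_gene`
#'   (tibble `id`, `coefficient`, `saturation`, `ultrasensitive`),
#'   `summary` (one-row tibble) and `histogram` (tibble `bin_left`,
#'   `bin_right`, `count`).
#' @export
genome_response_distribution <- function(state, breaks = NULL) {
  coef <- response_to_ribosome(state)
  per_gene <- tibble::tibble(
    id = state$id,
    coefficient = coef,
    saturation = effective_saturation(state),
    ultrasensitive = translation_ultrasensitive(state)
  )
  if (is.null(breaks)) {
    breaks <- seq(0, max(coef) + 0.1, by = 0.1)
  }
  counts <- table(cut(coef, breaks = breaks, include.lowest = TRUE,
                      right = FALSE))
  histogram <- tibble::tibble(
    bin_left = utils::head(breaks, -1),
    bin_right = breaks[-1],
    count = as.integer(counts)
  )
  q <- stats::quantile(coef, c(0.05, 0.25, 0.5, 0.75, 0.95))
  summary <- tibble::tibble(
    n_genes = length(coef),
    fraction_above_1 = mean(coef > 1),
    q05 = q[[1]], q25 = q[[2]], median = q[[3]], q75 = q[[4]], q95 = q[[5]],
    mean = mean(coef)
  )
  structure(list(per_gene = per_gene, summary = summary,
                 histogram = histogram),
            class = "genome_response")
}

#' @export
print.genome_response <- function(x, ...) {
  cat("<genome_response> ", x$summary$n_genes, " genes, ",
      round(100 * x$summary$fraction_above_1, 1),
      "% with pool response above 1\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Extract the tail bins of a response distribution
#'
#' Ranks genes by coefficient (ties broken by gene id, so the split is
#' fully deterministic) and returns the lowest- and highest-responding
#' bins, each of size `floor(fraction * n)` -- for 4621 genes at 5 percent,
#' bins of 231 genes.  Intended for export towards downstream annotation
#' tools.
#'
#' @param x A `genome_response` object, or a data frame with columns `id`
#'   and `coefficient`.
#' @param fraction Tail fraction in `(0, 0.5]`.
#' @return A list with tibbles `low` and `high` (columns `id`,
#'   `coefficient`, `rank`), ordered from the extreme inwards.
#' @export
tail_bins <- function(x, fraction = 0.05) {
  if (inherits(x, "genome_response")) x <- x$per_gene
  if (!all(c("id", "coefficient") %in% names(x))) {
    stop_validation("need columns `id` and `coefficient`")
  }
  if (fraction <= 0 || fraction > 0.5) {
    stop_validation("fraction must be in (0, 0.5]")
  }
  n <- nrow(x)
  size <- floor(fraction * n)
  if (size < 1) stop_validation("tail fraction selects no genes")
  ord <- order(x$coefficient, x$id)
  ranked <- tibble::as_tibble(x[ord, c("id", "coefficient")])
  ranked$rank <- seq_len(n)
  list(
    low = ranked[seq_len(size), ],
    high = ranked[seq(n, n - size + 1), ]
  )
}
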