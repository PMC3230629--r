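#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a response matrix into long form
#'
#' @param x A [response_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `flux`, `parameter` (`"T"` or a competitor
#'   label), `coefficient`.
#' @exportS3Method generics::tidy
tidy.response_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -"flux",
                              names_to = "parameter",
                              values_to = "coefficient")
  long$parameter <- sub("^R_", "", long$parameter)
  long$parameter[long$parameter == "T"] <- "T"
  long
}

#' One-row summary of a response matrix
#'
#' @param x A [response_matrix()].
#' @param ... Unused.
#' @return A tibble with the state totals, the free target, and the number
#'   of ultrasensitive fluxes (target response above 1).
#' @exportS3Method generics::glance
glance.response_matrix <- function(x, ...) {
  tibble::tibble(
    n_competitors = nrow(x),
    total_target = attr(x, "total_target"),
    free_target = attr(x, "free_target"),
    n_ultrasensitive = sum(x$R_T > 1)
  )
}

#' Tidy a polysome state into per-codon occupancies
#'
#' @param x A [polysome_state()].
#' @param ... Unused.
#' @return A tibble with columns `species`, `codon`, `occupancy`.
#' @exportS3Method generics::tidy
tidy.polysome_state <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$profiles, function(p, lab) {
    tibble::tibble(species = lab, codon = seq_along(p), occupancy = p)
  }))
}

#' One-row-per-species summary of a polysome state
#'
#' @param x A [polysome_state()].
#' @param ... Unused.
#' @return A tibble with `species`, `abundance`, `P`, `effective_saturation`,
#'   `flux`, and the shared `free_ribosome`.
#' @exportS3Method generics::glance
glance.polysome_state <- function(x, ...) {
  L <- attr(x$params, "footprint")
  tibble::tibble(
    species = x$params$label,
    abundance = x$params$abundance,
    P = unname(x$P),
    effective_saturation = unname(x$P) * L / x$params$n_codons,
    flux = unname(x$flux),
    free_ribosome = x$free_ribosome
  )
}

#' Tidy a genome response distribution
#'
#' @param x A `genome_response`.
#' @param ... Unused.
#' @return The per-gene coefficient tibble.
#' @exportS3Method generics::tidy
tidy.genome_response <- function(x, ...) x$per_gene

#' One-row summary of a genome response distribution
#'
#' @param x A `genome_response`.
#' @param ... Unused.
#' @return The summary tibble (fraction above 1, quantiles, mean).
#' @exportS3Method generics::glance
glance.genome_response <- function(x, ...) x$summary
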