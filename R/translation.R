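#' Construct a translation (mRNA/ribosome) competition state
#'
#' Each mRNA species competes for the shared ribosome pool and can bind
#' several ribosomes at once.  The single-binding theory carries over with
#' two substitutions: the saturation of mRNA `i` becomes `P_i * L / N_i`
#' (bound ribosomes over the packing capacity of the open reading frame)
#' and the fraction of the ribosome pool it holds becomes `C_i * P_i / T`.
#'
#' The mean number of bound ribosomes per mRNA molecule, `P`, may be given
#' directly, or as `occupancy * polysome_size` (fraction of molecules
#' carrying at least one ribosome, times mean ribosomes on those), or via a
#' ribosome `density`; precedence is `P`, then occupancy x polysome size,
#' then density (see [ribosomes_from_density()]).
#'
#' @param data A data frame with columns `id`, `abundance` (mRNA amount
#'   `C`), `orf_codons` (ORF length `N`), and at least one of: `P`;
#'   `occupancy` and `polysome_size`; `density` (ribosomes per 100 codons).
#' @param total_ribosome Total ribosome pool `T` (same unit family as
#'   `abundance`; 79 uM is the yeast-scale default used throughout).
#' @param footprint Codons occluded by one ribosome, `L` (default 12).
#' @param tol Relative validation slack for user tables.
#' @param check_pool Enforce `sum(C * P) <= T`.  Disabled for counterfactual
#'   recalculations such as [force_full_occupancy()], where the bookkeeping
#'   deliberately overcommits the pool.
#' @return A tibble of class `translation_state` with attributes
#'   `total_ribosome` and `footprint`; columns `id`, `abundance`,
#'   `orf_codons`, `P` plus any inputs carried through.
#' @export
translation_state <- function(data, total_ribosome = 79, footprint = 12,
                              tol = 1e-9, check_pool = TRUE) {
  data <- tibble::as_tibble(data)
  req <- c("id", "abundance", "orf_codons")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop_validation("transcript table needs columns ",
                    paste(missing_cols, collapse = ", "))
  }
  if (footprint < 1) stop_validation("footprint L must be >= 1")
  if (!is.numeric(total_ribosome) || total_ribosome < 0) {
    stop_validation("`total_ribosome` must be a non-negative number")
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) stop_validation("transcript ids must be unique")
  if (any(data$abundance < 0) || anyNA(data$abundance)) {
    stop_validation("abundances must be non-negative and non-missing")
  }
  if (any(data$orf_codons < footprint)) {
    stop_validation("every ORF must be at least one footprint (L = ",
                    footprint, " codons) long")
  }

  if (!"P" %in% names(data)) {
    if (all(c("occupancy", "polysome_size") %in% names(data))) {
      data$P <- data$occupancy * data$polysome_size
    } else if ("density" %in% names(data)) {
      data <- ribosomes_from_density(data, footprint = footprint)
    } else {
      stop_validation("supply `P`, or `occupancy` + `polysome_size`, ",
                      "or `density`")
    }
  }
  if (anyNA(data$P) || any(data$P < 0)) {
    stop_validation("bound-ribosome counts P must be non-negative ",
                    "and non-missing (see fill_occupancy())")
  }
  cap <- data$orf_codons / footprint
  if (any(data$P > cap * (1 + tol))) {
    stop_validation("P exceeds the packing capacity N/L for: ",
                    paste(utils::head(data$id[data$P > cap * (1 + tol)], 5),
                          collapse = ", "))
  }
  bound <- sum(data$abundance * data$P)
  if (check_pool && bound > total_ribosome * (1 + tol)) {
    stop_validation("bound ribosomes (sum C*P = ", format(bound),
                    ") exceed the pool T = ", format(total_ribosome))
  }
  structure(
    data,
    total_ribosome = total_ribosome,
    footprint = footprint,
    class = c("translation_state", class(tibble::tibble()))
  )
}

#' @export
print.translation_state <- function(x, ...) {
  cat("<translation_state> ", nrow(x), " mRNA species, ribosome pool T = ",
      format(attr(x, "total_ribosome")), ", footprint L = ",
      format(attr(x, "footprint")), "\n", sep = "")
  NextMethod()
}

#' Convert ribosome densities to bound-ribosome counts
#'
#' Densities are ribosomes per 100 codons (under which the physical maximum
#' is `100/L`, i.e. 8.33 for a 12-codon footprint); densities reported per
#' 1000 nucleotides can be converted with `unit = "per1000nt"` (1 ribosome
#' per 1000 nt = 10/3 ribosomes per 100 codons).  Values above the physical
#' cap are clamped to slightly below it, mirroring how genome-scale tables
#' with impossible entries are handled, and the number of clamped entries is
#' recorded in attribute `n_clamped` (with a warning).
#'
#' @param data Transcript table with columns `density` and `orf_codons`.
#' @param footprint Ribosome footprint in codons.
#' @param cap_epsilon How far below the cap clamped densities are placed,
#'   in density units (default 0.005).
#' @param unit Unit of the `density` column.
#' @return `data` with a `P` column added (`P = density * N / 100`).
#' @export
ribosomes_from_density <- function(data, footprint = 12, cap_epsilon = 0.005,
                                   unit = c("per100codons", "per1000nt")) {
  unit <- match.arg(unit)
  if (!"density" %in% names(data)) stop_validation("no `density` column")
  dens <- data$density
  if (any(dens < 0, na.rm = TRUE)) {
    stop_validation("ribosome densities must be non-negative")
  }
  if (unit == "per1000nt") dens <- dens * (1000 / 3) / 100
  cap <- 100 / footprint
  over <- !is.na(dens) & dens > cap
  if (any(over)) {
    dens[over] <- cap - cap_epsilon
    warning(sum(over), " density value(s) above the physical maximum ",
            format(round(cap, 2)), " were clamped", call. = FALSE)
  }
  data$density <- dens
  data$P <- dens * data$orf_codons / 100
  attr(data, "n_clamped") <- sum(over)
  data
}

#' Fill missing ribosome occupancies
#'
#' Transcript compilations often lack occupancy for a small fraction of
#' genes; those entries are set to a default (0.75, the mean of the measured
#' values in the yeast compilation this package emulates) and `P` is
#' recomputed as `occupancy * polysome_size`.
#'
#' @param data Transcript table with columns `occupancy` and
#'   `polysome_size` (occupancy may contain `NA`).
#' @param default Occupancy used for missing entries, in `(0, 1]`.
#' @return `data` with occupancies completed and `P` recomputed; attribute
#'   `n_filled` records how many entries were filled.
#' @export
fill_occupancy <- function(data, default = 0.75) {
  if (!all(c("occupancy", "polysome_size") %in% names(data))) {
    stop_validation("need `occupancy` and `polysome_size` columns")
  }
  if (default <= 0 || default > 1) {
    stop_validation("`default` occupancy must be in (0, 1]")
  }
  miss <- is.na(data$occupancy)
  data$occupancy[miss] <- default
  data$P <- data$occupancy * data$polysome_size
  attr(data, "n_filled") <- sum(miss)
  data
}

# translation state -> (s, f, T) on the effective single-binding scale
translation_sf <- function(state) {
  L <- attr(state, "footprint")
  T <- attr(state, "total_ribosome")
  if (T <= 0) stop_validation("ribosome pool must be > 0")
  list(
    s = state$P * L / state$orf_codons,
    f = state$abundance * state$P / T,
    T = T
  )
}

match_transcript <- function(state, i, arg = "i") {
  if (length(i) != 1 || is.na(i)) {
    stop_validation("`", arg, "` must be a single transcript id or index")
  }
  if (is.character(i)) {
    idx <- match(i, state$id)
    if (is.na(idx)) stop_validation("unknown transcript: ", i)
    return(idx)
  }
  idx <- as.integer(i)
  if (idx < 1 || idx > nrow(state)) {
    stop_validation("transcript index out of range: ", i)
  }
  idx
}

pick <- function(x, state, i, matcher = match_transcript) {
  if (is.null(i)) return(x)
  idx <- vapply(i, matcher, integer(1), state = state)
  unname(x[idx])
}

#' Effective saturation of an mRNA by ribosomes
#'
#' `P_i * L / N_i`: bound ribosomes relative to the ORF's packing capacity.
#'
#' @param state A [translation_state()].
#' @param i Transcript id or index; default all.
#' @return Fractions in `[0, 1]`.
#' @export
effective_saturation <- function(state, i = NULL) {
  pick(translation_sf(state)$s, state, i)
}

#' Fraction of the ribosome pool held by an mRNA species
#'
#' `C_i * P_i / T`; the fractions sum to the engaged share of the pool.
#'
#' @inheritParams effective_saturation
#' @return Fractions summing to at most 1.
#' @export
ribosome_fraction <- function(state, i = NULL) {
  pick(translation_sf(state)$f, state, i)
}

#' Translation flux response to the total ribosome pool
#'
#' The multiple-binding analogue of [response_to_target()], with saturation
#' `P_i L / N_i` and pool fraction `C_i P_i / T`.
#'
#' @inheritParams effective_saturation
#' @return Non-negative coefficients; values above 1 are ultrasensitive.
#' @export
response_to_ribosome <- function(state, i = NULL) {
  sf <- translation_sf(state)
  pick(response_core(sf$s, sf$f), state, i)
}

#' Translation flux response to the mRNA's own abundance
#' @inheritParams effective_saturation
#' @return Coefficients in `[0, 1]`.
#' @export
response_to_own_mrna <- function(state, i = NULL) {
  sf <- translation_sf(state)
  pick(1 - response_core(sf$s, sf$f) * sf$f, state, i)
}

#' Translation flux response to a competing mRNA's abundance
#' @inheritParams effective_saturation
#' @param i Transcript whose flux responds.
#' @param k Competing transcript whose abundance is perturbed (`k != i`).
#' @return A single non-positive coefficient.
#' @export
response_to_other_mrna <- function(state, i, k) {
  ii <- match_transcript(state, i, "i")
  kk <- match_transcript(state, k, "k")
  if (ii == kk) {
    stop_validation("i and k refer to the same transcript; ",
                    "use response_to_own_mrna() for the self response")
  }
  sf <- translation_sf(state)
  unname(-response_core(sf$s, sf$f)[ii] * sf$f[kk])
}

#' Is a translation flux ultrasensitive to the ribosome pool?
#'
#' Division-free criterion `sum_j C_j P_j s_j > s_i T` with
#' `s = P L / N`; algebraically equivalent to
#' `response_to_ribosome(state, i) > 1`.
#'
#' @inheritParams effective_saturation
#' @return Logical vector.
#' @export
translation_ultrasensitive <- function(state, i = NULL) {
  sf <- translation_sf(state)
  lhs <- sum(state$abundance * state$P * sf$s)
  pick(lhs > sf$s * sf$T, state, i)
}

#' Relative sensitivity of two translation fluxes to a third competitor
#'
#' `R_i^{C_k} / R_j^{C_k}` is independent of `k` and equals the ratio of
#' ribosome-pool responses `R_i^T / R_j^T`.
#'
#' @inheritParams effective_saturation
#' @param i,j Transcripts whose fluxes respond.
#' @param k The perturbed competitor (distinct from both).
#' @return A single ratio.
#' @export
crosstalk_ratio <- function(state, i, j, k) {
  ii <- match_transcript(state, i, "i")
  jj <- match_transcript(state, j, "j")
  kk <- match_transcript(state, k, "k")
  if (kk == ii || kk == jj) {
    stop_validation("k must differ from both i and j")
  }
  sf <- translation_sf(state)
  if (sf$s[jj] >= 1) {
    stop_degenerate("transcript ", state$id[jj], " is fully packed")
  }
  (1 - sf$s[ii]) / (1 - sf$s[jj])
}

#' Relative competitor strength of two mRNAs
#'
#' `C_k P_k / (C_l P_l)`: relative amount of ribosome bound, the same
#' ranking whichever third flux is influenced.
#'
#' @inheritParams effective_saturation
#' @param k,l Transcript ids or indices.
#' @return A single ratio.
#' @export
strength_ratio <- function(state, k, l) {
  kk <- match_transcript(state, k, "k")
  ll <- match_transcript(state, l, "l")
  denom <- state$abundance[ll] * state$P[ll]
  if (denom == 0) {
    stop_degenerate("transcript ", state$id[ll],
                    " holds no ribosomes; strength ratio undefined")
  }
  unname(state$abundance[kk] * state$P[kk] / denom)
}

#' View a translation state as a single-binding competition state
#'
#' Maps each mRNA to an effective single-site competitor with
#' `C = abundance * N / L` binding sites and `tc = abundance * P` bound
#' ribosomes, under which the single-binding formulas coincide with the
#' translation formulas.  For one-site mRNAs (`N = L`) this is the exact
#' reduction.
#'
#' @param state A [translation_state()].
#' @return A [competition_state()].
#' @export
as_competition_state <- function(state) {
  L <- attr(state, "footprint")
  competition_state(
    tibble::tibble(
      label = state$id,
      C = state$abundance * state$orf_codons / L,
      tc = state$abundance * state$P
    ),
    total_target = attr(state, "total_ribosome")
  )
}
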