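#' Parameters of the ribosome-traffic (polysome) translation model
#'
#' A mechanistic simulator of several mRNA species sharing one ribosome
#' pool, with hard-body steric exclusion.  Each codon of each species
#' carries a state variable: the fraction of that species' molecules with a
#' ribosome *front* at that codon.  Initiation is bimolecular in free
#' ribosomes and the free start region; elongation steps a front forward at
#' a rate weighted by the conditional probability that the next codon is
#' free; termination releases the ribosome from the last codon.
#'
#' @param n_codons ORF lengths (codons), one per species; each `>= L`.
#' @param k_init Initiation rate constants (amount^-1 time^-1).
#' @param k_elong Elongation rate constants (time^-1).
#' @param k_term Termination rate constants (time^-1).
#' @param abundance mRNA amounts `C`, same unit family as `total_ribosome`.
#' @param total_ribosome Total ribosome pool `T`.
#' @param footprint Codons occluded by one ribosome (`L`, default 12).
#' @param labels Species labels (default `"mrna1"`, ...).
#' @return A tibble of class `polysome_params` with attributes
#'   `total_ribosome` and `footprint`.
#' @export
polysome_params <- function(n_codons, k_init, k_elong, k_term, abundance,
                            total_ribosome, footprint = 12, labels = NULL) {
  n <- length(abundance)
  n_codons <- rep_len(n_codons, n)
  k_init <- rep_len(k_init, n)
  k_elong <- rep_len(k_elong, n)
  k_term <- rep_len(k_term, n)
  if (is.null(labels)) labels <- paste0("mrna", seq_len(n))
  if (any(c(k_init, k_elong, k_term) <= 0)) {
    stop_validation("all rate constants must be > 0")
  }
  if (any(n_codons < footprint)) {
    stop_validation("every ORF must be at least one footprint long")
  }
  if (any(abundance < 0) || total_ribosome < 0) {
    stop_validation("amounts must be non-negative")
  }
  structure(
    tibble::tibble(label = as.character(labels), n_codons = as.integer(n_codons),
                   k_init = k_init, k_elong = k_elong, k_term = k_term,
                   abundance = abundance),
    total_ribosome = total_ribosome,
    footprint = as.integer(footprint),
    class = c("polysome_params", class(tibble::tibble()))
  )
}

#' Two-mRNA ribosome competition benchmark
#'
#' A two-species system with strongly asymmetric initiation used throughout
#' for validating the translation response formulas against the traffic
#' simulator: ORFs of 240 codons, 12-codon footprint, mRNA amounts 0.2 and
#' 2 uM, initiation constants 0.2 and 5 (uM min)^-1, elongation and
#' termination at 50 min^-1 (species 1) and 20 min^-1 (species 2).
#'
#' @param total_ribosome Ribosome pool in uM.
#' @return A [polysome_params()] object.
#' @export
two_mrna_polysome_params <- function(total_ribosome = 79) {
  polysome_params(
    n_codons = c(240, 240), k_init = c(0.2, 5),
    k_elong = c(50, 20), k_term = c(50, 20),
    abundance = c(0.2, 2), total_ribosome = total_ribosome, footprint = 12
  )
}

# --- state ------------------------------------------------------------------

#' Construct (and validate) a polysome model state
#'
#' @param params A [polysome_params()].
#' @param profiles List of per-species codon occupancy profiles (fraction of
#'   molecules with a ribosome front at each codon).
#' @param tol Feasibility slack for the exclusion window sums and ribosome
#'   conservation.
#' @return A list of class `polysome_state` with elements `params`,
#'   `profiles`, `free_ribosome`, `P` (mean bound ribosomes per molecule,
#'   named) and `flux` (per-species protein synthesis flux
#'   `C * k_term * p_n`).
#' @export
polysome_state <- function(params, profiles, tol = 1e-9) {
  n <- nrow(params)
  if (length(profiles) != n) {
    stop_validation("need one occupancy profile per species")
  }
  L <- attr(params, "footprint")
  for (sp in seq_len(n)) {
    p <- profiles[[sp]]
    if (length(p) != params$n_codons[sp]) {
      stop_validation("profile length mismatch for species ",
                      params$label[sp])
    }
    if (any(p < -tol) || any(p > 1 + tol)) {
      stop_validation("occupancies must lie in [0, 1]")
    }
    win <- window_sums(p, L)
    if (any(win > 1 + 1e-6)) {
      stop_validation("hard-body exclusion violated for species ",
                      params$label[sp], " (an L-codon window sums above 1)")
    }
  }
  P <- vapply(profiles, sum, numeric(1))
  r_free <- attr(params, "total_ribosome") - sum(params$abundance * P)
  if (r_free < -tol * max(attr(params, "total_ribosome"), 1)) {
    stop_validation("bound ribosomes exceed the pool")
  }
  structure(
    list(
      params = params,
      profiles = stats::setNames(profiles, params$label),
      free_ribosome = max(0, r_free),
      P = stats::setNames(P, params$label),
      flux = stats::setNames(
        params$abundance * params$k_term *
          vapply(profiles, function(p) p[length(p)], numeric(1)),
        params$label
      )
    ),
    class = "polysome_state"
  )
}

#' @export
print.polysome_state <- function(x, ...) {
  cat("<polysome_state> ", nrow(x$params), " mRNA species, free ribosome = ",
      format(x$free_ribosome), "\n", sep = "")
  print(tibble::tibble(species = x$params$label, P = unname(x$P),
                       flux = unname(x$flux)))
  invisible(x)
}

# sliding sums of p over windows of (at most) L codons starting at each codon
window_sums <- function(p, L) {
  n <- length(p)
  cs <- c(0, cumsum(p))
  j <- seq_len(n)
  cs[pmin(j + L - 1, n) + 1] - cs[j]
}

#' Initiation rate of one species
#'
#' `k_init * r_free * max(0, 1 - sum(p[1:L]))`: bimolecular in free
#' ribosomes and the probability that the first footprint is clear.
#'
#' @param state A [polysome_state()].
#' @param species Species label or index.
#' @return Rate per mRNA molecule (time^-1).
#' @export
initiation_rate <- function(state, species) {
  sp <- match_competitor(state$params, species, "species")
  p <- state$profiles[[sp]]
  L <- attr(state$params, "footprint")
  state$params$k_init[sp] * state$free_ribosome *
    max(0, 1 - sum(p[seq_len(min(L, length(p)))]))
}

#' Elongation rate out of one codon
#'
#' `k_elong * p_j * (1 - S(j+1, j+L)) / (1 - S(j+1, j+L-1))` where
#' `S(a, b)` sums the profile over codons `a..min(b, n)`: the conditional
#' probability that the next codon is free given a front at `j`, with
#' codons past the stop treated as free.
#'
#' @inheritParams initiation_rate
#' @param codon Codon index `j` with `1 <= j < n_codons`.
#' @return Rate per mRNA molecule (time^-1).
#' @export
elongation_rate <- function(state, species, codon) {
  sp <- match_competitor(state$params, species, "species")
  p <- state$profiles[[sp]]
  n <- length(p)
  if (codon < 1 || codon >= n) {
    stop_validation("codon must satisfy 1 <= codon < n_codons")
  }
  L <- attr(state$params, "footprint")
  cs <- c(0, cumsum(p))
  S_num <- cs[min(codon + L, n) + 1] - cs[codon + 1]
  S_den <- cs[min(codon + L - 1, n) + 1] - cs[codon + 1]
  den <- 1 - S_den
  if (den <= 0) {
    stop_degenerate("exclusion violation downstream of codon ", codon,
                    " for species ", state$params$label[sp])
  }
  state$params$k_elong[sp] * p[codon] * (1 - S_num) / den
}

#' Termination rate of one species
#'
#' `k_term * p_n`; the corresponding protein synthesis flux is
#' `C * k_term * p_n`.
#'
#' @inheritParams initiation_rate
#' @return Rate per mRNA molecule (time^-1).
#' @export
termination_rate <- function(state, species) {
  sp <- match_competitor(state$params, species, "species")
  p <- state$profiles[[sp]]
  state$params$k_term[sp] * p[length(p)]
}

# --- dynamics ---------------------------------------------------------------

# vectorized RHS on the concatenated profile vector
polysome_rhs <- function(y, params, idx) {
  T <- attr(params, "total_ribosome")
  L <- attr(params, "footprint")
  bound <- 0
  for (sp in seq_along(idx)) {
    bound <- bound + params$abundance[sp] * sum(y[idx[[sp]]])
  }
  r_free <- T - bound
  dy <- numeric(length(y))
  for (sp in seq_along(idx)) {
    p <- y[idx[[sp]]]
    n <- length(p)
    cs <- c(0, cumsum(p))
    v_init <- params$k_init[sp] * r_free *
      max(0, 1 - cs[min(L, n) + 1])
    v_term <- params$k_term[sp] * p[n]
    if (n > 1) {
      j <- seq_len(n - 1)
      S_num <- cs[pmin(j + L, n) + 1] - cs[j + 1]
      S_den <- cs[pmin(j + L - 1, n) + 1] - cs[j + 1]
      den <- pmax(1 - S_den, 1e-12)
      v <- params$k_elong[sp] * p[j] * (1 - S_num) / den
      dp <- c(v_init - v[1],
              if (n > 2) v[j[-1] - 1] - v[j[-1]],
              v[n - 1] - v_term)
    } else {
      dp <- v_init - v_term
    }
    dy[idx[[sp]]] <- dp
  }
  dy
}

profile_index <- function(params) {
  ends <- cumsum(params$n_codons)
  starts <- c(1, utils::head(ends, -1) + 1)
  purrr::map2(starts, ends, seq)
}

#' Simulate the polysome model to steady state
#'
#' Two engines solve the same mechanistic model.  `"recursion"` (the
#' default) exploits the steady-state structure directly: along one mRNA
#' every per-molecule flux (initiation, each elongation step, termination)
#' is equal, so given the throughput the whole codon profile follows by
#' backward recursion from the stop codon; the throughput of each species
#' at a given free-ribosome level is then a monotone scalar root
#' (initiation balance), and the free-ribosome level itself the unique
#' root of pool conservation -- two nested bracketed root-finds, solved to
#' near machine precision.  `"ode"` integrates the per-codon occupancy
#' ODEs from empty mRNAs (or a warm start) with a stiff solver, checking
#' the derivative norm at geometric checkpoints until
#' `max |dp/dt| <= ss_tol`; it is the independent dynamic cross-check and
#' is practical at coarse ORF lengths.
#'
#' @param params A [polysome_params()].
#' @param engine `"recursion"` or `"ode"`.
#' @param init Optional warm-start profiles (ODE engine only).
#' @param ss_tol Steady-state criterion on the maximum absolute derivative
#'   (occupancy fraction per time unit; ODE engine).
#' @param max_time Integration horizon before non-convergence is reported
#'   (ODE engine).
#' @param rtol,atol Solver tolerances (ODE engine).
#' @return A [polysome_state()] at steady state.
#' @export
simulate_polysome <- function(params, engine = c("recursion", "ode"),
                              init = NULL, ss_tol = 1e-9,
                              max_time = 1e6, rtol = 1e-8, atol = 1e-10) {
  engine <- match.arg(engine)
  if (engine == "recursion") {
    return(steady_polysome_recursion(params))
  }
  idx <- profile_index(params)
  y0 <- if (is.null(init)) {
    numeric(sum(params$n_codons))
  } else {
    unlist(init, use.names = FALSE)
  }
  if (attr(params, "total_ribosome") == 0 && all(y0 == 0)) {
    return(polysome_state(params, purrr::map(params$n_codons, numeric)))
  }
  rhs <- function(time, y, p) list(polysome_rhs(y, params, idx))
  scale <- max(params$k_elong, params$k_term,
               params$k_init * attr(params, "total_ribosome"))
  t0 <- 1 / scale
  times <- c(0, t0 * 4^(0:max(0, ceiling(log(max_time / t0, base = 4)))))
  times <- times[times <= max_time]
  if (length(times) < 2) times <- c(0, max_time)
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  for (r in seq_len(nrow(sol))[-1]) {
    y <- pmin(pmax(sol[r, -1], 0), 1)
    if (max(abs(polysome_rhs(y, params, idx))) <= ss_tol) {
      return(polysome_state(params, purrr::map(idx, function(ii) unname(y[ii]))))
    }
  }
  last <- sol[nrow(sol), -1]
  stop_convergence("polysome model did not reach steady state",
                   last_state = purrr::map(idx, function(ii) unname(last[ii])))
}

# Backward recursion: steady profile of one species given its per-molecule
# throughput j.  Returns NULL if j exceeds the traffic capacity (profile
# leaves the feasible set).
profile_from_throughput <- function(j, n, L, k_elong, k_term) {
  p <- numeric(n)
  p[n] <- j / k_term
  if (p[n] > 1) return(NULL)
  if (n == 1) return(p)
  # running window sums over codons (i+1..i+L) and (i+1..i+L-1),
  # truncated at the stop codon, updated in O(1) per codon
  S_num <- p[n]                      # i = n-1: window (n..min(n-1+L, n))
  S_den <- if (L > 1) p[n] else 0    # i = n-1: window (n..min(n+L-2, n))
  for (i in seq(n - 1, 1)) {
    den <- 1 - S_den
    if (den <= 0) return(NULL)
    w <- (1 - S_num) / den
    if (w <= 0) return(NULL)
    p[i] <- j / (k_elong * w)
    if (p[i] > 1 || p[i] + S_den > 1) return(NULL)
    if (i > 1) {
      S_num <- S_num + p[i] - if (i + L <= n) p[i + L] else 0
      S_den <- S_den + p[i] - if (i + L - 1 <= n) p[i + L - 1] else 0
    }
  }
  p
}

# Per-species steady throughput at a given free-ribosome level: bisection
# on the initiation balance k_init * r_free * (1 - start window) - j,
# treating capacity-infeasible j as the high side.
species_throughput <- function(r_free, n, L, k_init, k_elong, k_term) {
  a <- k_init * r_free
  if (a <= 0) return(list(j = 0, p = numeric(n)))
  h <- function(j) {
    p <- profile_from_throughput(j, n, L, k_elong, k_term)
    if (is.null(p)) return(-Inf)
    a * (1 - sum(p[seq_len(min(L, n))])) - j
  }
  lo <- 0
  hi <- min(a, k_term, k_elong)
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
  }
  j <- lo
  list(j = j, p = profile_from_throughput(j, n, L, k_elong, k_term))
}

steady_polysome_recursion <- function(params) {
  T <- attr(params, "total_ribosome")
  L <- attr(params, "footprint")
  n_sp <- nrow(params)
  if (T == 0) {
    return(polysome_state(params, purrr::map(params$n_codons, numeric)))
  }
  bound_at <- function(r_free) {
    sols <- purrr::map(seq_len(n_sp), function(sp) {
      species_throughput(r_free, params$n_codons[sp], L,
                         params$k_init[sp], params$k_elong[sp],
                         params$k_term[sp])
    })
    list(sols = sols,
         bound = sum(params$abundance *
                       vapply(sols, function(s) sum(s$p), numeric(1))))
  }
  g <- function(r) r + bound_at(r)$bound - T
  # g strictly increasing, g(0) = -T < 0, g(T) >= 0
  r_free <- stats::uniroot(g, c(0, T), tol = 1e-13 * max(T, 1),
                           maxiter = 200)$root
  final <- bound_at(r_free)
  polysome_state(params, purrr::map(final$sols, "p"))
}

#' Finite-perturbation response coefficient from the polysome model
#'
#' Same log-difference estimator as
#' [mass_action_numerical_response()], applied to the steady-state protein
#' synthesis fluxes of the traffic simulator.  Perturbed runs are
#' warm-started from the reference steady state.
#'
#' @param params A [polysome_params()].
#' @param parameter `"T"` for the ribosome pool, or a species label/index
#'   for that species' mRNA amount.
#' @param delta Fractional perturbation (default 0.01).
#' @param scheme `"forward"` or `"central"` log-difference.
#' @param reference Optional precomputed reference [polysome_state()].
#' @param ... Passed to [simulate_polysome()].
#' @return A tibble with columns `flux`, `parameter`, `coefficient`.
#' @export
polysome_numerical_response <- function(params, parameter, delta = 0.01,
                                        scheme = c("forward", "central"),
                                        reference = NULL, ...) {
  scheme <- match.arg(scheme)
  if (delta <= 0) stop_validation("`delta` must be > 0")
  if (is.null(reference)) reference <- simulate_polysome(params, ...)
  warm <- unname(reference$profiles)
  flux_at <- function(factor) {
    if (factor == 1) return(reference$flux)
    simulate_polysome(perturb_polysome(params, parameter, factor),
                      init = warm, ...)$flux
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
    parameter = if (identical(parameter, "T")) "T" else
      params$label[match_competitor(params, parameter, "parameter")],
    coefficient = unname((log(J_hi) - log(J_lo)) / width)
  )
}

perturb_polysome <- function(params, parameter, factor) {
  T <- attr(params, "total_ribosome")
  C <- params$abundance
  if (identical(parameter, "T")) {
    T <- T * factor
  } else {
    idx <- match_competitor(params, parameter, "parameter")
    C[idx] <- C[idx] * factor
  }
  polysome_params(params$n_codons, params$k_init, params$k_elong,
                  params$k_term, C, T, attr(params, "footprint"),
                  params$label)
}

#' View a simulated polysome state as a translation state
#'
#' Extracts per-species `P` (mean bound ribosomes) from the simulated
#' profiles so the closed-form translation response formulas can be
#' evaluated on exactly the simulator's steady state.
#'
#' @param state A steady [polysome_state()].
#' @return A [translation_state()].
#' @export
as_translation_state <- function(state) {
  params <- state$params
  translation_state(
    tibble::tibble(id = params$label, abundance = params$abundance,
                   orf_codons = params$n_codons, P = unname(state$P)),
    total_ribosome = attr(params, "total_ribosome"),
    footprint = attr(params, "footprint")
  )
}

#' Scan the polysome model over ribosome pool levels
#'
#' For each pool level the simulator is run to steady state; the closed-form
#' translation coefficients are evaluated on the simulated `P` values and
#' compared with finite-perturbation coefficients measured from the
#' simulator, for the pool itself and for every species abundance.
#'
#' @param params A [polysome_params()]; its pool is replaced by each grid
#'   value in turn.
#' @param T_grid Positive ribosome pool levels.
#' @param delta Fractional perturbation.
#' @param ... Passed to [simulate_polysome()].
#' @return A tibble of class `polysome_scan`, long over
#'   (pool level, responding flux, perturbed parameter), with columns
#'   `total_ribosome`, `flux`, `saturation` (effective, of the responding
#'   species), `P`, `flux_value`, `parameter`, `formula`, `numeric`.
#' @export
polysome_scan <- function(params, T_grid, delta = 0.01, ...) {
  if (any(T_grid <= 0)) stop_validation("T grid values must be > 0")
  rows <- purrr::map(T_grid, function(Tval) {
    p <- perturb_polysome(params, "T", Tval / attr(params, "total_ribosome"))
    st <- simulate_polysome(p, ...)
    ts <- as_translation_state(st)
    sat <- effective_saturation(ts)
    selectors <- c(list("T"), as.list(p$label))
    per_param <- purrr::map(selectors, function(sel) {
      num <- polysome_numerical_response(p, sel, delta = delta,
                                         reference = st, ...)
      formula <- if (identical(sel, "T")) {
        response_to_ribosome(ts)
      } else {
        k <- match(sel, p$label)
        purrr::map_dbl(seq_len(nrow(p)), function(i) {
          if (i == k) response_to_own_mrna(ts, i) else
            response_to_other_mrna(ts, i, k)
        })
      }
      tibble::tibble(
        total_ribosome = Tval, flux = p$label, saturation = sat,
        P = unname(st$P), flux_value = unname(st$flux),
        parameter = num$parameter, formula = formula,
        numeric = num$coefficient
      )
    })
    dplyr::bind_rows(per_param)
  })
  structure(dplyr::bind_rows(rows),
            class = c("polysome_scan", class(tibble::tibble())))
}
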