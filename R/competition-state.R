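#' Construct a competition state
#'
#' A competition state holds the sufficient statistics for every response
#' coefficient in this package: the total amount of the shared target
#' (e.g. RNA polymerase core enzyme), and per competitor (e.g. each sigma
#' factor) its total amount and the amount found in complex with the target.
#' All three share one unit (molecules/cell or a concentration); the theory
#' is unit-agnostic and no conversion is ever applied.
#'
#' @param data A data frame with columns `label` (competitor identifier),
#'   `C` (total competitor amount) and `tc` (target-bound complex amount).
#'   Extra columns are carried along untouched.
#' @param total_target Total target amount `T`, same unit as `C` and `tc`.
#' @param tol Relative slack used when validating the conservation
#'   inequalities, to absorb rounding in user-supplied tables.
#'
#' @return A tibble of class `competition_state` with attribute
#'   `total_target`.
#' @examples
#' sigma_factor_state()
#' @export
competition_state <- function(data, total_target, tol = 1e-9) {
  data <- tibble::as_tibble(data)
  req <- c("label", "C", "tc")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(
      "competition state needs columns ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (nrow(data) < 1) stop_validation("at least one competitor is required")
  if (!is.numeric(total_target) || length(total_target) != 1 ||
      is.na(total_target) || total_target < 0) {
    stop_validation("`total_target` must be a single non-negative number")
  }
  data$label <- as.character(data$label)
  if (anyDuplicated(data$label)) {
    stop_validation("competitor labels must be unique")
  }
  if (!is.numeric(data$C) || !is.numeric(data$tc) ||
      anyNA(data$C) || anyNA(data$tc)) {
    stop_validation("`C` and `tc` must be numeric and non-missing")
  }
  slack <- tol * max(total_target, data$C, 1)
  if (any(data$C < -slack) || any(data$tc < -slack)) {
    stop_validation("amounts must be non-negative")
  }
  bad <- data$tc > data$C * (1 + tol) + slack
  if (any(bad)) {
    stop_validation(
      "bound amount exceeds total for: ",
      paste(data$label[bad], collapse = ", ")
    )
  }
  if (sum(data$tc) > total_target * (1 + tol) + slack) {
    stop_validation("sum of bound complexes exceeds the total target amount")
  }
  structure(
    data,
    total_target = total_target,
    class = c("competition_state", class(tibble::tibble()))
  )
}

#' Total target amount of a competition state
#' @param state A [competition_state()].
#' @return A single number, the conserved total target amount.
#' @export
total_target <- function(state) {
  attr(state, "total_target")
}

#' Free (unbound) target amount
#'
#' The conserved total minus the amount bound across all competitors,
#' `t = T - sum(tc)`.
#'
#' @inheritParams total_target
#' @return A single number (clipped at zero against rounding noise).
#' @export
free_target <- function(state) {
  max(0, total_target(state) - sum(state$tc))
}

#' @export
print.competition_state <- function(x, ...) {
  cat("<competition_state> ", nrow(x), " competitor(s), total target T = ",
      format(total_target(x)), ", free target t = ", format(free_target(x)),
      "\n", sep = "")
  NextMethod()
}

# Resolve a competitor selector (label or index) to an integer index.
match_competitor <- function(state, i, arg = "i") {
  if (length(i) != 1 || is.na(i)) {
    stop_validation("`", arg, "` must be a single competitor label or index")
  }
  if (is.character(i)) {
    idx <- match(i, state$label)
    if (is.na(idx)) stop_validation("unknown competitor: ", i)
    return(idx)
  }
  idx <- as.integer(i)
  if (idx < 1 || idx > nrow(state)) {
    stop_validation("competitor index out of range: ", i)
  }
  idx
}

#' Bundled sigma-factor competition example
#'
#' The exponential-phase Escherichia coli numbers for the three most
#' abundant sigma factors competing for RNA polymerase core enzyme:
#' 700 molecules/cell of RNAP (none free), with 545/700 sigma70,
#' 55/110 sigma54 and 100/370 sigma28 molecules bound.
#'
#' @return A [competition_state()] with three competitors.
#' @export
sigma_factor_state <- function() {
  competition_state(
    tibble::tibble(
      label = c("sigma70", "sigma54", "sigma28"),
      C = c(700, 110, 370),
      tc = c(545, 55, 100)
    ),
    total_target = 700
  )
}

# error constructors shared across modules ---------------------------------

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("fluxcompete_validation_error",
                                             "fluxcompete_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("fluxcompete_degenerate_error",
                                             "fluxcompete_error")))
}

stop_convergence <- function(msg, last_state = NULL) {
  stop(errorCondition(msg, last_state = last_state,
                      class = c("fluxcompete_convergence_error",
                                "fluxcompete_error")))
}
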