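# Single table dialect used across the package: UTF-8 TSV, "." decimal,
# leading `#key=value` comment lines for scalar metadata.

read_kv_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_validation("empty file: ", path)
  is_hdr <- cumprod(startsWith(lines, "#")) == 1
  keys <- list()
  for (ln in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      keys[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  body <- lines[!is_hdr]
  if (length(body) == 0) stop_validation("no table rows in ", path)
  tbl <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  list(keys = keys, table = tbl)
}

write_kv_tsv <- function(tbl, path, keys = list()) {
  hdr <- vapply(names(keys), function(k) paste0("#", k, "=", keys[[k]]),
                character(1))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

need_key <- function(keys, name, path) {
  if (is.null(keys[[name]])) {
    stop_validation("missing `#", name, "=` header in ", path)
  }
  val <- suppressWarnings(as.numeric(keys[[name]]))
  if (is.na(val)) stop_validation("non-numeric `#", name, "=` header in ", path)
  val
}

#' Read a competition state from TSV
#'
#' Expects a `#T=<value>` header line followed by tab-separated columns
#' `label`, `C`, `tc`.
#'
#' @param path File path.
#' @return A [competition_state()].
#' @export
read_competition_tsv <- function(path) {
  x <- read_kv_tsv(path)
  competition_state(x$table, total_target = need_key(x$keys, "T", path))
}

#' Write a competition state to TSV
#' @param state A [competition_state()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_competition_tsv <- function(state, path) {
  write_kv_tsv(tibble::as_tibble(state), path,
               keys = list(T = format(total_target(state), digits = 17)))
}

#' Write a response matrix to TSV (and optionally JSON)
#'
#' The TSV has columns `flux`, `R_T`, then `R_<label>` per competitor, with
#' `#T=` and `#t_free=` headers.  The JSON mirror carries the same entries
#' plus the state summary.
#'
#' @param rm A [response_matrix()].
#' @param path TSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_response_matrix_tsv <- function(rm, path, json_path = NULL) {
  write_kv_tsv(tibble::as_tibble(rm), path,
               keys = list(T = format(attr(rm, "total_target"), digits = 17),
                           t_free = format(attr(rm, "free_target"),
                                           digits = 17)))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(total_target = attr(rm, "total_target"),
           free_target = attr(rm, "free_target"),
           saturations = as.list(attr(rm, "saturations")),
           coefficients = tibble::as_tibble(rm)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read a response matrix written by [write_response_matrix_tsv()]
#' @param path TSV path.
#' @return A tibble of class `response_matrix`.
#' @export
read_response_matrix_tsv <- function(path) {
  x <- read_kv_tsv(path)
  structure(
    x$table,
    total_target = need_key(x$keys, "T", path),
    free_target = need_key(x$keys, "t_free", path),
    class = c("response_matrix", class(tibble::tibble()))
  )
}

#' Read a transcript table from TSV
#'
#' Expects `#T=` (ribosome pool) and `#L=` (footprint) headers and columns
#' `id`, `abundance`, `orf_codons` plus `P`, `density`, or `occupancy` and
#' `polysome_size` (see [translation_state()]).
#'
#' @param path File path.
#' @param fill_missing_occupancy Default occupancy for missing entries, or
#'   `NULL` to leave them missing.
#' @return A [translation_state()].
#' @export
read_transcriptome_tsv <- function(path, fill_missing_occupancy = 0.75) {
  x <- read_kv_tsv(path)
  tbl <- x$table
  if (!is.null(fill_missing_occupancy) &&
      all(c("occupancy", "polysome_size") %in% names(tbl)) &&
      anyNA(tbl$occupancy)) {
    tbl <- fill_occupancy(tbl, default = fill_missing_occupancy)
  }
  translation_state(tbl,
                    total_ribosome = need_key(x$keys, "T", path),
                    footprint = need_key(x$keys, "L", path))
}

#' Write a transcript table to TSV
#' @param state A [translation_state()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_tsv <- function(state, path) {
  write_kv_tsv(
    tibble::as_tibble(state), path,
    keys = list(T = format(attr(state, "total_ribosome"), digits = 17),
                L = attr(state, "footprint"))
  )
}

#' Write a genome response distribution summary
#'
#' Emits the per-gene coefficient table (TSV), the summary (JSON: fraction
#' ultrasensitive and quantiles), and the histogram (TSV with columns
#' `bin_left`, `bin_right`, `count`, `variant`).
#'
#' @param gr A `genome_response` from [genome_response_distribution()].
#' @param per_gene_path,summary_path,histogram_path Output paths (`NULL`
#'   skips that output).
#' @param variant Label written into the histogram's `variant` column.
#' @return Invisibly, the list of written paths.
#' @export
write_genome_response <- function(gr, per_gene_path = NULL,
                                  summary_path = NULL,
                                  histogram_path = NULL,
                                  variant = "default") {
  if (!is.null(per_gene_path)) {
    readr::write_tsv(gr$per_gene, per_gene_path, progress = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(gr$summary), summary_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(histogram_path)) {
    readr::write_tsv(dplyr::mutate(gr$histogram, variant = variant),
                     histogram_path, progress = FALSE)
  }
  invisible(list(per_gene = per_gene_path, summary = summary_path,
                 histogram = histogram_path))
}

#' Write ranked tail-bin gene lists
#'
#' @param bins Result of [tail_bins()].
#' @param low_path,high_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_tail_bins <- function(bins, low_path, high_path) {
  readr::write_tsv(bins$low, low_path, progress = FALSE)
  readr::write_tsv(bins$high, high_path, progress = FALSE)
  invisible(c(low_path, high_path))
}

#' Read a key-value simulator configuration file
#'
#' Plain `key=value` lines (comma-separated vectors allowed; `#` comments
#' ignored), e.g. `k_f=24,8,11`, `T=700`.
#'
#' @param path File path.
#' @return A named list of numeric vectors (unparseable values stay
#'   character).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop_validation("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(strsplit(substr(ln, eq + 1, nchar(ln)), ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (anyNA(num)) val else num
  }
  out
}
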