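#' Build a state-wide strata reference for indirect standardisation
#'
#' Sums per-area, per-age-stratum observed counts and populations to the
#' whole-of-study ("state-wide") level.  The resulting stratum-specific
#' rates `y_k / pop_k` are the reference schedule that indirect
#' standardisation applies to each area's own age structure.
#'
#' @param counts per-area counts by stratum: an areas-by-K matrix, or a
#'   length-K vector of state-wide totals.
#' @param populations per-area populations by stratum, same shape as
#'   `counts` (or length-K state totals).
#' @return An object of class `strata_reference`: list with `y_k`, `pop_k`
#'   and `K`.
#' @export
build_strata_reference <- function(counts, populations) {
  y_k <- if (is.matrix(counts)) colSums(counts) else as.numeric(counts)
  pop_k <- if (is.matrix(populations)) colSums(populations) else as.numeric(populations)
  if (length(y_k) != length(pop_k)) stop("strata misaligned across inputs")
  if (any(y_k < 0) || any(pop_k < 0)) stop("negative stratum totals")
  if (any(y_k > 0 & pop_k == 0)) {
    stop("stratum with observed cases but zero population")
  }
  structure(list(y_k = unname(y_k), pop_k = unname(pop_k), K = length(y_k)),
            class = "strata_reference")
}

#' Expected counts by indirect age standardisation
#'
#' `E_i = sum_k y_k * pop_ik / pop_k`: the count area i would record if the
#' state-wide stratum-specific rates applied to its own age structure.
#' The formula is linear in `pop_ik`, so computing E at a fine level and
#' aggregating equals computing it directly at the coarse level.
#'
#' @param pop_ik areas-by-K matrix of per-area stratum populations.
#' @param reference a [build_strata_reference()] object.
#' @return Numeric vector of expected counts, named by `rownames(pop_ik)`.
#' @export
expected_counts <- function(pop_ik, reference) {
  pop_ik <- as.matrix(pop_ik)
  if (ncol(pop_ik) != reference$K) stop("stratum count mismatch")
  if (any(pop_ik < 0)) stop("negative populations")
  rate_k <- ifelse(reference$pop_k > 0, reference$y_k / reference$pop_k, 0)
  if (any(reference$y_k > 0 & reference$pop_k == 0)) {
    stop("reference stratum with cases but zero population")
  }
  drop(pop_ik %*% rate_k)
}

#' Observed standardised incidence ratios
#'
#' `SIR_i = y_i / E_i`.  Areas with `E_i = 0` (zero population) have no
#' defined ratio and are reported as `NA`, the convention used when such
#' regions are greyed out on maps.
#'
#' @param y observed counts (non-negative).
#' @param E expected counts from [expected_counts()] (non-negative).
#' @param area_id optional ids; defaults to names of `y`/`E` or an index.
#' @return A data frame (`OutcomeTable`) with columns `area_id`, `y`, `E`,
#'   `sir`.
#' @export
compute_sir <- function(y, E, area_id = NULL) {
  if (length(y) != length(E)) stop("y and E misaligned")
  if (any(y < 0) || any(E < 0)) stop("negative inputs")
  if (is.null(area_id)) {
    area_id <- if (!is.null(names(y))) names(y)
      else if (!is.null(names(E))) names(E)
      else as.character(seq_along(y))
  }
  sir <- ifelse(E > 0, y / E, NA_real_)
  data.frame(area_id = as.character(area_id), y = as.numeric(y),
             E = as.numeric(E), sir = sir, row.names = NULL)
}

#' Read a long-format strata CSV (`area_id, stratum, count, population`)
#'
#' @param path file path.
#' @return List with matrices `counts` and `populations` (areas x strata).
#' @export
read_strata_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("area_id", "stratum", "count", "population")
  if (!all(need %in% names(df))) stop("strata CSV needs columns: ",
                                      paste(need, collapse = ", "))
  ids <- unique(df$area_id); strata <- sort(unique(df$stratum))
  shape <- function(col) {
    m <- matrix(0, length(ids), length(strata), dimnames = list(ids, strata))
    m[cbind(match(df$area_id, ids), match(df$stratum, strata))] <- df[[col]]
    m
  }
  list(counts = shape("count"), populations = shape("population"))
}

#' Write an outcome table CSV (`area_id, y, E, sir`)
#' @param outcome a [compute_sir()] data frame.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_outcome_csv <- function(outcome, path) {
  utils::write.csv(outcome, path, row.names = FALSE)
  invisible(path)
}
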