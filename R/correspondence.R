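#' Correspondence matrix between two levels of a hierarchy
#'
#' A correspondence matrix carries per-area shares in `[0, 1]` mapping one
#' level's areas onto another's; every row sums to one.  Aggregation
#' (fine source, coarse target) places weight 1 on the unique ancestor, so
#' transferring counts is exact summation.  Disaggregation (coarse source,
#' fine target) uses population shares: the weight on fine area `j` is the
#' total population of `j` divided by the total population of its source
#' ancestor, the standard practice for moving counts between incompatible
#' statistical geographies.
#'
#' @param hierarchy an [area_hierarchy()]; populations must be set for
#'   disaggregation.
#' @param source_level,target_level level names (either order).
#' @return An object of class `correspondence`: list with `source_level`,
#'   `target_level`, `source_ids`, `target_ids`, `direction`
#'   (`"aggregate"` or `"disaggregate"`) and sparse share matrix `W`
#'   (rows = source areas).
#' @export
membership_to_correspondence <- function(hierarchy, source_level, target_level) {
  h <- hierarchy
  i <- match(source_level, h$levels); j <- match(target_level, h$levels)
  if (is.na(i) || is.na(j) || i == j) stop("invalid level pair")
  if (i < j) {                         # fine -> coarse: exact aggregation
    anc <- .ancestor_map(h, source_level, target_level)
    sid <- h$ids[[source_level]]; tid <- h$ids[[target_level]]
    W <- Matrix::sparseMatrix(i = seq_along(sid), j = match(anc[sid], tid),
                              x = 1, dims = c(length(sid), length(tid)),
                              dimnames = list(sid, tid))
    direction <- "aggregate"
  } else {                             # coarse -> fine: population shares
    if (is.null(h$pop)) stop("populations required for disaggregation shares")
    anc <- .ancestor_map(h, target_level, source_level)
    sid <- h$ids[[source_level]]; tid <- h$ids[[target_level]]
    pop_t <- rowSums(h$pop[[target_level]])[tid]
    pop_s <- rowSums(h$pop[[source_level]])[sid]
    if (any(pop_s <= 0)) {
      stop("zero total population in source area(s): ",
           paste(utils::head(sid[pop_s <= 0], 5L), collapse = ", "),
           " (disaggregation shares undefined)")
    }
    W <- Matrix::sparseMatrix(i = match(anc[tid], sid), j = seq_along(tid),
                              x = pop_t / pop_s[anc[tid]],
                              dims = c(length(sid), length(tid)),
                              dimnames = list(sid, tid))
    direction <- "disaggregate"
  }
  structure(list(source_level = source_level, target_level = target_level,
                 source_ids = rownames(W), target_ids = colnames(W),
                 direction = direction, W = W),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("correspondence %s -> %s (%s): %d x %d\n", x$source_level,
              x$target_level, x$direction, nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' Transfer counts between levels
#'
#' Computes `target_j = sum_i counts_i * w_ij`.  Because every row of a
#' correspondence sums to one, the grand total is conserved exactly.
#' Disaggregated counts are fractional by default; `integerise = TRUE`
#' instead allocates each source area's (integer) count multinomially
#' across targets with the row shares, preserving integer totals.
#'
#' @param counts numeric vector of non-negative counts, named by or aligned
#'   with the correspondence's source areas.
#' @param corr a [membership_to_correspondence()] object.
#' @param integerise logical; stochastic integer allocation (uses the
#'   current RNG state; set a seed for reproducibility).
#' @return Named numeric vector over target areas.
#' @export
transfer_counts <- function(counts, corr, integerise = FALSE) {
  x <- .align_source(counts, corr)
  if (any(!is.finite(x)) || any(x < 0)) stop("counts must be finite and >= 0")
  if (!integerise) {
    out <- as.vector(Matrix::crossprod(corr$W, x))
  } else {
    if (any(x != round(x))) stop("integerise requires integer counts")
    out <- numeric(length(corr$target_ids))
    W <- corr$W
    for (i in seq_along(x)) {
      if (x[i] == 0) next
      cols <- which(W[i, ] > 0)
      if (length(cols) == 1L) {
        out[cols] <- out[cols] + x[i]
      } else {
        out[cols] <- out[cols] + rmultinom(1L, x[i], as.numeric(W[i, cols]))[, 1L]
      }
    }
  }
  stats::setNames(out, corr$target_ids)
}

#' Transfer an area-level index score between levels
#'
#' Index scores (such as socio-economic disadvantage indices) are not mass
#' quantities, so they are not summed.  Disaggregation copies each source
#' area's score unchanged to its descendants; aggregation takes the
#' population-weighted mean of constituent scores, following the usual
#' statistical-agency recommendation for re-scaling area indices.
#'
#' @param scores numeric vector named by/aligned with the source areas.
#' @param corr a [membership_to_correspondence()] object.
#' @param populations source-level per-area total populations (required for
#'   aggregation; defaults to equal weights if omitted with a warning).
#' @return Named numeric vector over target areas.
#' @export
transfer_score <- function(scores, corr, populations = NULL) {
  s <- .align_source(scores, corr)
  trip <- .triplets(corr$W)
  if (corr$direction == "disaggregate") {
    # each fine area descends from exactly one source area
    src <- integer(length(corr$target_ids))
    src[trip$j] <- trip$i
    return(stats::setNames(s[src], corr$target_ids))
  }
  ind <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = 1,
                              dims = dim(corr$W))
  if (is.null(populations)) {
    warning("no populations supplied; using equal weights for aggregation")
    populations <- rep(1, length(s))
  }
  p <- .align_source(populations, corr)
  num <- as.vector(Matrix::crossprod(ind, p * s))
  den <- as.vector(Matrix::crossprod(ind, p))
  if (any(den <= 0)) stop("zero aggregate population in target area(s)")
  stats::setNames(num / den, corr$target_ids)
}

# triplet (i, j, x) form of a sparse matrix
.triplets <- function(W) {
  T <- methods::as(methods::as(W, "generalMatrix"), "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x)
}

.align_source <- function(x, corr) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), corr$source_ids)) {
      stop("names of input do not match correspondence source areas")
    }
    x <- x[corr$source_ids]
  } else if (length(x) != length(corr$source_ids)) {
    stop("input length does not match number of source areas")
  }
  as.numeric(x)
}

#' Population-weighted quintiles of an area score
#'
#' Areas are sorted by ascending score and cut at cumulative-population
#' fractions 0.2/0.4/0.6/0.8, so each quintile holds about 20% of people
#' rather than 20% of areas.  Quintile 1 (lowest scores) is the most
#' disadvantaged, the usual convention for disadvantage indices, and serves
#' as the regression reference category.  Tied scores share the quintile of
#' the first tied area.  With fewer than five areas some quintiles are
#' necessarily empty (a genuine feature of very coarse aggregations).
#'
#' @param scores finite numeric vector.
#' @param populations non-negative weights, same length.
#' @return Integer vector in `1:5`, same order (and names) as `scores`.
#' @export
assign_quintiles <- function(scores, populations) {
  if (length(scores) < 2L) stop("need at least 2 areas")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(populations) != length(scores)) stop("length mismatch")
  if (length(unique(scores)) == 1L) {
    stop("degenerate covariate: all scores identical")
  }
  ord <- order(scores)
  p <- as.numeric(populations)[ord]
  cum_before <- cumsum(c(0, p[-length(p)])) / sum(p)
  q <- 1L + as.integer(rowSums(outer(cum_before, c(.2, .4, .6, .8), ">=")))
  # ties: first tied element's quintile
  s <- scores[ord]
  q <- stats::ave(q, match(s, s), FUN = function(z) z[1L])
  out <- integer(length(scores))
  out[ord] <- as.integer(q)
  names(out) <- names(scores)
  out
}

#' Read / write correspondence CSV (`source_id,target_id,weight`)
#' @param corr a `correspondence` object.
#' @param path file path.
#' @return `write_correspondence` invisibly returns `path`;
#'   `read_correspondence` returns a `correspondence` with
#'   direction inferred from the weights (unit rows = aggregate).
#' @export
write_correspondence <- function(corr, path) {
  trip <- .triplets(corr$W)
  df <- data.frame(source_id = corr$source_ids[trip$i],
                   target_id = corr$target_ids[trip$j],
                   weight = trip$x)
  utils::write.csv(df[order(df$source_id, df$target_id), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence
#' @param source_level,target_level level names to record on the object.
#' @export
read_correspondence <- function(path, source_level = "source",
                                target_level = "target") {
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric"))
  sid <- sort(unique(df$source_id)); tid <- sort(unique(df$target_id))
  W <- Matrix::sparseMatrix(i = match(df$source_id, sid),
                            j = match(df$target_id, tid), x = df$weight,
                            dims = c(length(sid), length(tid)),
                            dimnames = list(sid, tid))
  rs <- Matrix::rowSums(W)
  if (any(abs(rs - 1) > 1e-9)) stop("correspondence rows must sum to 1")
  direction <- if (all(W@x %in% c(0, 1))) "aggregate" else "disaggregate"
  structure(list(source_level = source_level, target_level = target_level,
                 source_ids = sid, target_ids = tid,
                 direction = direction, W = W),
            class = "correspondence")
}
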