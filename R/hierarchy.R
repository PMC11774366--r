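#' Construct a nested areal hierarchy
#'
#' An `area_hierarchy` holds an ordered set of areal levels (finest first),
#' the areas at each level, the strict child-to-parent nesting between
#' consecutive levels, and optionally per-level adjacency, age-stratified
#' populations and polygon geometry.  It is the container every other
#' module operates on: counts and covariates are moved between its levels
#' by correspondence matrices, and models are fitted per level.
#'
#' @param levels character vector of level names ordered fine to coarse.
#' @param ids named list: for each level, the character vector of area ids.
#' @param membership named list keyed by *child* level name: a named
#'   character vector mapping each child id to its parent id at the next
#'   coarser level.
#' @param adjacency optional named list of [build_adjacency()] objects per
#'   level.
#' @param geometry optional named list (per level) of lists of polygon
#'   coordinate matrices.
#' @return An object of class `area_hierarchy`.
#' @export
area_hierarchy <- function(levels, ids, membership,
                           adjacency = NULL, geometry = NULL) {
  levels <- as.character(levels)
  if (length(levels) < 2L) stop("a hierarchy needs at least two levels")
  if (!setequal(names(ids), levels)) stop("'ids' must be keyed by level name")
  for (lev in levels) {
    if (anyDuplicated(ids[[lev]])) stop("duplicate ids at level ", lev)
  }
  for (k in seq_len(length(levels) - 1L)) {
    child <- levels[k]; parent <- levels[k + 1L]
    m <- membership[[child]]
    if (is.null(m)) stop("missing membership for level ", child)
    if (!setequal(names(m), ids[[child]])) {
      stop("membership for ", child, " must cover exactly its area ids")
    }
    if (!all(m %in% ids[[parent]])) {
      stop("membership for ", child, " references unknown parent ids")
    }
  }
  structure(list(levels = levels, ids = ids,
                 membership = membership[levels[-length(levels)]],
                 adjacency = adjacency, geometry = geometry,
                 pop = NULL),
            class = "area_hierarchy")
}

#' @export
print.area_hierarchy <- function(x, ...) {
  cat("area_hierarchy:", paste(x$levels, collapse = " -> "), "\n")
  for (lev in x$levels) {
    cat(sprintf("  %-8s %6d areas%s\n", lev, length(x$ids[[lev]]),
                if (!is.null(x$pop)) sprintf(", total pop %.0f",
                                             sum(x$pop[[lev]])) else ""))
  }
  invisible(x)
}

#' Attach age-stratified populations to a hierarchy
#'
#' Populations are supplied at the finest level as an areas-by-strata
#' matrix and aggregated upwards by exact summation, so that by construction
#' every parent's population equals the sum of its children's in every age
#' stratum.
#'
#' @param hierarchy an [area_hierarchy()].
#' @param pop_finest numeric matrix, rows named by finest-level area ids,
#'   one column per age stratum; entries non-negative and finite.
#' @return The hierarchy with `$pop`: a named list of population matrices,
#'   one per level.
#' @export
set_population <- function(hierarchy, pop_finest) {
  h <- hierarchy
  finest <- h$levels[1L]
  pop_finest <- as.matrix(pop_finest)
  if (is.null(rownames(pop_finest))) stop("'pop_finest' needs area-id rownames")
  if (!setequal(rownames(pop_finest), h$ids[[finest]])) {
    stop("'pop_finest' rows must match finest-level ids")
  }
  if (any(!is.finite(pop_finest)) || any(pop_finest < 0)) {
    stop("populations must be non-negative and finite")
  }
  pop <- list()
  pop[[finest]] <- pop_finest[h$ids[[finest]], , drop = FALSE]
  for (k in seq_len(length(h$levels) - 1L)) {
    child <- h$levels[k]; parent <- h$levels[k + 1L]
    fac <- factor(h$membership[[child]][h$ids[[child]]],
                  levels = h$ids[[parent]])
    agg <- rowsum(pop[[child]], fac)
    pop[[parent]] <- agg[h$ids[[parent]], , drop = FALSE]
  }
  h$pop <- pop
  h
}

#' Total population per area at a level
#' @param hierarchy an [area_hierarchy()] with populations set.
#' @param level level name.
#' @return Named numeric vector of per-area total populations.
#' @export
level_population <- function(hierarchy, level) {
  if (is.null(hierarchy$pop)) stop("populations not set; see set_population()")
  rowSums(hierarchy$pop[[level]])
}

# ancestor map from a finer to a strictly coarser level, composing the
# stepwise memberships
.ancestor_map <- function(hierarchy, from, to) {
  lv <- hierarchy$levels
  i <- match(from, lv); j <- match(to, lv)
  if (is.na(i) || is.na(j) || i >= j) stop("'from' must be finer than 'to'")
  map <- stats::setNames(hierarchy$ids[[from]], hierarchy$ids[[from]])
  for (k in i:(j - 1L)) map <- hierarchy$membership[[lv[k]]][map]
  stats::setNames(unname(map), hierarchy$ids[[from]])
}

#' Validate hierarchy invariants
#'
#' Checks strict nesting (every child has exactly one parent) and, when
#' populations are attached, the exact conservation of per-stratum
#' populations from each level to the next.
#'
#' @param hierarchy an [area_hierarchy()].
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_hierarchy <- function(hierarchy) {
  h <- hierarchy
  for (k in seq_len(length(h$levels) - 1L)) {
    child <- h$levels[k]; parent <- h$levels[k + 1L]
    m <- h$membership[[child]]
    stopifnot(!anyNA(m[h$ids[[child]]]))
    if (!is.null(h$pop)) {
      fac <- factor(m[h$ids[[child]]], levels = h$ids[[parent]])
      agg <- rowsum(h$pop[[child]], fac)[h$ids[[parent]], , drop = FALSE]
      if (max(abs(agg - h$pop[[parent]])) > 1e-9) {
        stop("population not conserved from ", child, " to ", parent)
      }
    }
  }
  invisible(TRUE)
}

#' Read a membership table
#'
#' CSV with columns `child_id, parent_id, child_level, parent_level`.
#'
#' @param path file path.
#' @return Named list keyed by child level, each a named character vector
#'   child id -> parent id, suitable for [area_hierarchy()].
#' @export
read_membership <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("child_id", "parent_id", "child_level", "parent_level")
  if (!all(need %in% names(df))) stop("membership CSV needs columns: ",
                                      paste(need, collapse = ", "))
  lapply(split(df, df$child_level), function(d) {
    stats::setNames(d$parent_id, d$child_id)
  })
}
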