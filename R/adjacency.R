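#' Build a symmetric binary adjacency structure
#'
#' Constructs the neighbourhood structure `w_ij` used by the CAR prior and
#' by Moran's I: `w_ij = 1` if areas i and j are adjacent, 0 otherwise, with
#' a zero diagonal.  Input is either a set of polygons (one per area) or an
#' explicit edge list.  From polygons, *queen* contiguity declares two areas
#' neighbours when their boundaries share at least one point; *rook*
#' requires a shared boundary segment.  Polygon boundaries are compared
#' through their vertices, which is exact for lattice-aligned geometries
#' such as the grids produced by [make_synthetic_hierarchy()] and the usual
#' GeoJSON exports of administrative boundaries where shared borders repeat
#' the same coordinates.
#'
#' @param ids character vector of area identifiers (defines the area order).
#' @param polygons optional list, parallel to `ids`, of two-column numeric
#'   matrices of polygon ring coordinates.
#' @param edge_list optional two-column matrix or data frame of unordered id
#'   pairs.
#' @param contiguity `"queen"` (default) or `"rook"`; polygons only.
#' @param snap coordinate rounding used when matching polygon vertices.
#' @return An object of class `adjacency`: a list with elements `n`, `ids`,
#'   `nb` (list of integer neighbour indices), `W` (sparse symmetric 0/1
#'   matrix), `n_edges`, `components` (integer component labels) and
#'   `n_components`.  Isolated areas are permitted; their indices are
#'   reported in `isolated`.
#' @examples
#' adj <- build_adjacency(ids = c("a", "b", "c"),
#'                        edge_list = rbind(c("a", "b"), c("b", "c")))
#' adj$n_edges  # 2
#' @export
build_adjacency <- function(ids, polygons = NULL, edge_list = NULL,
                            contiguity = c("queen", "rook"), snap = 1e-8) {
  contiguity <- match.arg(contiguity)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("area ids must be unique")
  if (is.null(polygons) == is.null(edge_list)) {
    stop("supply exactly one of 'polygons' or 'edge_list'")
  }
  if (!is.null(polygons)) {
    edges <- .edges_from_polygons(polygons, contiguity, snap)
  } else {
    edges <- .edges_from_pairs(edge_list, ids)
  }
  new_adjacency(ids, edges)
}

.edges_from_pairs <- function(edge_list, ids) {
  el <- as.matrix(edge_list)
  if (length(el) == 0L) return(matrix(integer(), 0, 2))
  if (ncol(el) != 2L) stop("edge list must have two columns")
  i <- match(as.character(el[, 1]), ids)
  j <- match(as.character(el[, 2]), ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(el[, 1][is.na(i)], el[, 2][is.na(j)]))
    stop("unknown area id(s) in edge list: ", paste(bad, collapse = ", "))
  }
  if (any(i == j)) stop("self-pair in edge list")
  cbind(pmin(i, j), pmax(i, j))
}

.edges_from_polygons <- function(polygons, contiguity, snap) {
  # key every (rounded) vertex of every polygon; queen: areas sharing any
  # vertex; rook: areas sharing an undirected boundary segment
  n <- length(polygons)
  vkey <- function(m) paste(round(m[, 1] / snap), round(m[, 2] / snap))
  if (contiguity == "queen") {
    keys <- lapply(polygons, function(p) unique(vkey(as.matrix(p))))
  } else {
    keys <- lapply(polygons, function(p) {
      m <- as.matrix(p)
      # close the ring if needed, then enumerate undirected segments
      if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
      a <- vkey(m[-nrow(m), , drop = FALSE])
      b <- vkey(m[-1, , drop = FALSE])
      unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
    })
  }
  df <- data.frame(key = unlist(keys),
                   area = rep.int(seq_len(n), lengths(keys)))
  pairs <- do.call(rbind, lapply(split(df$area, df$key), function(a) {
    a <- sort(unique(a))
    if (length(a) < 2L) return(NULL)
    t(utils::combn(a, 2L))
  }))
  if (is.null(pairs)) return(matrix(integer(), 0, 2))
  unique(pairs)
}

#' @rdname build_adjacency
#' @param edges two-column integer matrix of area indices (i, j), i != j.
#' @export
new_adjacency <- function(ids, edges) {
  n <- length(ids)
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n)) {
    stop("edge index out of range")
  }
  nb <- rep(list(integer()), n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
    nb <- lapply(nb, sort)
  }
  W <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n), dimnames = list(ids, ids))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  structure(list(
    n = n, ids = ids, nb = nb, W = W,
    n_edges = nrow(edges),
    components = as.integer(comp),
    n_components = max(comp),
    isolated = which(lengths(nb) == 0L)
  ), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("adjacency: %d areas, %d edges, %d component(s), %d isolated\n",
              x$n, x$n_edges, x$n_components, length(x$isolated)))
  invisible(x)
}

#' Queen or rook adjacency of a rectangular grid
#'
#' @param nrow,ncol grid dimensions; areas are ordered row-major.
#' @param contiguity `"queen"` or `"rook"`.
#' @param ids optional identifiers (default `g1..g{nrow*ncol}`).
#' @return An `adjacency` object.
#' @export
grid_adjacency <- function(nrow, ncol, contiguity = c("queen", "rook"),
                           ids = NULL) {
  contiguity <- match.arg(contiguity)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow * ncol))
  idx <- function(r, c) (r - 1L) * ncol + c
  off <- if (contiguity == "rook") {
    cbind(c(0L, 1L), c(1L, 0L))
  } else {
    cbind(c(0L, 1L, 1L, 1L), c(1L, -1L, 0L, 1L))
  }
  edges <- matrix(integer(), 0, 2)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    r <- rep(seq_len(nrow), each = ncol); c <- rep(seq_len(ncol), nrow)
    ok <- r + dr >= 1 & r + dr <= nrow & c + dc >= 1 & c + dc <= ncol
    edges <- rbind(edges, cbind(idx(r[ok], c[ok]),
                                idx(r[ok] + dr, c[ok] + dc)))
  }
  new_adjacency(ids, edges)
}

#' Read a tab-separated edge list file
#'
#' One `id_i<TAB>id_j` pair per line.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param ids full universe of area ids (areas absent from the file are
#'   isolated).
#' @return An `adjacency` object.
#' @export
read_edge_list <- function(path, ids) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(build_adjacency(ids, edge_list = matrix(character(), 0, 2)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("each line must contain exactly two tab-separated ids")
  build_adjacency(ids, edge_list = do.call(rbind, parts))
}
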