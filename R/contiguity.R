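#' Queen-contiguity neighbour structures
#'
#' A `contiguity_graph` stores an ordered set of area identifiers, the
#' neighbour set of each area, and the weighting convention used when
#' averaging over neighbours. Queen contiguity counts any two areas that
#' share at least one boundary point (a boundary segment or a single vertex)
#' as neighbours.
#'
#' @name contiguity_graph
#' @keywords internal
NULL

new_contiguity_graph <- function(ids, nb, weights = NULL,
                                 weight_scheme = c("equal", "custom")) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(is.character(ids), !anyDuplicated(ids), length(nb) == length(ids))
  names(nb) <- ids
  g <- structure(
    list(ids = ids, nb = nb, weights = weights, weight_scheme = weight_scheme),
    class = "contiguity_graph"
  )
  validate_contiguity_graph(g)
}

validate_contiguity_graph <- function(g) {
  for (i in seq_along(g$ids)) {
    ni <- g$nb[[i]]
    if (any(ni == i)) {
      stop("self-loop at area '", g$ids[i], "'", call. = FALSE)
    }
    for (j in ni) {
      if (!(i %in% g$nb[[j]])) {
        stop("asymmetric adjacency between '", g$ids[i], "' and '",
             g$ids[j], "'", call. = FALSE)
      }
    }
    if (g$weight_scheme == "custom" && length(ni) > 0) {
      wi <- g$weights[[i]]
      if (length(wi) != length(ni) || any(wi < 0) ||
          abs(sum(wi) - 1) > 1e-8) {
        stop("custom weights for area '", g$ids[i],
             "' must be nonnegative and sum to 1", call. = FALSE)
      }
    }
  }
  g
}

#' @export
print.contiguity_graph <- function(x, ...) {
  deg <- lengths(x$nb)
  cat("Queen contiguity graph:", length(x$ids), "areas,",
      sum(deg) / 2, "edges\n")
  cat("  islands:", sum(deg == 0), "  weight scheme:", x$weight_scheme, "\n")
  invisible(x)
}

#' Number of neighbours of each area
#'
#' @param graph a `contiguity_graph`.
#' @return Named integer vector of neighbour counts.
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "contiguity_graph"))
  stats::setNames(lengths(graph$nb), graph$ids)
}

#' Areas with no neighbours
#'
#' @param graph a `contiguity_graph`.
#' @return Character vector of island identifiers.
#' @export
graph_islands <- function(graph) {
  stopifnot(inherits(graph, "contiguity_graph"))
  graph$ids[lengths(graph$nb) == 0]
}

#' Queen contiguity on a regular lattice
#'
#' Builds the queen-contiguity graph of a `rows` by `cols` grid of unit
#' cells: two cells are neighbours when they touch along an edge or at a
#' corner, so interior cells have 8 neighbours, edge cells 5 and corner
#' cells 3.
#'
#' @param rows,cols positive integers, the lattice dimensions.
#' @param ids optional character vector of cell identifiers in row-major
#'   order; defaults to `g<row>_<col>`.
#' @return A `contiguity_graph`.
#' @examples
#' g <- queen_from_grid(3, 3)
#' table(graph_degrees(g))
#' @export
queen_from_grid <- function(rows, cols, ids = NULL) {
  if (length(rows) != 1 || length(cols) != 1 ||
      is.na(rows) || is.na(cols) || rows < 1 || cols < 1 ||
      rows != as.integer(rows) || cols != as.integer(cols)) {
    stop("'rows' and 'cols' must be positive integers", call. = FALSE)
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (is.null(ids)) {
    rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    ids <- sprintf("g%d_%d", rc$row, rc$col)
  }
  stopifnot(length(ids) == n)
  idx <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", n)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      rr <- max(1L, r - 1L):min(rows, r + 1L)
      cc <- max(1L, c - 1L):min(cols, c + 1L)
      cells <- as.vector(outer(rr, cc, idx))
      nb[[idx(r, c)]] <- sort(cells[cells != idx(r, c)])
    }
  }
  new_contiguity_graph(as.character(ids), nb)
}

#' Queen contiguity from an edge list
#'
#' Accepts a precomputed adjacency as pairs of identifiers. Edges are
#' symmetrized and de-duplicated; self-loops are dropped with a warning.
#' The edge list is treated as authoritative: no geometric validation is
#' attempted.
#'
#' @param edges a two-column data frame or matrix of identifier pairs, or a
#'   path to a two-column CSV with a header row.
#' @param nodes character vector of all area identifiers (so that areas with
#'   no edges are retained as islands).
#' @return A `contiguity_graph`.
#' @export
queen_from_edgelist <- function(edges, nodes) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.csv(edges, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list needs two columns", call. = FALSE)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers", call. = FALSE)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  unknown <- setdiff(c(a, b), nodes)
  if (length(unknown) > 0) {
    stop("edge endpoint(s) not in node set: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from edge list", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  ia <- match(a, nodes); ib <- match(b, nodes)
  nb <- rep(list(integer(0)), length(nodes))
  if (length(ia) > 0) {
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    keep <- !duplicated(key)
    ia <- ia[keep]; ib <- ib[keep]
    for (k in seq_along(ia)) {
      nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
      nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  }
  new_contiguity_graph(nodes, nb)
}

# --- polygon path -----------------------------------------------------------

# Squared distance from point p to segment (a, b).
point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sum((p - a)^2))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sum((p - (a + t * ab))^2)
}

# Do segments (p1,p2) and (q1,q2) properly cross?
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Boundary contact test between two polygon coordinate sets within tol.
rings_touch <- function(ringsA, ringsB, tol) {
  tol2 <- (tol + 1e-9)^2
  for (A in ringsA) {
    for (B in ringsB) {
      nA <- nrow(A); nB <- nrow(B)
      # vertex of A near a segment of B (covers shared vertices and edges)
      for (i in seq_len(nA - 1)) {
        p <- A[i, ]
        for (j in seq_len(nB - 1)) {
          if (point_segment_dist2(p, B[j, ], B[j + 1, ]) <= tol2) return(TRUE)
        }
      }
      for (j in seq_len(nB - 1)) {
        q <- B[j, ]
        for (i in seq_len(nA - 1)) {
          if (point_segment_dist2(q, A[i, ], A[i + 1, ]) <= tol2) return(TRUE)
        }
      }
      # proper crossings with no vertex near the other boundary
      for (i in seq_len(nA - 1)) {
        for (j in seq_len(nB - 1)) {
          if (segments_cross(A[i, ], A[i + 1, ], B[j, ], B[j + 1, ])) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

close_ring <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("polygon ring needs at least 3 vertices", call. = FALSE)
  if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

read_geojson_polygons <- function(path, id_property = "area_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  ids <- character(0)
  polys <- list()
  for (f in feats) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing '", id_property, "' property",
                          call. = FALSE)
    geom <- f$geometry
    coords_to_rings <- function(coords) {
      lapply(coords, function(ring) {
        close_ring(do.call(rbind, lapply(ring, function(pt) {
          c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
        })))
      })
    }
    rings <- switch(
      geom$type,
      Polygon = coords_to_rings(geom$coordinates),
      MultiPolygon = unlist(lapply(geom$coordinates, coords_to_rings),
                            recursive = FALSE),
      stop("unsupported geometry type '", geom$type, "' for area '", id, "'",
           call. = FALSE)
    )
    ids <- c(ids, as.character(id))
    polys <- c(polys, list(rings))
  }
  names(polys) <- ids
  polys
}

#' Queen contiguity from area polygons
#'
#' Two areas are neighbours when their boundaries intersect in at least one
#' point (within `tolerance`): a shared boundary segment or a single shared
#' vertex both count. Input is either a named list of polygons (each a
#' coordinate matrix or a list of ring matrices; multipolygons are lists of
#' rings) or a path to a GeoJSON file whose features carry an identifier
#' property.
#'
#' @param polygons named list of polygon coordinates, or a GeoJSON file path.
#' @param tolerance nonnegative contact tolerance in coordinate units;
#'   default 0 (exact shared-point test).
#' @param id_property property name holding the identifier when reading
#'   GeoJSON.
#' @return A `contiguity_graph`.
#' @export
queen_from_polygons <- function(polygons, tolerance = 0,
                                id_property = "area_id") {
  if (is.character(polygons) && length(polygons) == 1) {
    polygons <- read_geojson_polygons(polygons, id_property)
  }
  if (tolerance < 0) stop("'tolerance' must be nonnegative", call. = FALSE)
  ids <- names(polygons)
  if (is.null(ids) || any(ids == "")) {
    stop("polygons must be named by area identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate area identifier: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  rings <- lapply(seq_along(polygons), function(k) {
    p <- polygons[[k]]
    out <- tryCatch({
      if (is.matrix(p) || is.data.frame(p)) list(close_ring(p))
      else lapply(p, close_ring)
    }, error = function(e) {
      stop("invalid geometry for area '", ids[k], "': ",
           conditionMessage(e), call. = FALSE)
    })
    out
  })
  n <- length(ids)
  bbox <- lapply(rings, function(rs) {
    xy <- do.call(rbind, rs)
    c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  })
  nb <- rep(list(integer(0)), n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        bi <- bbox[[i]]; bj <- bbox[[j]]
        if (bi[1] > bj[3] + tolerance || bj[1] > bi[3] + tolerance ||
            bi[2] > bj[4] + tolerance || bj[2] > bi[4] + tolerance) next
        if (rings_touch(rings[[i]], rings[[j]], tolerance)) {
          nb[[i]] <- c(nb[[i]], j)
          nb[[j]] <- c(nb[[j]], i)
        }
      }
    }
  }
  nb <- lapply(nb, sort)
  new_contiguity_graph(ids, nb)
}

#' Spatial lag: weighted mean of neighbour values
#'
#' Computes, for every area, the weighted mean of its neighbours' values
#' (for a deprivation index this is the adjacent locality deprivation, ALD).
#' With the default `equal` scheme the weights are row-standardized binary
#' queen weights, i.e. the simple mean over neighbours. Islands (areas with
#' no neighbours) get `NA` and are reported, never imputed.
#'
#' @param values numeric vector, one value per area, either named by
#'   identifier or aligned with `graph$ids`.
#' @param graph a `contiguity_graph`.
#' @return A list of class `lag_result` with elements `ald` (named numeric,
#'   `NA` for islands) and `islands` (character).
#' @examples
#' g <- queen_from_grid(3, 3)
#' v <- c(9, rep(1, 8))
#' spatial_lag(v, g)$ald
#' @export
spatial_lag <- function(values, graph) {
  stopifnot(inherits(graph, "contiguity_graph"))
  ids <- graph$ids
  if (!is.null(names(values))) {
    missing <- setdiff(ids, names(values))
    if (length(missing) > 0) {
      stop("missing values for area(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    values <- values[ids]
  } else if (length(values) != length(ids)) {
    stop("'values' must have one entry per area", call. = FALSE)
  }
  if (anyNA(values)) stop("'values' contains NA", call. = FALSE)
  ald <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    ni <- graph$nb[[i]]
    if (length(ni) == 0) next
    ald[i] <- if (graph$weight_scheme == "custom") {
      sum(graph$weights[[i]] * values[ni])
    } else {
      mean(values[ni])
    }
  }
  names(ald) <- ids
  structure(list(ald = ald, islands = ids[lengths(graph$nb) == 0]),
            class = "lag_result")
}
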