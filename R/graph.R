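#' Build a spatial neighborhood graph from an edge list
#'
#' Constructs the region adjacency structure underlying the Leroux CAR prior.
#' Edges are symmetrized and deduplicated; self-loops are dropped. Isolated
#' areas (degree zero) are permitted: under the Leroux prior with mixing
#' `rho < 1` their conditional prior is proper, `N(0, sigma2 / (1 - rho))`.
#'
#' @param edge_list a two-column matrix or data frame of area-id pairs
#'   (character), or `NULL` for a graph with no edges.
#' @param area_ids ordered character vector of unique area identifiers.
#' @return An object of class `region_graph`: a list with `area_ids`,
#'   `edges` (integer matrix, one row per undirected edge, indices into
#'   `area_ids` with `i < j`), and `n`.
#' @examples
#' g <- build_graph(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
#' g$n
#' @export
build_graph <- function(edge_list, area_ids) {
  .assert(is.character(area_ids) && length(area_ids) >= 1,
          "area_ids must be a non-empty character vector")
  dup <- unique(area_ids[duplicated(area_ids)])
  .assert(length(dup) == 0, "duplicate area ids: ", paste(dup, collapse = ", "))
  n <- length(area_ids)
  if (is.null(edge_list) || NROW(edge_list) == 0) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    el <- as.matrix(edge_list)
    .assert(ncol(el) == 2, "edge_list must have two columns")
    el <- matrix(as.character(el), ncol = 2)
    unknown <- setdiff(unique(c(el)), area_ids)
    .assert(length(unknown) == 0,
            "unknown area id(s) in edge list: ", paste(unknown, collapse = ", "))
    i <- match(el[, 1], area_ids)
    j <- match(el[, 2], area_ids)
    keep <- i != j   # drop self-loops
    lo <- pmin(i, j)[keep]
    hi <- pmax(i, j)[keep]
    if (length(lo) == 0) {
      edges <- matrix(integer(0), ncol = 2L)
    } else {
      key <- unique(lo * (n + 1) + hi)
      edges <- cbind(as.integer(key %/% (n + 1)), as.integer(key %% (n + 1)))
      edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    }
  }
  structure(list(area_ids = area_ids, edges = edges, n = n),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", x$n, "areas,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Area degrees (neighbor counts)
#' @param graph a `region_graph`.
#' @return Integer vector of neighbor counts, in `area_ids` order.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n)
}

#' Sparse binary adjacency matrix
#' @param graph a `region_graph`.
#' @return A symmetric sparse 0/1 matrix (`Matrix` package) with dimnames
#'   equal to the area ids.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  W <- Matrix::sparseMatrix(
    i = c(graph$edges[, 1], graph$edges[, 2]),
    j = c(graph$edges[, 2], graph$edges[, 1]),
    x = 1, dims = c(graph$n, graph$n),
    dimnames = list(graph$area_ids, graph$area_ids)
  )
  Matrix::drop0(W)
}

#' Leroux CAR precision matrix
#'
#' Computes `Q = (1 / sigma2) * (rho * (D - W) + (1 - rho) * I)` where `W` is
#' the binary adjacency matrix and `D` the diagonal degree matrix. For
#' `rho < 1` the matrix is strictly diagonally dominant, hence positive
#' definite, so the implied Gaussian prior on the spatial field is proper
#' without a sum-to-zero constraint. At `rho = 0` the prior reduces to
#' independent `N(0, sigma2)` effects.
#'
#' @param graph a `region_graph`.
#' @param rho spatial mixing parameter in `[0, 1)`. `rho = 1` (the intrinsic
#'   CAR limit) is only admitted when `unscaled = TRUE`, to inspect the
#'   structure matrix `D - W`.
#' @param sigma2 spatial variance, `> 0`.
#' @param unscaled if `TRUE`, return `rho * (D - W) + (1 - rho) * I` without
#'   the `1 / sigma2` factor.
#' @return A sparse symmetric matrix (class `dsCMatrix`).
#' @examples
#' g <- build_graph(cbind("A", "B"), c("A", "B"))
#' leroux_precision(g, rho = 0.5, sigma2 = 1)
#' @export
leroux_precision <- function(graph, rho, sigma2 = 1, unscaled = FALSE) {
  stopifnot(inherits(graph, "region_graph"))
  rho_max <- if (unscaled) 1 else 1 - .Machine$double.eps
  .assert(is.numeric(rho) && length(rho) == 1 && rho >= 0 && rho <= rho_max,
          "rho must be a single value in [0, 1)")
  .assert(is.numeric(sigma2) && length(sigma2) == 1 && sigma2 > 0,
          "sigma2 must be a single positive value")
  W <- adjacency_matrix(graph)
  D <- Matrix::Diagonal(graph$n, degrees(graph))
  I <- Matrix::Diagonal(graph$n)
  Q <- rho * (D - W) + (1 - rho) * I
  if (!unscaled) Q <- Q / sigma2
  Q <- methods::as(methods::as(Matrix::forceSymmetric(Q), "symmetricMatrix"),
                   "CsparseMatrix")
  dimnames(Q) <- list(graph$area_ids, graph$area_ids)
  Q
}

# ---------------------------------------------------------------------------
# Queen contiguity from GeoJSON polygons.
# Two areas are neighbors iff their polygons share at least one boundary
# point. Detection: shared vertices (within tolerance) or a vertex of one
# polygon lying on a boundary segment of the other; a bounding-box overlap
# prefilter keeps the pairwise scan cheap.
# ---------------------------------------------------------------------------

# rings of a GeoJSON geometry -> list of k x 2 coordinate matrices
.geom_rings <- function(geom) {
  .assert(is.list(geom) && !is.null(geom$type), "invalid geometry")
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    .assert(is.matrix(m) && nrow(m) >= 4 && all(is.finite(m)),
            "invalid geometry: ring with fewer than 4 coordinates")
    m
  }
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, ring_mat)
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop("invalid geometry: unsupported type '", geom$type, "'", call. = FALSE)
  }
}

# does any vertex of pts lie on any segment of rings (within tol)?
.vertex_on_boundary <- function(pts, rings, tol) {
  for (ring in rings) {
    a <- ring[-nrow(ring), , drop = FALSE]
    b <- ring[-1, , drop = FALSE]
    dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
    len2 <- pmax(dx * dx + dy * dy, .Machine$double.xmin)
    for (k in seq_len(nrow(pts))) {
      px <- pts[k, 1]; py <- pts[k, 2]
      t <- pmin(1, pmax(0, ((px - a[, 1]) * dx + (py - a[, 2]) * dy) / len2))
      d2 <- (a[, 1] + t * dx - px)^2 + (a[, 2] + t * dy - py)^2
      if (any(d2 <= tol * tol)) return(TRUE)
    }
  }
  FALSE
}

.polys_touch <- function(rings_a, rings_b, tol) {
  va <- do.call(rbind, rings_a)
  vb <- do.call(rbind, rings_b)
  # fast path: shared vertex (rounded key match)
  key <- function(m) paste(round(m[, 1] / tol), round(m[, 2] / tol))
  if (length(intersect(key(va), key(vb))) > 0) return(TRUE)
  # slow path: vertex-on-segment in either direction
  .vertex_on_boundary(va, rings_b, tol) || .vertex_on_boundary(vb, rings_a, tol)
}

#' Queen-contiguity graph from GeoJSON polygons
#'
#' Two areas are treated as neighbors iff their polygons share at least one
#' boundary point (queen contiguity), detected via shared vertices or a
#' vertex of one polygon lying on a boundary segment of the other. This is
#' exact for administrative boundary files, where touching polygons share
#' vertices.
#'
#' @param x path to a GeoJSON file, a GeoJSON string, or an already-parsed
#'   FeatureCollection (as returned by [jsonlite::fromJSON] with
#'   `simplifyVector = FALSE`).
#' @param id_property name of the feature property holding the area id.
#' @param tol coordinate tolerance for point coincidence.
#' @return A `region_graph` over the feature ids, in file order.
#' @export
contiguity_from_polygons <- function(x, id_property = "area_id", tol = 1e-9) {
  fc <- .parse_geojson(x)
  feats <- fc$features
  .assert(length(feats) >= 1, "FeatureCollection has no features")
  ids <- vapply(feats, function(f) {
    v <- f$properties[[id_property]]
    .assert(!is.null(v), "feature missing id property '", id_property, "'")
    as.character(v)
  }, character(1))
  dup <- unique(ids[duplicated(ids)])
  .assert(length(dup) == 0, "duplicate area ids: ", paste(dup, collapse = ", "))
  rings <- lapply(feats, function(f) .geom_rings(f$geometry))
  bbox <- t(vapply(rings, function(r) {
    v <- do.call(rbind, r)
    c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  }, numeric(4)))
  n <- length(ids)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (bbox[i, 1] > bbox[j, 2] + tol || bbox[j, 1] > bbox[i, 2] + tol ||
          bbox[i, 3] > bbox[j, 4] + tol || bbox[j, 3] > bbox[i, 4] + tol) next
      if (.polys_touch(rings[[i]], rings[[j]], tol)) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  build_graph(cbind(ids[from], ids[to]), ids)
}

.parse_geojson <- function(x) {
  if (is.list(x)) {
    fc <- x
  } else {
    .assert(is.character(x) && length(x) == 1, "expected a path, string or list")
    fc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  .assert(identical(fc$type, "FeatureCollection"),
          "input is not a GeoJSON FeatureCollection")
  fc
}
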