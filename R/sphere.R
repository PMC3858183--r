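#' Orientation tessellations on the unit sphere
#'
#' Spin distribution functions and orientation distribution functions are
#' sampled on a discrete set of unit vectors.  The standard construction is
#' a subdivided icosahedron re-projected onto the sphere ("icosphere"),
#' which is antipodally symmetric and yields `10 * 4^k + 2` vertices at
#' subdivision level `k` (level 3 gives the common 642-direction set).
#'
#' @name sphere_tessellation
NULL

# Icosahedron vertices, unit-normalized. Antipodally symmetric by
# construction: vertex i and its antipode appear as a +/- pair.
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(1 + phi^2)  # all rows have equal norm
}

.icosahedron_faces <- function(v) {
  # faces = triangles of mutually adjacent vertices; adjacency by the
  # minimal pairwise distance among distinct vertices
  d <- as.matrix(dist(v))
  edge_len <- min(d[d > 1e-9])
  adj <- d < edge_len + 1e-6 & d > 1e-9
  faces <- list()
  n <- nrow(v)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k])
      faces[[length(faces) + 1L]] <- c(i, j, k)
  }
  do.call(rbind, faces)
}

#' Build an icosphere orientation tessellation
#'
#' Constructs the full-sphere vertex set by `subdivision_level` rounds of
#' edge-midpoint subdivision of an icosahedron, re-projecting each new
#' vertex to the unit sphere, together with the triangulation, the 1-ring
#' adjacency of every vertex, and the antipodal pairing used to evaluate
#' symmetric functions on one hemisphere only.
#'
#' @param subdivision_level Non-negative integer number of subdivision
#'   rounds; level 0 is the icosahedron (12 vertices), level 3 yields 642
#'   vertices. Capped at 6.
#' @return An object of class `sphere_tess`: a list with `vertices`
#'   (n x 3 matrix of unit vectors), `faces`, `edges`, `adjacency` (list of
#'   integer 1-ring neighbour vectors), `antipode` (index of -v for each
#'   v), `hemi_vertices` (indices of the hemisphere representatives),
#'   `hemi_index` (map from every vertex to its representative's slot),
#'   `n_vertices`, and `level`.
#' @examples
#' tess <- build_tessellation(2)
#' tess$n_vertices            # 162
#' angular_resolution(tess)   # mean adjacent-vertex arc, degrees
#' @export
build_tessellation <- function(subdivision_level) {
  if (length(subdivision_level) != 1L || is.na(subdivision_level) ||
      subdivision_level < 0 || subdivision_level != round(subdivision_level))
    stop("subdivision_level must be a single non-negative integer")
  if (subdivision_level > 6)
    stop("subdivision_level > 6 not supported")
  v <- .icosahedron()
  f <- .icosahedron_faces(v)
  lev <- 0L
  while (lev < subdivision_level) {
    res <- .subdivide_once(v, f)
    v <- res$vertices
    f <- res$faces
    lev <- lev + 1L
  }
  .finish_tessellation(v, f, as.integer(subdivision_level))
}

# one round of midpoint subdivision with re-projection to the sphere
.subdivide_once <- function(v, f) {
  n <- nrow(v)
  midpoint_id <- new.env(hash = TRUE)
  verts <- vector("list", n)
  for (i in seq_len(n)) verts[[i]] <- v[i, ]
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- midpoint_id[[key]]
    if (!is.null(id)) return(id)
    m <- verts[[a]] + verts[[b]]
    m <- m / sqrt(sum(m^2))
    id <- length(verts) + 1L
    verts[[id]] <<- m
    midpoint_id[[key]] <- id
    id
  }
  nf <- vector("list", 4L * nrow(f))
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
    nf[[4 * t - 3]] <- c(a, ab, ca)
    nf[[4 * t - 2]] <- c(b, bc, ab)
    nf[[4 * t - 1]] <- c(cc, ca, bc)
    nf[[4 * t]]     <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, nf))
}

.finish_tessellation <- function(v, f, level) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  adjacency <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    a <- e[r, 1]; b <- e[r, 2]
    adjacency[[a]] <- c(adjacency[[a]], b)
    adjacency[[b]] <- c(adjacency[[b]], a)
  }
  adjacency <- lapply(adjacency, function(x) sort(unique(as.integer(x))))
  antipode <- .match_antipodes(v)
  # hemisphere representatives: z > 0, ties broken on y then x
  is_rep <- v[, 3] > 1e-9 |
    (abs(v[, 3]) <= 1e-9 & (v[, 2] > 1e-9 |
       (abs(v[, 2]) <= 1e-9 & v[, 1] > 0)))
  hemi_vertices <- which(is_rep)
  hemi_index <- integer(n)
  hemi_index[hemi_vertices] <- seq_along(hemi_vertices)
  hemi_index[antipode[hemi_vertices]] <- seq_along(hemi_vertices)
  structure(list(
    vertices = v, faces = f, edges = e, adjacency = adjacency,
    antipode = antipode, hemi_vertices = hemi_vertices,
    hemi_index = hemi_index, n_vertices = n, level = level),
    class = "sphere_tess")
}

.match_antipodes <- function(v) {
  # pair each vertex with the vertex closest to -v; construction keeps
  # the set exactly antipodally symmetric so the match is essentially exact
  antipode <- apply(v %*% t(v), 1, which.min)
  err <- sqrt(rowSums((v + v[antipode, , drop = FALSE])^2))
  if (any(err > 1e-9))
    stop("tessellation is not antipodally symmetric")
  as.integer(antipode)
}

#' Angular resolution of a tessellation
#'
#' The arc angle between edge-connected vertices summarises how finely the
#' sphere is sampled; the mean over all edges is reported as the angular
#' resolution (the maximum is also available).
#'
#' @param tess A `sphere_tess` object.
#' @param method `"mean"` (default) or `"max"` over all tessellation edges.
#' @return Angle in degrees.
#' @export
angular_resolution <- function(tess, method = c("mean", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(tess, "sphere_tess"))
  a <- .edge_angles_deg(tess)
  if (method == "mean") mean(a) else max(a)
}

.edge_angles_deg <- function(tess) {
  v <- tess$vertices
  d <- rowSums(v[tess$edges[, 1], , drop = FALSE] *
               v[tess$edges[, 2], , drop = FALSE])
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Export a tessellation as plain-text vertex and edge tables
#'
#' @param tess A `sphere_tess` object.
#' @param vertex_path,edge_path Output paths for whitespace-separated
#'   tables (vertex coordinates; 1-based edge index pairs).
#' @return Invisibly, `NULL`.
#' @export
write_tessellation <- function(tess, vertex_path, edge_path) {
  stopifnot(inherits(tess, "sphere_tess"))
  utils::write.table(tess$vertices, vertex_path, row.names = FALSE,
                     col.names = c("x", "y", "z"))
  utils::write.table(tess$edges, edge_path, row.names = FALSE,
                     col.names = c("a", "b"))
  invisible(NULL)
}

#' @export
print.sphere_tess <- function(x, ...) {
  cat(sprintf(
    "Icosphere tessellation: level %d, %d vertices (%d hemisphere), %d edges\n",
    x$level, x$n_vertices, length(x$hemi_vertices), nrow(x$edges)))
  cat(sprintf("  angular resolution (mean adjacent arc): %.2f deg\n",
              angular_resolution(x)))
  invisible(x)
}
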