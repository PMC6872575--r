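# 3D Delaunay tetrahedralization by incremental (Bowyer-Watson) insertion.
# Returns a list with `tetra` (m x 4 vertex indices into `pts`); degenerate
# inputs (< 4 points, coplanar) return zero tetrahedra.
delaunay3d <- function(pts, seed = 1L) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4L) return(list(tetra = matrix(integer(0), 0, 4)))
  ctr <- colMeans(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  w <- sweep(sweep(pts, 2, ctr), 2, rep(scale, 3), "/")
  # coplanarity check via SVD of centred coordinates
  sv <- svd(w)$d
  if (sv[3] < 1e-10 * max(sv[1], 1e-300))
    return(list(tetra = matrix(integer(0), 0, 4)))
  C <- 1e3
  super <- rbind(c(C, C, C), c(C, -C, -C), c(-C, C, -C), c(-C, -C, C))
  W <- rbind(w, super)
  tet <- matrix(n + 1:4, 1, 4)
  cc <- matrix(0, 1, 3)
  r2 <- numeric(1)
  circ <- circumsphere(W[tet[1, ], ])
  cc[1, ] <- circ$c
  r2[1] <- circ$r2
  alive <- TRUE
  # deterministic scrambled insertion order (no global RNG use)
  ord <- order((seq_len(n) * 2654435761) %% 4294967296)
  for (p in ord) {
    pw <- W[p, ]
    d2 <- (cc[, 1] - pw[1])^2 + (cc[, 2] - pw[2])^2 + (cc[, 3] - pw[3])^2
    bad <- which(alive & d2 < r2 * (1 + 1e-12))
    if (length(bad) == 0L) {
      # numerical fallback: use the nearest circumsphere
      bad <- which.min(ifelse(alive, d2 - r2, Inf))
    }
    faces <- matrix(0L, 4L * length(bad), 3)
    k <- 0L
    for (b in bad) {
      v <- tet[b, ]
      faces[k + 1L, ] <- sort(v[-1])
      faces[k + 2L, ] <- sort(v[-2])
      faces[k + 3L, ] <- sort(v[-3])
      faces[k + 4L, ] <- sort(v[-4])
      k <- k + 4L
    }
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    boundary <- faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[bad] <- FALSE
    nb <- nrow(boundary)
    if (nb > 0L) {
      newt <- cbind(boundary, p)
      newc <- matrix(0, nb, 3)
      newr <- numeric(nb)
      for (i in seq_len(nb)) {
        circ <- circumsphere(W[newt[i, ], ])
        newc[i, ] <- circ$c
        newr[i] <- circ$r2
      }
      tet <- rbind(tet, newt)
      cc <- rbind(cc, newc)
      r2 <- c(r2, newr)
      alive <- c(alive, rep(TRUE, nb))
    }
    if (length(alive) > 500L && mean(alive) < 0.5) {
      tet <- tet[alive, , drop = FALSE]
      cc <- cc[alive, , drop = FALSE]
      r2 <- r2[alive]
      alive <- rep(TRUE, nrow(tet))
    }
  }
  keep <- alive & apply(tet <= n, 1, all)
  list(tetra = tet[keep, , drop = FALSE])
}

# circumcentre and squared circumradius of a tetrahedron (4 x 3 matrix);
# flat tetrahedra get an infinite radius so they never survive alpha filtering
circumsphere <- function(v) {
  a <- v[1, ]
  M <- 2 * sweep(v[2:4, , drop = FALSE], 2, a)
  rhs <- rowSums(v[2:4, , drop = FALSE]^2) - sum(a^2)
  ctr <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(ctr) || anyNA(ctr) || any(!is.finite(ctr)))
    return(list(c = c(Inf, Inf, Inf), r2 = Inf))
  list(c = as.numeric(ctr), r2 = sum((a - ctr)^2))
}

tetra_volume <- function(pts, tet) {
  if (nrow(tet) == 0L) return(numeric(0))
  a <- pts[tet[, 1], , drop = FALSE]
  u <- pts[tet[, 2], , drop = FALSE] - a
  v <- pts[tet[, 3], , drop = FALSE] - a
  w <- pts[tet[, 4], , drop = FALSE] - a
  abs(u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Alpha-shape volume and surface of a 3D point set
#'
#' Delaunay-tetrahedralizes the points (incremental insertion) and keeps the
#' tetrahedra whose circumsphere radius is strictly less than `alpha`; the
#' alpha-shape volume is the sum of the kept tetra volumes and the surface
#' area the sum of the boundary-face areas (faces belonging to exactly one
#' kept tetrahedron). For alpha above the largest circumradius this recovers
#' the convex hull. Applied to nucleus centroids it yields the approximate
#' spheroid volume and surface of an organoid.
#'
#' @param centroids n x 3 matrix of points (e.g. `(z, y, x)` centroids in
#'   voxels).
#' @param alpha circumsphere radius threshold (default 240 voxels).
#' @return An `alpha_shape_result`: list with `alpha`, `volume`,
#'   `surface_area`, `n_tetrahedra`, `boundary_faces`.
#' @export
#' @examples
#' tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' compute_alpha_shape(tet, alpha = 1000)$volume  # 1/6
compute_alpha_shape <- function(centroids, alpha = 240) {
  pts <- as.matrix(centroids)
  if (ncol(pts) != 3L) stop("`centroids` must be an n x 3 matrix")
  zero <- structure(list(alpha = alpha, volume = 0, surface_area = 0,
                         n_tetrahedra = 0L, boundary_faces = 0L),
                    class = "alpha_shape_result")
  dt <- delaunay3d(pts)
  if (nrow(dt$tetra) == 0L) {
    warning("fewer than 4 points or degenerate (coplanar) input; zero-volume alpha shape")
    return(zero)
  }
  rad <- apply(dt$tetra, 1, function(t) sqrt(circumsphere(pts[t, ])$r2))
  keep <- dt$tetra[rad < alpha, , drop = FALSE]
  if (nrow(keep) == 0L) return(zero)
  vol <- sum(tetra_volume(pts, keep))
  faces <- rbind(keep[, -1, drop = FALSE], keep[, -2, drop = FALSE],
                 keep[, -3, drop = FALSE], keep[, -4, drop = FALSE])
  faces <- t(apply(faces, 1, sort))
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  boundary <- faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  area <- 0
  if (nrow(boundary) > 0L) {
    u <- pts[boundary[, 2], , drop = FALSE] - pts[boundary[, 1], , drop = FALSE]
    v <- pts[boundary[, 3], , drop = FALSE] - pts[boundary[, 1], , drop = FALSE]
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area <- sum(sqrt(rowSums(cr^2))) / 2
  }
  structure(list(alpha = alpha, volume = vol, surface_area = area,
                 n_tetrahedra = nrow(keep),
                 boundary_faces = nrow(boundary)),
            class = "alpha_shape_result")
}

#' @export
print.alpha_shape_result <- function(x, ...) {
  cat(sprintf(
    "<alpha_shape> alpha %g: volume %.6g, surface %.6g, %d tetrahedra, %d boundary faces\n",
    x$alpha, x$volume, x$surface_area, x$n_tetrahedra, x$boundary_faces))
  invisible(x)
}

#' Cell graph over nucleus centroids
#'
#' Connects every pair of centroids at Euclidean distance at most
#' `edge_threshold` and removes outlier nodes: nodes with no edge whose
#' nearest-neighbour distance also exceeds `outlier_distance` (a node that
#' participates in an edge is never an outlier, so two nuclei 59 voxels
#' apart under the default 60/55 thresholds form an edge and stay). The
#' per-node degree serves as a local cell density proxy.
#'
#' @param centroids n x 3 matrix of points, pairwise distinct.
#' @param edge_threshold maximal edge length (default 60 voxels).
#' @param outlier_distance maximal nearest-neighbour distance beyond which
#'   an isolated node is discarded as an outlier (default 55 voxels).
#' @return A `cell_graph`: list with `nodes` (indices of retained nodes),
#'   `edges` (m x 2 matrix of node indices, i < j), `outliers`, `degree`
#'   (named by node index) and the thresholds.
#' @export
build_cell_graph <- function(centroids, edge_threshold = 60,
                             outlier_distance = 55) {
  pts <- as.matrix(centroids)
  n <- nrow(pts)
  if (n == 0L)
    return(structure(list(nodes = integer(0),
                          edges = matrix(integer(0), 0, 2),
                          outliers = integer(0), degree = integer(0),
                          edge_threshold = edge_threshold,
                          outlier_distance = outlier_distance),
                     class = "cell_graph"))
  dd <- as.matrix(dist(pts))
  diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  isolated <- if (n == 1L) TRUE else apply(dd > edge_threshold, 1, all)
  outliers <- unname(which(isolated & nn > outlier_distance))
  nodes <- setdiff(seq_len(n), outliers)
  edges <- matrix(integer(0), 0, 2)
  if (length(nodes) > 1L) {
    sub <- dd[nodes, nodes, drop = FALSE]
    hit <- which(upper.tri(sub) & sub <= edge_threshold, arr.ind = TRUE)
    edges <- cbind(nodes[hit[, 1]], nodes[hit[, 2]])
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  degree <- integer(length(nodes))
  names(degree) <- nodes
  if (nrow(edges) > 0L) {
    tb <- table(factor(c(edges[, 1], edges[, 2]), levels = nodes))
    degree <- as.integer(tb)
    names(degree) <- nodes
  }
  structure(list(nodes = nodes, edges = edges, outliers = outliers,
                 degree = degree, edge_threshold = edge_threshold,
                 outlier_distance = outlier_distance),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d edges, %d outliers (edge <= %g, outlier > %g)\n",
              length(x$nodes), nrow(x$edges), length(x$outliers),
              x$edge_threshold, x$outlier_distance))
  invisible(x)
}

#' Nuclei volume distribution
#'
#' Histogram and summary of the per-nucleus physical volumes, supporting the
#' comparison of median nuclei volumes between organoids.
#'
#' @param records feature data frame (see [nucleus_records()]).
#' @param binwidth histogram bin width in um^3 (default 50).
#' @return A list with `histogram` (data frame: `mid`, `count`), `median`,
#'   `q1`, `q3` and `n`. For empty input the summaries are `NA` and a
#'   warning is raised.
#' @export
nuclei_volume_distribution <- function(records, binwidth = 50) {
  if (!is.data.frame(records) || !"volume_um3" %in% names(records))
    stop("`records` must contain a `volume_um3` column")
  v <- records$volume_um3
  if (length(v) == 0L) {
    warning("no records: median undefined")
    return(list(histogram = data.frame(mid = numeric(0), count = integer(0)),
                median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0L))
  }
  lo <- binwidth * floor(min(v) / binwidth)
  hi <- binwidth * ceiling(max(v) / binwidth)
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- hist(v, breaks = breaks, plot = FALSE, right = FALSE)
  list(histogram = data.frame(mid = h$mids, count = h$counts),
       median = median(v),
       q1 = as.numeric(quantile(v, 0.25)),
       q3 = as.numeric(quantile(v, 0.75)),
       n = length(v))
}
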