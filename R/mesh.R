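# Tissue label codes used on disk (VTK "label" cell array) and in memory.
TISSUE_LEVELS <- c("BULK", "PV", "LAA", "MVR", "BB", "FO", "LESION")
TISSUE_CODES <- stats::setNames(seq_along(TISSUE_LEVELS) - 1L, TISSUE_LEVELS)

# Remodeled-substrate defaults: longitudinal conductivity 8.9 mS/m with a
# 10:1 longitudinal:transverse anisotropy ratio.
DEFAULT_SIGMA_L <- 8.9
DEFAULT_ANISOTROPY <- 10

#' Construct a triangulated surface mesh
#'
#' The central geometry container: node coordinates in mm, triangle
#' connectivity, a per-element fiber direction, a per-element tissue label,
#' and per-element longitudinal/transverse monodomain conductivities in mS/m.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param elements integer matrix, m x 3, 1-based node indices per triangle.
#' @param fiber numeric matrix, m x 3, unit fiber direction per element.
#'   Defaults to the (normalised) first edge of each element.
#' @param label character vector of length m with values from
#'   \code{c("BULK","PV","LAA","MVR","BB","FO","LESION")}; default "BULK".
#' @param sigma_l,sigma_t numeric vectors of length m, conductivities in
#'   mS/m. Default: 8.9 mS/m longitudinal with a 10:1 anisotropy ratio.
#' @return an object of class \code{rb_mesh}.
#' @export
rb_mesh <- function(nodes, elements, fiber = NULL, label = NULL,
                    sigma_l = NULL, sigma_t = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) == 2) nodes <- cbind(nodes, 0)
  stopifnot(ncol(nodes) == 3)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(elements) == 3)
  dimnames(nodes) <- NULL
  dimnames(elements) <- NULL
  n <- nrow(nodes); m <- nrow(elements)
  if (any(elements < 1L) || any(elements > n))
    stop("mesh format error: element references node outside 1..", n)
  if (is.null(fiber)) {
    e1 <- nodes[elements[, 2], , drop = FALSE] - nodes[elements[, 1], , drop = FALSE]
    fiber <- e1 / sqrt(rowSums(e1^2))
  }
  fiber <- as.matrix(fiber)
  dimnames(fiber) <- NULL
  if (is.null(label)) label <- rep("BULK", m)
  label <- as.character(label)
  if (!all(label %in% TISSUE_LEVELS))
    stop("mesh format error: unknown tissue label(s): ",
         paste(setdiff(unique(label), TISSUE_LEVELS), collapse = ", "))
  if (is.null(sigma_l)) sigma_l <- rep(DEFAULT_SIGMA_L, m)
  if (is.null(sigma_t)) sigma_t <- rep(DEFAULT_SIGMA_L / DEFAULT_ANISOTROPY, m)
  sigma_l <- rep_len(as.numeric(sigma_l), m)
  sigma_t <- rep_len(as.numeric(sigma_t), m)
  mesh <- structure(list(nodes = nodes, elements = elements, fiber = fiber,
                         label = label, sigma_l = sigma_l, sigma_t = sigma_t),
                    class = "rb_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  m <- nrow(mesh$elements)
  stopifnot(nrow(mesh$fiber) == m, length(mesh$label) == m,
            length(mesh$sigma_l) == m, length(mesh$sigma_t) == m)
  nrm <- sqrt(rowSums(mesh$fiber^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("mesh format error: fiber directions must be unit vectors")
  if (any(mesh$sigma_l < 0) || any(mesh$sigma_t < 0))
    stop("mesh format error: negative conductivity")
  if (any(mesh$sigma_t > mesh$sigma_l + 1e-12))
    stop("mesh format error: sigma_t exceeds sigma_l")
  les <- mesh$label == "LESION"
  if (any(mesh$sigma_l[les] != 0) || any(mesh$sigma_t[les] != 0))
    stop("mesh format error: LESION elements must have zero conductivity")
  invisible(mesh)
}

#' @export
print.rb_mesh <- function(x, ...) {
  cat("<rb_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements), " triangles\n",
      sep = "")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$label)),
                                 as.integer(table(x$label))), collapse = " "), "\n")
  cat("  sigma_l [mS/m]: ", paste(format(range(x$sigma_l)), collapse = " .. "),
      "; sigma_t: ", paste(format(range(x$sigma_t)), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Element centroids of a mesh
#' @param mesh an \code{rb_mesh}.
#' @return m x 3 matrix of centroid coordinates (mm).
#' @export
mesh_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1], , drop = FALSE] +
   mesh$nodes[mesh$elements[, 2], , drop = FALSE] +
   mesh$nodes[mesh$elements[, 3], , drop = FALSE]) / 3
}

#' Element areas of a mesh
#' @param mesh an \code{rb_mesh}.
#' @return numeric vector of triangle areas (mm^2).
#' @export
mesh_areas <- function(mesh) {
  a <- mesh$nodes[mesh$elements[, 1], , drop = FALSE]
  u <- mesh$nodes[mesh$elements[, 2], , drop = FALSE] - a
  v <- mesh$nodes[mesh$elements[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# Median edge length; used as the mesh-resolution scale in tolerances.
mesh_edge_length <- function(mesh) {
  el <- mesh$elements
  p <- mesh$nodes
  d <- function(i, j) sqrt(rowSums((p[el[, i], , drop = FALSE] -
                                    p[el[, j], , drop = FALSE])^2))
  stats::median(c(d(1, 2), d(2, 3), d(3, 1)))
}

# Undirected edge list (2-column matrix of node indices, i < j), unique.
mesh_edges <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Element adjacency over shared edges: list of integer vectors per element.
element_adjacency <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  e <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  eid <- rep(seq_len(m), 3)
  sp <- split(eid, key)
  adj <- vector("list", m)
  for (grp in sp) {
    if (length(grp) < 2) next
    for (a in grp) adj[[a]] <- c(adj[[a]], setdiff(grp, a))
  }
  adj
}

# Connected components of a subset of elements (edge connectivity).
# Returns integer component id per member of `which_elems`.
element_components <- function(mesh, which_elems) {
  idx <- which(which_elems)
  if (length(idx) == 0) return(integer(0))
  adj <- element_adjacency(mesh)
  comp <- rep(NA_integer_, nrow(mesh$elements))
  cid <- 0L
  for (s in idx) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[which_elems[nb] & is.na(comp[nb])]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp[idx]
}

# Boundary edges (edges used by exactly one triangle).
mesh_boundary_edges <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  single <- names(tab)[tab == 1]
  e[key %in% single, , drop = FALSE]
}
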