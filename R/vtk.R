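# Legacy ASCII VTK I/O for triangulated meshes.
#
# Only the subset used by the package is supported: DATASET POLYDATA
# (POLYGONS) or UNSTRUCTURED_GRID (CELLS + CELL_TYPES, triangles only),
# with optional CELL_DATA arrays "fiber" (VECTORS), "label" (SCALARS int),
# "sigma_l"/"sigma_t" (SCALARS float), and optional POINT_DATA scalars.

#' Save a mesh as legacy ASCII VTK
#'
#' Writes POLYDATA with cell-data arrays \code{fiber}, \code{label},
#' \code{sigma_l} and \code{sigma_t}; optional named point-data scalar
#' vectors are appended as POINT_DATA (used for density and phase exports).
#'
#' @param mesh an \code{rb_mesh}.
#' @param path output file path.
#' @param point_data optional named list of per-node numeric vectors.
#' @export
save_mesh <- function(mesh, path, point_data = NULL) {
  validate_mesh(mesh)
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("rotorbench surface mesh")
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS ", n, " float")
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  wl("POLYGONS ", m, " ", 4L * m)
  writeLines(paste(3L, mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
                   mesh$elements[, 3] - 1L), con)
  wl("CELL_DATA ", m)
  wl("VECTORS fiber float")
  writeLines(apply(format(mesh$fiber, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  wl("SCALARS label int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(TISSUE_CODES[mesh$label]), con)
  wl("SCALARS sigma_l float 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(mesh$sigma_l, digits = 17, trim = TRUE, scientific = FALSE), con)
  wl("SCALARS sigma_t float 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(mesh$sigma_t, digits = 17, trim = TRUE, scientific = FALSE), con)
  if (!is.null(point_data)) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) {
      wl("SCALARS ", nm, " float 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(as.numeric(point_data[[nm]]), digits = 17, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Load a mesh from legacy ASCII VTK
#'
#' Accepts POLYDATA or UNSTRUCTURED_GRID datasets with triangle cells.
#' Missing cell-data arrays are filled with documented defaults: BULK
#' labels, the remodeled bulk conductivities (8.9 mS/m, 10:1 anisotropy),
#' and fibers along each element's first edge.
#'
#' @param path file path to a legacy ASCII VTK file.
#' @return an \code{rb_mesh}.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh format error: cannot read '", path, "'")
  raw <- readLines(path, warn = FALSE)
  # drop the two header lines and comments, tokenize the rest
  body <- raw[-(1:2)]
  toks <- scan(text = paste(body, collapse = "\n"), what = "character",
               quiet = TRUE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(k = 1L) {
    if (pos + k - 1L > length(toks))
      stop("mesh format error: truncated file at token ", pos)
    out <- toks[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  take_num <- function(k) {
    v <- suppressWarnings(as.numeric(take(k)))
    if (anyNA(v)) stop("mesh format error: non-numeric value where number expected")
    v
  }
  if (!identical(take(), "ASCII"))
    stop("mesh format error: only ASCII legacy VTK is supported")
  take()  # DATASET
  dstype <- take()
  if (!dstype %in% c("POLYDATA", "UNSTRUCTURED_GRID"))
    stop("mesh format error: unsupported dataset type ", dstype)

  nodes <- NULL; elements <- NULL
  m <- 0L
  fiber <- NULL; label <- NULL; sigma_l <- NULL; sigma_t <- NULL
  while (!is.na(peek())) {
    kw <- take()
    if (kw == "POINTS") {
      n <- as.integer(take()); take()  # dtype
      nodes <- matrix(take_num(3L * n), ncol = 3, byrow = TRUE)
    } else if (kw == "POLYGONS") {
      m <- as.integer(take()); total <- as.integer(take())
      dat <- as.integer(take_num(total))
      elements <- parse_cell_list(dat, m, "POLYGONS")
    } else if (kw == "CELLS") {
      m <- as.integer(take()); total <- as.integer(take())
      dat <- as.integer(take_num(total))
      elements <- parse_cell_list(dat, m, "CELLS")
    } else if (kw == "CELL_TYPES") {
      k <- as.integer(take())
      types <- as.integer(take_num(k))
      if (any(types != 5L))
        stop("mesh format error: CELL_TYPES contains non-triangle cells")
    } else if (kw == "CELL_DATA" || kw == "POINT_DATA") {
      nrec <- as.integer(take())
      is_cell <- kw == "CELL_DATA"
      while (!is.na(peek()) && peek() %in% c("SCALARS", "VECTORS")) {
        akw <- take(); aname <- take(); take()  # dtype
        if (akw == "SCALARS") {
          if (!is.na(peek()) && peek() == "1") take()
          if (!is.na(peek()) && peek() == "LOOKUP_TABLE") take(2L)
          vals <- take_num(nrec)
          if (is_cell && aname == "label") label <- vals
          if (is_cell && aname == "sigma_l") sigma_l <- vals
          if (is_cell && aname == "sigma_t") sigma_t <- vals
        } else {
          vals <- matrix(take_num(3L * nrec), ncol = 3, byrow = TRUE)
          if (is_cell && aname == "fiber") fiber <- vals
        }
      }
    } else {
      stop("mesh format error: unexpected record '", kw, "'")
    }
  }
  if (is.null(nodes) || is.null(elements))
    stop("mesh format error: file lacks POINTS or cells")
  if (!is.null(label)) {
    if (!all(label %in% TISSUE_CODES))
      stop("mesh format error: unknown label code(s) in 'label' array")
    label <- names(TISSUE_CODES)[match(label, TISSUE_CODES)]
  }
  rb_mesh(nodes, elements, fiber = fiber, label = label,
          sigma_l = sigma_l, sigma_t = sigma_t)
}

parse_cell_list <- function(dat, m, what) {
  out <- matrix(0L, m, 3)
  i <- 1L
  for (e in seq_len(m)) {
    if (i > length(dat)) stop("mesh format error: truncated ", what, " record")
    k <- dat[i]
    if (k != 3L)
      stop("mesh format error: ", what, " cell ", e, " has ", k,
           " vertices (triangles required)")
    out[e, ] <- dat[(i + 1L):(i + 3L)] + 1L
    i <- i + 4L
  }
  out
}
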