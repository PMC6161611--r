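# Mesh container, VTK round trips, and lesion geometry.

test_that("sheet construction arithmetic and defaults", {
  m <- make_sheet(100, 100, 1)
  expect_equal(nrow(m$nodes), 10000)
  expect_equal(as.numeric(apply(m$nodes, 2, max) - apply(m$nodes, 2, min)),
               c(99, 99, 0))
  expect_true(all(abs(m$fiber[, 1] - 1) < 1e-12))
  expect_true(all(m$label == "BULK"))
  # determinism
  expect_identical(make_sheet(10, 7, 2), make_sheet(10, 7, 2))
})

test_that("VTK round trip preserves coordinates and all cell data", {
  m <- make_sheet(5, 4, 1.5)
  m$label[3] <- "PV"
  m$sigma_l[7] <- 0; m$sigma_t[7] <- 0; m$label[7] <- "LESION"
  f <- tempfile(fileext = ".vtk")
  save_mesh(m, f)
  m2 <- load_mesh(f)
  expect_lt(max(abs(m2$nodes - m$nodes)), 1e-6)
  expect_identical(m2$elements, m$elements)
  expect_identical(m2$label, m$label)
  expect_equal(m2$sigma_l, m$sigma_l)
  expect_equal(m2$sigma_t, m$sigma_t)
  expect_lt(max(abs(m2$fiber - m$fiber)), 1e-12)
})

test_that("VTK loader fills missing arrays with defaults and rejects bad files", {
  # minimal file without any cell data
  f <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII", "DATASET POLYDATA",
               "POINTS 4 float", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "POLYGONS 2 8", "3 0 1 2", "3 0 2 3"), f)
  m <- load_mesh(f)
  expect_true(all(m$label == "BULK"))
  expect_true(all(m$sigma_l == 8.9))
  expect_true(all(m$sigma_t == 0.89))
  expect_lt(max(abs(sqrt(rowSums(m$fiber^2)) - 1)), 1e-9)
  # out-of-range node index
  f2 <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII", "DATASET POLYDATA",
               "POINTS 4 float", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "POLYGONS 1 4", "3 0 1 99"), f2)
  expect_error(load_mesh(f2), "format error")
  expect_error(load_mesh(tempfile()), "format error")
})

test_that("circular lesion matches a brute-force centroid scan and is idempotent", {
  m <- make_sheet(41, 41, 1)
  ctr <- c(20, 20, 0)
  les <- apply_circular_lesion(m, ctr, 7)
  cc <- mesh_centroids(m)
  expected <- sqrt(colSums((t(cc) - ctr)^2)) <= 7
  expect_identical(les$label == "LESION", expected)
  expect_true(all(les$sigma_l[expected] == 0))
  expect_true(all(les$sigma_t[expected] == 0))
  expect_equal(les$sigma_l[!expected], m$sigma_l[!expected])
  # idempotence
  les2 <- apply_circular_lesion(les, ctr, 7)
  expect_identical(les2, les)
  # empty lesion warns, modifies nothing
  expect_warning(les3 <- apply_circular_lesion(m, c(0.5, 0.5, 5), 0.2),
                 "no element")
  expect_identical(les3, m)
})

test_that("linear lesion matches brute-force point-segment distance and is contiguous", {
  m <- make_sheet(31, 31, 1)
  poly <- rbind(c(5, 15, 0), c(25, 15, 0))
  les <- apply_linear_lesion(m, poly, 1)
  cc <- mesh_centroids(m)
  # brute force: distance to the single segment
  a <- poly[1, ]; b <- poly[2, ]
  ab <- b - a
  tt <- pmin(1, pmax(0, as.numeric(sweep(cc, 2, a) %*% ab) / sum(ab^2)))
  d <- sqrt(rowSums((cc - (rep(1, nrow(cc)) %o% a + outer(tt, ab)))^2))
  expect_identical(les$label == "LESION", d <= 1)
  # contiguity of the lesioned band
  comp <- rotorbench:::element_components(les, les$label == "LESION")
  expect_equal(max(comp), 1L)
  # degenerate polyline behaves as a disc
  deg <- apply_linear_lesion(m, rbind(c(15, 15, 0), c(15, 15, 0)), 3)
  circ <- apply_circular_lesion(m, c(15, 15, 0), 3)
  expect_identical(deg$label, circ$label)
  expect_error(apply_linear_lesion(m, rbind(c(1, 1, 0)), 1), "2 points")
})

test_that("lesions never increase conductivity and are rigid-motion invariant", {
  m <- make_sheet(21, 21, 1)
  les <- apply_circular_lesion(m, c(10, 10, 0), 4)
  expect_true(all(les$sigma_l <= m$sigma_l))
  expect_true(all(les$sigma_t <= m$sigma_t))
  # rotate mesh + lesion jointly: same membership
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m_rot <- m
  m_rot$nodes <- m$nodes %*% t(R)
  m_rot$fiber <- m$fiber %*% t(R)
  les_rot <- apply_circular_lesion(m_rot, as.numeric(R %*% c(10, 10, 0)), 4)
  expect_identical(les_rot$label, les$label)
})

test_that("ellipsoid surrogate has the right topology and fibers", {
  m0 <- make_ellipsoid_atrium(resolution = 8)
  euler <- function(m) {
    nrow(m$nodes) - nrow(rotorbench:::mesh_edges(m)) + nrow(m$elements)
  }
  expect_equal(euler(m0), 2)
  # nodes satisfy the ellipsoid equation
  ax <- c(45, 30, 27.5)
  r <- sqrt(rowSums(sweep(m0$nodes, 2, ax, `/`)^2))
  expect_true(all(abs(r - 1) < 1e-9))
  holes <- list(list(center = c(0, 0, 27.5), radius = 6, label = "PV"),
                list(center = c(0, 0, -27.5), radius = 6, label = "MVR"))
  m5 <- make_ellipsoid_atrium(resolution = 8, holes = holes)
  expect_equal(euler(m5), 0)  # 2 - number of holes
  expect_true(any(m5$label == "PV"))
  expect_true(any(m5$label == "MVR"))
  expect_lt(max(abs(sqrt(rowSums(m5$fiber^2)) - 1)), 1e-9)
})
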