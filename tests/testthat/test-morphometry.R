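test_that("vertex thickness matches construction oracles", {
  # concentric spheres: thickness exactly R - r everywhere
  outer <- icosphere(50, 3)
  inner <- icosphere(48, 3)
  pair <- surface_pair(outer, inner)
  expect_equal(vertex_thickness(pair), rep(2, nrow(outer$vertices)),
               tolerance = 1e-9)
  # identical meshes: all zeros
  expect_equal(vertex_thickness(surface_pair(outer, outer)),
               rep(0, nrow(outer$vertices)))
  # inner offset along normals on a perturbed sphere: exactly the offset
  sp <- generate_surface_pair(radius = 30, amplitude = 3, thickness_field = 3,
                              subdivisions = 3)
  expect_equal(vertex_thickness(sp), rep(3, nrow(sp$outer$vertices)),
               tolerance = 1e-9)
  # topology mismatch rejected
  expect_error(surface_pair(outer, icosphere(48, 2)), "identical face list")
})

test_that("thickness is invariant under rigid motion of the pair", {
  sp <- generate_surface_pair(radius = 20, amplitude = 2, thickness_field = 2,
                              subdivisions = 2)
  th0 <- vertex_thickness(sp)
  ang <- 0.7
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  move <- function(m) tri_mesh(m$vertices %*% t(Rz) + rep(c(5, -3, 11),
                                                          each = nrow(m$vertices)),
                               m$faces)
  th1 <- vertex_thickness(surface_pair(move(sp$outer), move(sp$inner)))
  expect_equal(th1, th0, tolerance = 1e-9)
})

test_that("surface area obeys analytic, similarity, and partition rules", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri)$total, 0.5)
  scaled <- tri_mesh(tri$vertices * 2, tri$faces)
  expect_equal(surface_area(scaled)$total, 4 * surface_area(tri)$total)

  sp <- generate_surface_pair(radius = 15, amplitude = 1.5, subdivisions = 3)
  key <- sp$outer$vertex_labels + ifelse(sp$outer$vertex_hemi == "R", 17L, 0L)
  a <- surface_area(sp$outer, labels = key)
  expect_equal(sum(a$by_region), a$total, tolerance = 1e-9)
  # mirror-symmetric labels: left and right sector areas agree within mesh
  # tolerance
  lab_hemi <- ifelse(key > 17, "R", "L")
  aL <- sum(a$by_region[as.integer(names(a$by_region)) <= 17])
  aR <- sum(a$by_region[as.integer(names(a$by_region)) > 17])
  expect_lt(abs(aL - aR) / a$total, 0.02)
})

test_that("inflation is a near-fixed-point on spheres and flattens bumps", {
  s <- icosphere(20, 3)
  infl <- inflate_surface(s, iterations = 200)
  expect_equal(surface_area(infl)$total, surface_area(s)$total,
               tolerance = 1e-6)
  # uniform-Laplacian equilibrium stays within ~3% of the sphere radius
  expect_lt(max(abs(sqrt(rowSums(infl$vertices^2)) - 20)), 0.6)

  # a harmonic perturbation is flattened to < 5% of its input amplitude,
  # measured against the sphere's own inflation equilibrium
  sp <- generate_surface_pair(radius = 20, amplitude = 2, subdivisions = 3)
  infl2 <- inflate_surface(sp$outer, iterations = 200)
  rs <- sqrt(rowSums(infl$vertices^2))
  rb <- sqrt(rowSums(infl2$vertices^2))
  residual <- (rb / mean(rb) - rs / mean(rs)) * 20
  pert_in <- sqrt(rowSums(sp$outer$vertices^2)) - 20
  expect_lt(sd(residual) / sd(pert_in), 0.05)
  expect_equal(surface_area(infl2)$total, surface_area(sp$outer)$total,
               tolerance = 0.01)
})

test_that("depth is zero-minimum, catches harmonic amplitude, offset-invariant", {
  s <- icosphere(20, 3)
  expect_equal(sp_depth(s, s), rep(0, nrow(s$vertices)))

  sp <- generate_surface_pair(radius = 25, amplitude = 2, subdivisions = 3)
  infl <- inflate_surface(sp$outer, iterations = 100)
  d <- sp_depth(sp$outer, infl)
  expect_identical(min(d), 0)
  # single-harmonic perturbation of amplitude A gives depth range ~ 2A
  expect_equal(diff(range(d)), 4, tolerance = 0.25)

  # adding a constant radial offset to both surfaces leaves depth unchanged
  push <- function(m, eps) {
    u <- m$vertices / sqrt(rowSums(m$vertices^2))
    tri_mesh(m$vertices + eps * u, m$faces)
  }
  d2 <- sp_depth(push(sp$outer, 1.5), push(infl, 1.5))
  expect_equal(d2, d, tolerance = 0.02)
})

test_that("region volumes count voxels and conserve totals", {
  g <- array(0L, c(4, 4, 4))
  g[1:10] <- 1L
  lv <- label_volume(g, 0.5)
  rv <- region_volume(lv)
  expect_equal(unname(rv$by_region["1"]), 10 * 0.125)
  expect_equal(rv$total, 1.25)
  expect_equal(region_volume(label_volume(array(0L, c(3, 3, 3)), 1))$total, 0)
})

test_that("regional medians equal the brute-force sorted median", {
  expect_equal(unname(regional_median(rep(7, 30), rep(1:3, 10))), rep(7, 3))
  expect_equal(unname(regional_median(c(1, 2, 100), c(1, 1, 1))), 2)
  set.seed(8)
  vals <- rnorm(500)
  labs <- sample(1:9, 500, replace = TRUE)
  expect_equal(unname(regional_median(vals, labs)),
               unname(median_oracle(vals, labs)))
  # excluded labels dropped; empty region is NA, not zero
  out <- regional_median(c(1, 2, 3), c(1, 2, 2), exclude = 1)
  expect_identical(names(out), "2")
  expect_error(regional_median(1:3, 1:2), "lengths differ")
})

test_that("surface quality metrics behave on analytic fixtures", {
  s <- icosphere(20, 3)
  sp <- surface_pair(s, icosphere(18, 3))
  lv <- voxelize_labels(relabel_pair(sp), 1)
  qc <- surface_qc(s, lv)
  # constant-curvature sphere: smoothness error ~ 0
  expect_lt(qc$smoothness_error, 5e-3)
  # vertices sit on the shell boundary: distance below the voxel diagonal
  expect_lt(qc$boundary_distance_error, sqrt(3))
  # displacing the mesh 1 mm from its own voxelization boundary shifts the
  # boundary distance error by about 1 mm
  s2 <- tri_mesh(s$vertices * (21 / 20), s$faces)
  qc2 <- surface_qc(s2, lv)
  expect_equal(qc2$boundary_distance_error - qc$boundary_distance_error, 1,
               tolerance = 0.35)
  expect_error(surface_qc(s, label_volume(array(0L, c(3, 3, 3)), 1)),
               "empty boundary")
})
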