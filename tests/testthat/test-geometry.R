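test_that("mesh volumes match closed forms", {
  expect_equal(mesh_volume(box_mesh(dims = c(1, 1, 1))), 1)
  expect_equal(mesh_volume(box_mesh(dims = c(2, 3, 4))), 24)
  # geodesic sphere, 4 subdivisions: within 1% of (4/3) pi r^3
  s <- icosphere_mesh(radius = 5, subdivisions = 4)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.01)
  # prism: equilateral cross-section area times height
  expect_equal(mesh_volume(prism_mesh(side = 2, height = 3)),
               sqrt(3) / 4 * 4 * 3)
})

test_that("open meshes are rejected with a not-closed error", {
  cube <- box_mesh()
  open <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open), class = "ctpop_not_closed")
})

test_that("degenerate faces and bad indices are invalid geometry", {
  expect_error(tri_mesh(diag(3), rbind(c(1, 1, 2))),
               class = "ctpop_invalid_geometry")
  expect_error(tri_mesh(diag(3), rbind(c(1, 2, 4))),
               class = "ctpop_invalid_geometry")
  expect_error(box_mesh(dims = c(1, 0, 1)), class = "ctpop_invalid_geometry")
})

test_that("cuboid mesh volume equals dx*dy*dz for random placements", {
  set.seed(11)
  for (i in 1:50) {
    dims <- runif(3, 0.1, 10)
    s <- extraction_site("s", dims, runif(3, -20, 20), runif(3, -180, 180))
    expect_equal(mesh_volume(cuboid_to_mesh(s)), prod(dims),
                 tolerance = 1e-9)
  }
})

test_that("cuboid placement follows the center-rotation-translation convention", {
  s0 <- extraction_site("s", c(1, 1, 1))
  expect_equal(mesh_volume(cuboid_to_mesh(s0)), 1)
  # translation moves the centroid by exactly the offset
  st <- extraction_site("s", c(1, 1, 1), translation = c(5, 0, 0))
  expect_equal(colMeans(cuboid_to_mesh(st)$vertices), c(5, 0, 0))
  # rotation never changes the volume
  sr <- extraction_site("s", c(2, 3, 4), rotation = c(33, -71, 112))
  expect_equal(mesh_volume(cuboid_to_mesh(sr)), 24, tolerance = 1e-9)
  # 90 degrees about z maps the x extent onto y
  sz <- extraction_site("s", c(4, 2, 2), rotation = c(0, 0, 90))
  bb <- mesh_bbox(cuboid_to_mesh(sz))
  expect_equal(unname(bb[2, ] - bb[1, ]), c(2, 4, 2), tolerance = 1e-12)
  expect_error(extraction_site("s", c(-1, 1, 1)),
               class = "ctpop_invalid_geometry")
})

test_that("validate_mesh reports closedness and repairs simple holes", {
  cube <- box_mesh()
  rep <- validate_mesh(cube)
  expect_true(rep$closed)
  expect_true(rep$manifold)
  expect_true(rep$oriented)
  # remove one quad (two triangles): open, then filled back to closed
  open <- tri_mesh(cube$vertices, cube$faces[-c(1, 2), ])
  rep2 <- validate_mesh(open)
  expect_false(rep2$closed)
  filled <- validate_mesh(open, fill = TRUE)$mesh
  rep3 <- validate_mesh(filled, fill = TRUE)
  expect_true(rep3$closed)
  expect_true(rep3$manifold)
  # repair is idempotent and volume-preserving
  expect_identical(validate_mesh(filled, fill = TRUE)$mesh$faces, filled$faces)
  expect_equal(mesh_volume(filled), 1, tolerance = 1e-9)
})

test_that("non-manifold meshes fail repair rather than guessing", {
  cube <- box_mesh()
  bad <- tri_mesh(cube$vertices, rbind(cube$faces, cube$faces[1, ]))
  expect_error(validate_mesh(bad, fill = TRUE), class = "ctpop_repair_failed")
})

test_that("voxel volume estimates converge to analytic volumes", {
  g <- voxelize(box_mesh(), 0.05)
  expect_lt(abs(voxel_volume(g) - 1), 0.02)
  s <- icosphere_mesh(radius = 5, subdivisions = 2)
  vs <- mesh_volume(s)
  g2 <- voxelize(s, 0.25)
  expect_lt(abs(voxel_volume(g2) - vs) / vs, 0.02)
  expect_gt(sum(g$occ), 0)  # a valid closed mesh always occupies voxels
  expect_error(voxelize(box_mesh(), -1), class = "ctpop_invalid_parameter")
})

test_that("halving the pitch tightens the voxel estimate on convex fixtures", {
  for (m in list(box_mesh(dims = c(1.3, 0.9, 1.1)),
                 icosphere_mesh(radius = 1, subdivisions = 2))) {
    v <- mesh_volume(m)
    area_bound <- 2 * sum((mesh_bbox(m)[2, ] - mesh_bbox(m)[1, ])^2) * 3
    e1 <- abs(voxel_volume(voxelize(m, 0.1)) - v)
    e2 <- abs(voxel_volume(voxelize(m, 0.05)) - v)
    expect_lte(e2, e1 + 0.1 * area_bound)
  }
})

test_that("voxel surface extraction yields a closed mesh of equal volume", {
  g <- voxelize(box_mesh(dims = c(1.3, 0.7, 1)), 0.1)
  m <- voxel_surface_mesh(g)
  expect_true(validate_mesh(m)$closed)
  expect_equal(mesh_volume(m), voxel_volume(g), tolerance = 1e-9)
})
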