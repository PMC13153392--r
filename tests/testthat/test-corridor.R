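test_that("search domain is the Minkowski expansion of the target boxes", {
  # single unit-cube target, unit-cube site: admissible centers form the cube
  # expanded by half the site extents in each axis
  org <- two_box_organ()
  s <- extraction_site("s", c(1, 1, 1), c(0, 0, 0), target_organ = "organA",
                       organ_sex = "male")
  dom <- search_domain(s, list(org$structures$AS1))
  expect_equal(unname(dom[1, ]), c(-1, -1, -1))
  expect_equal(unname(dom[2, ]), c(1, 1, 1))
  # the original placement is inside the domain when it collides with targets
  s2 <- straddle_site()
  dom2 <- search_domain(s2, list(org$structures$AS1, org$structures$AS2))
  expect_true(all(s2$translation >= dom2[1, ] & s2$translation <= dom2[2, ]))
  # targets farther apart than the site can reach: infeasible
  far <- reference_organ("organA", "male", list(
    box_mesh(c(0, 0, 0), c(1, 1, 1), id = "A1"),
    box_mesh(c(10, 0, 0), c(1, 1, 1), id = "A2")))
  expect_error(search_domain(s, list(far$structures$A1, far$structures$A2)),
               class = "ctpop_infeasible_domain")
})

test_that("the original placement is feasible at tolerance 0", {
  org <- two_box_organ()
  s <- straddle_site()
  targets <- c(AS1 = 0.5, AS2 = 0.5)
  fp <- feasible_placements(s, org, targets,
                            corridor_params(step = 0.25, tolerance = 0))
  orig <- fp[abs(fp$tx - 0.5) < 1e-12 & abs(fp$ty) < 1e-12 &
               abs(fp$tz) < 1e-12, ]
  expect_equal(nrow(orig), 1)
  expect_true(orig$feasible)
})

test_that("feasibility along the interface normal dies beyond the tolerance", {
  org <- two_box_organ()
  s <- straddle_site()
  targets <- c(AS1 = 0.5, AS2 = 0.5)
  fp <- feasible_placements(s, org, targets,
                            corridor_params(step = 0.1, tolerance = 0.1))
  feas <- fp[fp$feasible, ]
  # sliding within the shared-face plane keeps 50/50; moving 0.1 mm along x
  # changes each target volume by 20% of 0.5 and must be infeasible
  expect_true(all(abs(feas$tx - 0.5) < 1e-9))
  expect_true(any(abs(feas$ty) > 0.05))  # in-plane sliding survives
  x_off <- fp[abs(fp$tx - 0.6) < 1e-9 & abs(fp$ty) < 1e-9 &
                abs(fp$tz) < 1e-9, ]
  expect_false(x_off$feasible)
})

test_that("targets exceeding the site volume are flagged inconsistent", {
  org <- two_box_organ()
  s <- straddle_site()
  fp <- feasible_placements(s, org, c(AS1 = 5, AS2 = 5),
                            corridor_params(step = 0.5))
  expect_true(attr(fp, "inconsistent"))
  expect_false(any(fp$feasible))
})

test_that("single-structure corridors return the structure verbatim", {
  org <- two_box_organ(gap = 1)
  s <- extraction_site("inside", c(0.4, 0.4, 0.4), c(0, 0, 0),
                       target_organ = "organA", organ_sex = "male")
  cor <- build_corridor(s, org)
  expect_equal(attr(cor, "case"), 1L)
  expect_equal(mesh_volume(cor), mesh_volume(org$structures$AS1),
               tolerance = 1e-9)
  expect_equal(cor$vertices, org$structures$AS1$vertices)
})

test_that("three-or-more-structure corridors are the site cuboid exactly", {
  org <- reference_organ("organA", "male", list(
    box_mesh(c(0, 0, 0), c(1, 1, 1), id = "A1"),
    box_mesh(c(1, 0, 0), c(1, 1, 1), id = "A2"),
    box_mesh(c(2, 0, 0), c(1, 1, 1), id = "A3")))
  s <- extraction_site("s3", c(2.2, 0.5, 0.5), c(1, 0, 0),
                       target_organ = "organA", organ_sex = "male")
  cor <- build_corridor(s, org)
  expect_equal(attr(cor, "case"), 3L)
  expect_equal(cor$vertices, cuboid_to_mesh(s)$vertices)
  expect_equal(mesh_volume(cor), site_volume(s), tolerance = 1e-12)
})

test_that("two-structure corridors contain the site and all feasible cuboids", {
  org <- two_box_organ()
  s <- straddle_site()
  cor <- build_corridor(s, org, corridor_params(step = 0.2))
  expect_equal(attr(cor, "case"), 2L)
  expect_true(validate_mesh(cor)$closed)
  expect_gte(mesh_volume(cor), site_volume(s))
  fp <- attr(cor, "placements")
  pts <- as.matrix(fp[fp$feasible, c("tx", "ty", "tz")])
  corners <- cuboid_to_mesh(s)$vertices
  for (r in seq_len(nrow(pts))) {
    moved <- sweep(sweep(corners, 2, s$translation), 2, pts[r, ], "+")
    expect_true(all(points_in_mesh_parity(moved, cor)),
                label = sprintf("feasible cuboid %d inside corridor", r))
  }
})

test_that("feasible placements are sound under the 10% rule", {
  org <- two_box_organ()
  s <- straddle_site()
  col <- mesh_collisions(s, org)
  targets <- stats::setNames(col$intersection_volume, col$as_id)
  fp <- feasible_placements(s, org, targets, corridor_params(step = 0.2))
  pts <- as.matrix(fp[fp$feasible, c("tx", "ty", "tz")])
  set.seed(5)
  pts <- pts[sample(nrow(pts), min(10, nrow(pts))), , drop = FALSE]
  for (r in seq_len(nrow(pts))) {
    s2 <- s; s2$translation <- pts[r, ]
    col2 <- mesh_collisions(s2, org)
    v2 <- col2$intersection_volume[match(names(targets), col2$as_id)]
    expect_true(all(abs(v2 - targets) <= 0.1 * targets + 1e-12))
  }
})

test_that("refining the step keeps coarse feasible points; tolerance grows corridors", {
  org <- two_box_organ()
  s <- straddle_site()
  targets <- c(AS1 = 0.5, AS2 = 0.5)
  coarse <- feasible_placements(s, org, targets,
                                corridor_params(step = 0.2, tolerance = 0.1))
  fine <- feasible_placements(s, org, targets,
                              corridor_params(step = 0.1, tolerance = 0.1))
  cf <- coarse[coarse$feasible, 1:3]
  ff <- fine[fine$feasible, 1:3]
  for (r in seq_len(nrow(cf))) {
    hit <- any(rowSums(abs(sweep(as.matrix(ff), 2, as.numeric(cf[r, ])))) < 1e-9)
    expect_true(hit, label = sprintf("coarse point %d survives refinement", r))
  }
  vols <- vapply(c(0.05, 0.1, 0.2), function(tau) {
    mesh_volume(build_corridor(s, org, corridor_params(step = 0.2,
                                                       tolerance = tau)))
  }, numeric(1))
  expect_true(all(diff(vols) >= -1e-9))
})

test_that("corridor OFF output is byte-identical across runs", {
  org <- two_box_organ()
  s <- straddle_site()
  p1 <- withr::local_tempfile(fileext = ".off")
  p2 <- withr::local_tempfile(fileext = ".off")
  write_off(build_corridor(s, org, corridor_params(step = 0.25)), p1)
  write_off(build_corridor(s, org, corridor_params(step = 0.25)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a site colliding with nothing has no corridor", {
  org <- two_box_organ()
  s <- extraction_site("far", c(1, 1, 1), c(0, 30, 0),
                       target_organ = "organA", organ_sex = "male")
  expect_error(build_corridor(s, org), class = "ctpop_no_collision")
})
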