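test_that("identical, shifted and disjoint cuboids give exact volumes", {
  org <- reference_organ("organA", "male", list(
    box_mesh(c(0, 0, 0), c(1, 1, 1), label = "AS one", id = "AS1")))
  # identical: 100% of the site volume
  s <- extraction_site("s", c(1, 1, 1), c(0, 0, 0), target_organ = "organA")
  col <- mesh_collisions(s, org)
  expect_equal(col$intersection_volume, 1)
  expect_equal(col$percentage_of_site, 100)
  # shifted by 0.5 along x: interval arithmetic says half the volume
  s2 <- extraction_site("s2", c(1, 1, 1), c(0.5, 0, 0), target_organ = "organA")
  col2 <- mesh_collisions(s2, org)
  expect_equal(col2$intersection_volume,
               interval_overlap_volume(c(0.5, 0, 0), c(1, 1, 1),
                                       c(0, 0, 0), c(1, 1, 1)))
  expect_equal(col2$percentage_of_site, 50)
  # disjoint: no records
  s3 <- extraction_site("s3", c(1, 1, 1), c(10, 0, 0), target_organ = "organA")
  expect_equal(nrow(mesh_collisions(s3, org)), 0)
})

test_that("mesh hits are always a subset of bounding-box hits", {
  set.seed(21)
  for (i in 1:25) {
    org <- two_box_organ(gap = runif(1, 0, 0.5))
    s <- extraction_site("s", runif(3, 0.3, 1.5), runif(3, -1, 2),
                         runif(3, 0, 90), target_organ = "organA",
                         organ_sex = "male")
    expect_true(all(mesh_collisions(s, org)$as_id %in% bbox_collisions(s, org)))
  }
})

test_that("a rotated site can graze a bounding box without a mesh hit", {
  org <- reference_organ("organA", "male", list(
    box_mesh(c(0, 0, 0), c(1, 1, 1), label = "AS", id = "AS1")))
  # cuboid rotated 45 deg about z, positioned so its AABB overlaps the box
  # corner but its rotated body does not
  s <- extraction_site("s", c(1, 1, 1), c(1.15, 1.15, 0), c(0, 0, 45),
                       target_organ = "organA", organ_sex = "male")
  expect_equal(bbox_collisions(s, org), "AS1")
  expect_equal(nrow(mesh_collisions(s, org)), 0)
})

test_that("boolean volumes agree with the voxel oracle on random fixtures", {
  set.seed(31)
  for (i in 1:15) {
    pair <- random_convex_pair()
    sm <- cuboid_to_mesh(pair$site)
    vb <- convex_intersection_volume(sm, pair$as)
    vv <- voxel_intersection_volume(sm, pair$as)
    if (vb > 1e-3)
      expect_lt(abs(vb - vv) / vb, 0.02)
  }
})

test_that("intersection volumes respect the site-volume bound", {
  set.seed(41)
  for (i in 1:20) {
    org <- two_box_organ(gap = 0.2)
    s <- extraction_site("s", runif(3, 0.3, 1.2), runif(3, -0.5, 1.7),
                         runif(3, 0, 90), target_organ = "organA",
                         organ_sex = "male")
    col <- mesh_collisions(s, org)
    if (nrow(col) > 0) {
      expect_true(all(col$percentage_of_site > 0 &
                        col$percentage_of_site <= 100 + 1e-9))
      # the two structures are disjoint, so summed volumes cannot exceed the site
      expect_lte(sum(col$intersection_volume),
                 site_volume(s) * (1 + 1e-6))
    }
  }
})

test_that("collision records sort by volume with lexicographic ties", {
  org <- two_box_organ(gap = 0)
  # 70/30 straddle: AS1 gets more
  s <- extraction_site("s", c(1, 1, 1), c(0.3, 0, 0), target_organ = "organA",
                       organ_sex = "male")
  col <- mesh_collisions(s, org)
  expect_equal(col$as_id, c("AS1", "AS2"))
  expect_equal(col$intersection_volume, c(0.7, 0.3), tolerance = 1e-9)
  expect_equal(as_tags(s, org), c("AS one", "AS two"))
  # exact 50/50 tie: lexicographic by id
  s2 <- straddle_site(gap = 0)
  expect_equal(mesh_collisions(s2, org)$as_id, c("AS1", "AS2"))
})

test_that("organ mismatch is an error", {
  org <- two_box_organ()
  s <- extraction_site("s", c(1, 1, 1), target_organ = "otherOrgan")
  expect_error(bbox_collisions(s, org), class = "ctpop_organ_mismatch")
  expect_error(mesh_collisions(s, org), class = "ctpop_organ_mismatch")
})

test_that("reference-structure overlap detection matches interval arithmetic", {
  disjoint <- make_reference_organ(3, "box", size = 2, gap = 1)
  expect_equal(nrow(detect_reference_overlaps(disjoint)), 0)
  # two boxes overlapping in a 0.5 mm^3 slab
  org <- reference_organ("o", "male", list(
    box_mesh(c(0, 0, 0), c(2, 1, 1), id = "A"),
    box_mesh(c(1.5, 0, 0), c(2, 1, 1), id = "B")))
  ov <- detect_reference_overlaps(org)
  expect_equal(nrow(ov), 1)  # each unordered pair reported once
  expect_equal(ov$shared_volume,
               interval_overlap_volume(c(0, 0, 0), c(2, 1, 1),
                                       c(1.5, 0, 0), c(2, 1, 1)))
  expect_equal(ov$shared_volume, 0.5)
  expect_true(ov$as_id_a < ov$as_id_b)
})

test_that("face contact with zero shared volume is not a collision", {
  org <- two_box_organ(gap = 0)
  # unit cube spanning x in [-1.5, -0.5]: touches AS1's x = -0.5 face only
  s <- extraction_site("s", c(1, 1, 1), c(-1, 0, 0),
                       target_organ = "organA", organ_sex = "male")
  expect_equal(nrow(mesh_collisions(s, org)), 0)
})
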