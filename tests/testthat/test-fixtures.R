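test_that("generated organs are closed, convex and pairwise disjoint", {
  org <- make_reference_organ(5, c("box", "sphere", "prism"), size = 2, gap = 1)
  expect_length(org$structures, 5)
  for (m in org$structures) {
    expect_true(validate_mesh(m)$closed)
    expect_true(is_convex_mesh(m))
  }
  expect_equal(nrow(detect_reference_overlaps(org)), 0)
  # requesting an overlapping pair yields exactly one colliding pair
  org2 <- make_reference_organ(3, "box", overlap_pairs = 1)
  ov <- detect_reference_overlaps(org2)
  expect_equal(nrow(ov), 1)
  expect_gt(ov$shared_volume, 0)
})

test_that("organ generation is deterministic", {
  a <- make_reference_organ(4, c("box", "sphere"), seed = 9)
  b <- make_reference_organ(4, c("box", "sphere"), seed = 9)
  for (aid in names(a$structures))
    expect_identical(a$structures[[aid]]$vertices, b$structures[[aid]]$vertices)
})

test_that("site ground truth matches mesh-based collision detection", {
  org <- make_reference_organ(3, "box", size = 2, gap = 1)
  full <- make_extraction_sites(org, 3, "full")
  gt <- attr(full, "ground_truth")
  for (sid in names(full)) {
    col <- mesh_collisions(full[[sid]], org)
    g <- gt[gt$site_id == sid, ]
    expect_equal(col$as_id, g$as_id)
    expect_equal(col$percentage_of_site, g$percentage, tolerance = 1e-9)
  }
  s2 <- make_extraction_sites(org, 2, "straddle2")
  gt2 <- attr(s2, "ground_truth")
  for (sid in names(s2)) {
    col <- mesh_collisions(s2[[sid]], org)
    g <- gt2[gt2$site_id == sid, ]
    expect_setequal(col$as_id, g$as_id)
    m <- match(col$as_id, g$as_id)
    expect_equal(col$intersection_volume, g$volume[m], tolerance = 0.01)
  }
  s3 <- make_extraction_sites(org, 1, "straddle3")
  expect_equal(nrow(mesh_collisions(s3[[1]], org)), 3)
  out <- make_extraction_sites(org, 1, "outside")
  expect_equal(nrow(mesh_collisions(out[[1]], org)), 0)
})

test_that("cell datasets realize their mixtures within binomial bounds", {
  mix <- c(ct1 = 0.7, ct2 = 0.3)
  d <- make_cell_dataset("dsA", mix, n_cells = 1000, seed = 6)
  frac <- d$truth / sum(d$truth)
  # 99% binomial interval around the target fraction
  for (ct in names(mix)) {
    half <- 2.576 * sqrt(mix[[ct]] * (1 - mix[[ct]]) / 1000)
    expect_lt(abs(frac[[ct]] - mix[[ct]]), half + 1e-12)
  }
  expect_equal(sum(d$truth), 1000)
  # determinism
  d2 <- make_cell_dataset("dsA", mix, n_cells = 1000, seed = 6)
  expect_identical(d$cells, d2$cells)
  expect_identical(d$counts, d2$counts)
})

test_that("planted markers are recovered as top-ranked genes", {
  mix <- stats::setNames(rep(0.25, 4), paste0("ct", 1:4))
  d <- make_cell_dataset("dsB", mix, n_cells = 400, seed = 7)
  mk <- rank_markers(d$cells, d$counts, n = 10)
  for (ct in names(mix)) {
    top <- mk[[paste0("azimuth:", ct)]]$gene[1:10]
    expect_true(all(d$markers[[ct]] %in% top))
  }
})

test_that("crosswalk fixtures control unmapped counts and narrow merges", {
  cts <- paste0("ct", 1:10)
  xw0 <- make_crosswalk(cts, unmapped_fraction = 0)
  pop <- ct_population("d", "dataset", "azimuth", data.frame(
    ct_id = paste("azimuth", cts, sep = ":"),
    ct_label = paste("azimuth", cts, sep = ":"), count = 1:10))
  expect_length(apply_crosswalk(pop, xw0$crosswalk)$unmapped, 0)
  xw2 <- make_crosswalk(cts, unmapped_fraction = 0.2, seed = 3)
  expect_length(apply_crosswalk(pop, xw2$crosswalk)$unmapped, 2)
  # narrow rows merge two children onto one target
  xwn <- make_crosswalk(cts, narrow_pairs = 1)
  res <- apply_crosswalk(pop, xwn$crosswalk)
  e <- res$population$entries
  merged <- xwn$ct_ids[["ct1"]]
  expect_equal(e$count[e$ct_id == merged], 1 + 2)
  expect_equal(sum(e$count), sum(pop$entries$count))
})

test_that("simulated studies are reproducible and write readable inputs", {
  a <- simulate_preset("small", seed = 31)
  b <- simulate_preset("small", seed = 31)
  expect_identical(a$datasets, b$datasets)
  expect_identical(a$cell_tables, b$cell_tables)
  d <- withr::local_tempdir()
  simulate_preset("small", seed = 31, out = d)
  expect_true(file.exists(file.path(d, "sites.json")))
  org <- read_reference_organ(file.path(d, "organs", a$organ$id))
  expect_equal(names(org$structures), names(a$organ$structures))
})
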