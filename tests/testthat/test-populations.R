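test_that("populations count label multiplicities and normalize to 100", {
  cells <- data.frame(cell_id = paste0("c", 1:3),
                      ct_label = c("A", "A", "B"), tool = "azimuth")
  pop <- population_from_cell_table(cells)
  expect_equal(pop$entries$count[pop$entries$ct_id == "A"], 2)
  expect_equal(pop$entries$percentage,
               c(200 / 3, 100 / 3), tolerance = 1e-9)
  one <- population_from_cell_table(
    data.frame(cell_id = "c1", ct_label = "A", tool = "popv"))
  expect_equal(one$entries$percentage, 100)
})

test_that("population counts equal a brute-force tally on random labels", {
  set.seed(9)
  labs <- sample(paste0("ct", 1:5), 10000, replace = TRUE,
                 prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
  cells <- data.frame(cell_id = sprintf("c%05d", 1:10000), ct_label = labs,
                      tool = "celltypist")
  pop <- population_from_cell_table(cells)
  # independent tally: loop accumulation, no table()/aggregate machinery
  tally <- stats::setNames(numeric(5), paste0("ct", 1:5))
  for (l in labs) tally[l] <- tally[l] + 1
  expect_equal(stats::setNames(pop$entries$count, pop$entries$ct_id),
               tally[sort(names(tally))])
  expect_equal(sum(pop$entries$percentage), 100, tolerance = 1e-6)
})

test_that("empty tables and duplicate cells are errors", {
  expect_error(population_from_cell_table(
    data.frame(cell_id = character(0), ct_label = character(0))),
    class = "ctpop_empty_input")
  expect_error(population_from_cell_table(
    data.frame(cell_id = c("c1", "c1"), ct_label = c("A", "B"),
               tool = "azimuth")),
    class = "ctpop_duplicate_cell")
})

test_that("crosswalking re-keys, merges narrow matches, and reports unmapped", {
  xw <- crosswalk_table(data.frame(
    tool = "azimuth",
    source_label = c("alpha-like", "alpha-ish", "beta"),
    source_id = c("s1", "s2", "s3"),
    target_id = c("CL:X1", "CL:X1", "CL:X2"),
    target_label = c("alpha cell", "alpha cell", "beta cell"),
    match_type = c("exact", "narrow", "exact")))
  pop <- ct_population("ds", "dataset", "azimuth", data.frame(
    ct_id = c("alpha-like", "alpha-ish", "beta", "mystery"),
    ct_label = c("alpha-like", "alpha-ish", "beta", "mystery"),
    count = c(3, 7, 5, 2)))
  res <- apply_crosswalk(pop, xw)
  e <- res$population$entries
  expect_equal(e$count[e$ct_id == "CL:X1"], 10)  # merged 3 + 7
  expect_equal(e$count[e$ct_id == "CL:X2"], 5)
  expect_true(e$not_crosswalked[e$ct_id == "mystery"])
  expect_equal(res$unmapped, "mystery")
  # conservation of cells and of the percentage identity
  expect_equal(sum(e$count), 17)
  expect_equal(sum(e$percentage), 100, tolerance = 1e-6)
})

test_that("rollup pools children and buckets unmapped types", {
  xw <- crosswalk_table(data.frame(
    tool = "azimuth", source_label = c("a", "b", "c"),
    source_id = c("s1", "s2", "s3"),
    target_id = c("CL:1", "CL:2", "CL:3"),
    target_label = c("A", "B", "C"), match_type = "exact"))
  pop <- ct_population("ds", "dataset", "azimuth", data.frame(
    ct_id = c("a", "b", "c", "zz"), ct_label = c("a", "b", "c", "zz"),
    count = c(3, 7, 4, 1)))
  cw <- apply_crosswalk(pop, xw)$population
  parent_map <- data.frame(ct_id = c("CL:1", "CL:2"),
                           parent_id = "CL:HIGH1",
                           parent_label = "high-level A")
  up <- rollup_to_parents(cw, parent_map)
  e <- up$entries
  expect_equal(e$count[e$ct_id == "CL:HIGH1"], 10)          # 3 + 7
  expect_equal(e$count[e$ct_id == "no_mapped_parent"], 4)   # CL:3
  expect_equal(e$count[e$ct_id == "not_crosswalked"], 1)    # zz
  expect_equal(sum(e$count), sum(pop$entries$count))
  expect_equal(sum(e$percentage), 100, tolerance = 1e-6)
})

test_that("weighted cosine matches the closed form and its identities", {
  mk <- function(ids, pct) ct_population("p", "dataset", "azimuth",
    data.frame(ct_id = ids, ct_label = ids, count = pct))
  u <- mk(c("a", "b"), c(1, 1))
  v <- mk(c("a", "c"), c(1, 1))
  expect_equal(weighted_cosine(u, v), 0.5)   # (1,1,0).(1,0,1)/2
  expect_equal(weighted_cosine(u, u), 1)
  expect_equal(weighted_cosine(mk("a", 1), mk("b", 1)), 0)
  expect_error(weighted_cosine(u, v, weights = c(a = -1)),
               class = "ctpop_invalid_parameter")
  set.seed(13)
  for (i in 1:50) {
    pa <- random_population("a"); pb <- random_population("b")
    s <- weighted_cosine(pa, pb)
    expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
    expect_equal(s, weighted_cosine(pb, pa))
    # scale invariance: counts scaled by k leave percentages unchanged
    pk <- pa; pk$entries$count <- pk$entries$count * 7.3
    pk <- ct_population("a", "dataset", "azimuth", pk$entries[1:3])
    expect_equal(weighted_cosine(pk, pb), s, tolerance = 1e-12)
  }
})

test_that("origin prediction ranks the generating source first", {
  mk <- function(owner, counts) ct_population(owner, "anatomical_structure",
    "azimuth", data.frame(ct_id = names(counts), ct_label = names(counts),
                          count = as.numeric(counts)))
  query <- mk("q", c(ct1 = 70, ct2 = 30))
  cands <- list(AS1 = mk("AS1", c(ct1 = 72, ct2 = 28)),
                AS2 = mk("AS2", c(ct1 = 10, ct2 = 90)),
                AS3 = mk("AS3", c(ct9 = 100)))
  r <- predict_origin(query, cands)
  expect_equal(r$id[1], "AS1")
  expect_equal(r$similarity[r$id == "AS3"], 0)
  # identical candidate wins with similarity 1
  r2 <- predict_origin(query, c(cands, list(AS0 = query)))
  expect_equal(r2$id[1], "AS0")
  expect_equal(r2$similarity[1], 1)
  # all-orthogonal candidates tie at 0 and sort lexicographically
  orth <- list(B = mk("B", c(x = 1)), A = mk("A", c(y = 1)))
  expect_equal(predict_origin(query, orth)$id, c("A", "B"))
})

test_that("z-score rows standardize to mean 0, population SD 1", {
  m <- rbind(ct1 = c(0, 10), ct2 = c(4, 4), ct3 = c(1, 2))
  z <- zscore_matrix(m)
  expect_equal(unname(z["ct1", ]), c(-1, 1))  # population sigma = 5
  expect_equal(unname(z["ct2", ]), c(0, 0))   # constant row rule
  set.seed(17)
  big <- matrix(runif(60, 0, 100), nrow = 6)
  zb <- zscore_matrix(big)
  for (r in seq_len(nrow(zb))) {
    expect_equal(mean(zb[r, ]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((zb[r, ] - mean(zb[r, ]))^2)), 1, tolerance = 1e-9)
  }
})
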