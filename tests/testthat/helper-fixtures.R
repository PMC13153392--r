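# shared builders for geometry and pipeline tests

two_box_organ <- function(gap = 0) {
  # two unit boxes along x; gap = 0 means a shared face at x = 0.5
  reference_organ("organA", "male", list(
    box_mesh(c(0, 0, 0), c(1, 1, 1), label = "AS one", id = "AS1"),
    box_mesh(c(1 + gap, 0, 0), c(1, 1, 1), label = "AS two", id = "AS2")))
}

straddle_site <- function(gap = 0) {
  extraction_site("straddle", c(1, 1, 1), c((1 + gap) / 2, 0, 0),
                  target_organ = "organA", organ_sex = "male")
}

# independent random convex fixture: (rotated cuboid site, convex structure)
random_convex_pair <- function() {
  shape <- sample(c("box", "sphere", "prism"), 1)
  as <- switch(shape,
    box = box_mesh(c(0, 0, 0), stats::runif(3, 1, 3), id = "AS1", label = "AS1"),
    sphere = icosphere_mesh(c(0, 0, 0), stats::runif(1, 0.7, 1.6), 2,
                            id = "AS1", label = "AS1"),
    prism = prism_mesh(c(0, 0, 0), side = stats::runif(1, 1, 2.5),
                       height = stats::runif(1, 1, 2.5), id = "AS1",
                       label = "AS1"))
  site <- extraction_site("s", stats::runif(3, 0.5, 1.5),
                          stats::runif(3, -0.3, 0.3), stats::runif(3, 0, 90))
  list(site = site, as = as)
}

# independent point-in-mesh oracle: z-ray crossing parity per point
points_in_mesh_parity <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(points, 1, function(p) {
    px <- p[1] + 1.1e-7; py <- p[2] + 0.9e-7
    crossings <- 0
    for (t in seq_len(nrow(f))) {
      a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c_ <- v[f[t, 3], ]
      area2 <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
      if (abs(area2) < 1e-14) next
      w0 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      w1 <- (c_[1] - b[1]) * (py - b[2]) - (c_[2] - b[2]) * (px - b[1])
      w2 <- (a[1] - c_[1]) * (py - c_[2]) - (a[2] - c_[2]) * (px - c_[1])
      s <- sign(area2)
      if (s * w0 >= 0 && s * w1 >= 0 && s * w2 >= 0) {
        n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
               (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
               area2)
        zt <- a[3] - ((px - a[1]) * n[1] + (py - a[2]) * n[2]) / n[3]
        if (zt > p[3]) crossings <- crossings + 1
      }
    }
    crossings %% 2 == 1
  })
}

# axis-aligned interval-arithmetic overlap volume of two boxes given as
# (center, dims); the analytic oracle for box-box intersections
interval_overlap_volume <- function(c1, d1, c2, d2) {
  lo <- pmax(c1 - d1 / 2, c2 - d2 / 2)
  hi <- pmin(c1 + d1 / 2, c2 + d2 / 2)
  if (any(hi <= lo)) 0 else prod(hi - lo)
}

random_population <- function(owner = "p", k = 5, tool = "azimuth") {
  ids <- sprintf("CL:%07d", sample(1:12, k))
  ct_population(owner, "dataset", tool,
                data.frame(ct_id = ids, ct_label = ids,
                           count = stats::runif(k, 0, 100)))
}
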