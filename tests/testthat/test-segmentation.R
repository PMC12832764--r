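make_blob_spots <- function(centers, umi_per_blob, grid, sigma = 4,
                            seed = 1) {
  # Gaussian point clouds of unspliced molecules around each center
  set.seed(seed)
  recs <- lapply(seq_len(nrow(centers)), function(i) {
    x <- pmin(pmax(round(rnorm(umi_per_blob, centers[i, 1], sigma)), 0),
              grid$width_bins - 1L)
    y <- pmin(pmax(round(rnorm(umi_per_blob, centers[i, 2], sigma)), 0),
              grid$height_bins - 1L)
    data.frame(x = x, y = y)
  })
  recs <- do.call(rbind, recs)
  agg <- aggregate(list(n = rep(1L, nrow(recs))), recs, FUN = sum)
  spot_table(sprintf("b_%d_%d", agg$x, agg$y), agg$x, agg$y, "g1",
             "unspliced", agg$n, grid)
}

test_that("density maps accumulate counts per channel and conserve totals", {
  g <- grid_spec(6, 6)
  st <- spot_table(c("a", "a", "b"), c(2L, 2L, 4L), c(3L, 3L, 1L),
                   c("g1", "g2", "g1"),
                   c("unspliced", "unspliced", "spliced"),
                   c(2L, 3L, 7L), g)
  du <- build_density(st, "unspliced")
  expect_equal(du[4, 3], 5)  # two records at the same bin add up
  expect_equal(sum(du), 5)
  dt_ <- build_density(st, "total")
  expect_equal(sum(dt_), sum(st$umi_count))

  set.seed(12)
  st2 <- random_spot_table(200, grid_spec(15, 15))
  for (ch in c("unspliced", "spliced", "total")) {
    want <- sum(st2$umi_count[ch == "total" | st2$splice_class == ch])
    expect_equal(sum(build_density(st2, ch)), want, info = ch)
  }
})

test_that("Gaussian smoothing is normalized, constant-preserving and linear", {
  imp <- matrix(0, 101, 101); imp[51, 51] <- 1
  sm <- smooth_density(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_true(all(sm >= 0))

  const <- matrix(4.2, 30, 30)
  expect_equal(smooth_density(const, 5), const, tolerance = 1e-9)

  two <- matrix(0, 101, 101); two[31, 41] <- 1; two[71, 61] <- 2
  a <- matrix(0, 101, 101); a[31, 41] <- 1
  b <- matrix(0, 101, 101); b[71, 61] <- 2
  expect_equal(smooth_density(two, 3),
               smooth_density(a, 3) + smooth_density(b, 3),
               tolerance = 1e-9)

  expect_error(smooth_density(imp, 0), "positive")
})

test_that("core detection finds one core per well-separated blob", {
  g <- grid_spec(120, 80)
  two <- make_blob_spots(rbind(c(40, 40), c(80, 40)), 500, g)
  raw <- build_density(two, "unspliced")
  sm <- smooth_density(raw, 4)
  p <- segmentation_params(sigma_bins = 4)
  cores <- detect_cores(sm, raw, p)
  expect_equal(max(cores), 2L)
  # each generating center sits inside its own core
  l1 <- cores[41, 41]; l2 <- cores[41, 81]
  expect_true(l1 > 0 && l2 > 0 && l1 != l2)

  one <- make_blob_spots(rbind(c(60, 40)), 500, g)
  raw1 <- build_density(one, "unspliced")
  expect_equal(max(detect_cores(smooth_density(raw1, 4), raw1, p)), 1L)

  # uniform low background: Otsu finds no usable split -> zero cores
  flat <- matrix(0.001, 80, 120)
  expect_equal(max(detect_cores(flat, flat, p)), 0L)
})

test_that("core labels are ordered by descending UMI", {
  g <- grid_spec(120, 80)
  # same shape, double the molecules on the right blob: it takes label 1
  left <- make_blob_spots(rbind(c(40, 40)), 300, g, seed = 3)
  right <- make_blob_spots(rbind(c(80, 40)), 600, g, seed = 4)
  st <- rbind(left, right)
  data.table::setattr(st, "grid", g)
  data.table::setattr(st, "class", class(left))
  raw <- build_density(st, "unspliced")
  cores <- detect_cores(smooth_density(raw, 4), raw,
                        segmentation_params(sigma_bins = 4))
  expect_equal(max(cores), 2L)
  expect_equal(cores[41, 81], 1L)
  expect_equal(cores[41, 41], 2L)
})

test_that("expansion grows monotonically with the distance cap and respects caps", {
  sc <- small_scene_spec(seed = 4)
  scene <- generate_scene(sc)
  raw_u <- build_density(scene$spots, "unspliced")
  raw_t <- build_density(scene$spots, "total")
  sm_u <- smooth_density(raw_u, 8)
  sm_t <- smooth_density(raw_t, 8)
  base <- segmentation_params()
  cores <- detect_cores(sm_u, raw_u, base)
  expect_gt(max(cores), 0)

  areas <- sapply(c(0L, 5L, 15L, 40L, 60L), function(d) {
    p <- segmentation_params(expansion_max_dist_bins = d)
    lab <- expand_cores(cores, sm_t, raw_t, p)
    sum(lab > 0)
  })
  expect_true(all(diff(areas) >= 0))

  # cores never merge and stay inside their cellbins
  lab <- expand_cores(cores, sm_t, raw_t, base)
  k <- max(cores)
  expect_equal(max(lab), k)  # all cores survive in this scene
  for (id in seq_len(k)) {
    core_px <- which(cores == id)
    owner <- unique(lab[core_px])
    expect_length(owner, 1)
  }

  # max_area trims: a tiny cap yields exactly that many pixels per cellbin
  p_small <- segmentation_params(max_area_bins = 200L, min_total_umi = 10L)
  lab_s <- expand_cores(cores, sm_t, raw_t, p_small)
  sizes <- tabulate(lab_s[lab_s > 0])
  expect_true(all(sizes <= 200L))
})

test_that("a core with no surrounding signal expands to itself", {
  g <- grid_spec(80, 80)
  one <- make_blob_spots(rbind(c(40, 40)), 600, g)
  raw <- build_density(one, "unspliced")
  sm <- smooth_density(raw, 4)
  p <- segmentation_params(sigma_bins = 4)
  cores <- detect_cores(sm, raw, p)
  # total signal == unspliced signal here, so the growth substrate equals
  # the core's own foreground: the cellbin must equal the core
  lab <- expand_cores(cores, sm, raw, p)
  attr(lab, "geodesic") <- NULL
  expect_identical(lab, cores)
})

test_that("assign_spots conserves UMI and computes per-cellbin summaries", {
  g <- grid_spec(10, 10)
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L   # y 1..3, x 1..3
  labels[7:9, 7:9] <- 2L
  st <- spot_table(c("a", "b", "c", "d"),
                   c(2L, 3L, 7L, 0L), c(2L, 2L, 7L, 0L),
                   c("g1", "mt-Nd4", "g1", "g2"),
                   c("spliced", "unspliced", "spliced", "spliced"),
                   c(4L, 1L, 2L, 9L), g)
  res <- assign_spots(labels, st)
  cb <- res$cellbins
  expect_equal(nrow(cb), 2)
  expect_equal(cb$area_bins, c(9L, 9L))
  expect_equal(cb$centroid_x, c(2, 7))
  expect_equal(cb$centroid_y, c(2, 7))
  expect_equal(cb$total_umi, c(5L, 2L))
  expect_equal(cb$n_genes, c(2L, 1L))
  expect_equal(cb$mito_fraction, c(0.2, 0))
  expect_equal(nrow(res$unassigned), 1)
  expect_equal(res$unassigned$umi_count, 9L)
  # conservation, and matrix row totals match
  expect_equal(sum(cb$total_umi) + sum(res$unassigned$umi_count),
               sum(st$umi_count))
  expect_equal(unname(Matrix::rowSums(res$matrix$counts)),
               as.numeric(cb$total_umi))

  set.seed(44)
  st2 <- random_spot_table(300, g)
  res2 <- assign_spots(labels, st2)
  expect_equal(sum(res2$cellbins$total_umi) + sum(res2$unassigned$umi_count),
               sum(st2$umi_count))
})

test_that("segmentation is deterministic and scale-equivariant", {
  sc <- small_scene_spec(seed = 2)
  scene <- generate_scene(sc)
  a <- segment_cellbins(scene$spots)
  b <- segment_cellbins(scene$spots)
  expect_identical(a$labels, b$labels)

  # doubling every count with doubled UMI thresholds preserves boundaries
  doubled <- data.table::copy(scene$spots)
  doubled[, umi_count := umi_count * 2L]
  data.table::setattr(doubled, "grid", attr(scene$spots, "grid"))
  data.table::setattr(doubled, "class", class(scene$spots))
  p2 <- segmentation_params(min_core_umi = 100L, min_total_umi = 200L)
  d <- segment_cellbins(doubled, p2)
  expect_identical(d$labels, a$labels)

  expect_error(segment_cellbins(scene$spots[0]), "empty")
})

test_that("cellbins partition the plane and contain their cores", {
  cached <- default_scene_cached()
  seg <- cached$seg
  core_px <- which(seg$cores > 0)
  expect_true(all(seg$labels[core_px] > 0))
  # core label k maps to exactly one cellbin label
  map <- unique(data.frame(core = seg$cores[core_px],
                           cell = seg$labels[core_px]))
  expect_false(any(duplicated(map$core)))
  # constraint compliance on the default parameters
  sizes <- tabulate(seg$labels[seg$labels > 0])
  expect_true(all(sizes <= segmentation_params()$max_area_bins))
  expect_true(all(seg$cellbins$total_umi >=
                    segmentation_params()$min_total_umi))
})
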