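test_that("nucleus segmentation counts cells and applies the inclusive area bound", {
  img <- generate_tissue_image(image_params(n_cells = 9, rng_seed = 6))
  nuc <- segment_nuclei(img$channels$dapi)
  expect_equal(max(nuc), 9)
  expect_warning(z <- segment_nuclei(matrix(3, 50, 50)), "uniform")
  expect_equal(max(z), 0)
  # a 25 x 20 px block at 0.1 um/px is exactly 5.0 um^2: retained
  im <- matrix(0, 60, 60); im[10:34, 10:29] <- 100
  expect_equal(max(segment_nuclei(im)), 1)
  # a 24 x 20 px block (4.8 um^2) falls below the bound
  im2 <- matrix(0, 60, 60); im2[10:33, 10:29] <- 100
  expect_warning(out <- segment_nuclei(im2), "minimum area")
  expect_equal(max(out), 0)
})

test_that("watershed segments partition the foreground with one seed each", {
  img <- generate_tissue_image(image_params(n_cells = 12, rng_seed = 3))
  nuc <- segment_nuclei(img$channels$dapi)
  lab <- watershed_cells(img$channels$wga, nuc)
  expect_equal(sort(unique(lab[lab > 0])), 1:12)
  for (i in 1:12) {
    seeds_in <- unique(nuc[lab == i])
    expect_equal(setdiff(seeds_in, 0L), i)
  }
  expect_error(watershed_cells(img$channels$wga, matrix(0L, 10, 10)), "no seeds")
})

test_that("actinin threshold is the histogram mode plus one SD", {
  set.seed(2)
  img <- matrix(sample(c(rep(10, 900), round(rnorm(100, 60, 5)))), 50, 20)
  sa <- segment_actinin(img)
  expect_equal(sa$mode, 10.5, tolerance = 0.51)  # mode bin of width 1
  expect_equal(sa$threshold, sa$mode + sd(as.vector(img)), tolerance = 1e-12)
  expect_warning(e <- segment_actinin(matrix(7, 10, 10)), "constant")
  expect_false(any(e$mask))
})

test_that("cell geometry matches analytic values for simple shapes", {
  lab <- matrix(0L, 120, 40)
  lab[11:110, 16:25] <- 1L   # 100 x 10 px rectangle along x
  g <- cell_morphology(lab, pixel_size = 0.1)
  expect_equal(g$area_um2, 10)
  expect_equal(g$length_um, 10)
  expect_equal(g$width_um, 1)
  expect_equal(g$orientation_deg, 0, tolerance = 1e-9)
  # rotated ellipse from the generator recovers its orientation
  img <- generate_tissue_image(image_params(n_cells = 1, orientation_mean = 30,
                                            orientation_sd = 0, rng_seed = 2))
  g2 <- cell_morphology(img$labels)
  expect_equal(g2$orientation_deg, 30, tolerance = 0.5)
  # a disc is flagged isotropic
  d <- matrix(0L, 60, 60)
  xy <- expand.grid(x = 1:60, y = 1:60)
  d[as.matrix(xy[(xy$x - 30)^2 + (xy$y - 30)^2 <= 400, ])] <- 1L
  g3 <- cell_morphology(d)
  expect_true(g3$isotropic)
  expect_equal(g3$length_um, g3$width_um, tolerance = 0.1)
})

test_that("neighbor graph reports 1st and 2nd degree adjacency correctly", {
  lab <- matrix(0L, 40, 12)
  lab[1:10, 2:11] <- 1L; lab[11:20, 2:11] <- 2L
  lab[21:30, 2:11] <- 3L; lab[31:40, 2:11] <- 4L
  g <- neighbor_graph(lab)
  expect_equal(g$first[[2]], c(1L, 3L))
  expect_equal(g$second[[2]], 4L)
  # isolated cell
  iso <- matrix(0L, 20, 20); iso[5:8, 5:8] <- 1L
  gi <- neighbor_graph(iso)
  expect_length(gi$first[[1]], 0)
  expect_length(gi$second[[1]], 0)
})

test_that("adjacency equals the brute-force pairwise boundary scan", {
  img <- generate_tissue_image(image_params(n_cells = 9, mean_cell_length = 6,
                                            mean_cell_width = 3, rng_seed = 8,
                                            nucleus_area_mean = 4))
  # grow labels into a closed mask so segments touch
  nuc <- segment_nuclei(img$channels$dapi, min_area_um2 = 2)
  lab <- watershed_cells(img$channels$wga, nuc, close_radius_um = 3)
  g <- neighbor_graph(lab)
  adj <- adjacency_oracle(lab)
  for (i in seq_len(max(lab)))
    expect_equal(g$first[[i]], which(adj[i, ]))
})

test_that("axial dispersion treats angles modulo 180 degrees", {
  expect_equal(axial_sd(c(10, 10, 10)), 0)
  # {0, 170} are 10 degrees apart axially: deviations +-5, not +-85
  expect_equal(axial_sd(c(0, 170)), sd(c(-5, 5)))
  g <- list(first = list(2L, 1L), second = list(integer(0), integer(0)))
  d <- local_dispersion(c(0, 170), g, min_set = 2)
  expect_equal(d, rep(sd(c(-5, 5)), 2))
  # too-small neighborhoods are NA
  expect_true(all(is.na(local_dispersion(c(0, 170), g, min_set = 3))))
})

test_that("raising either myocyte filter threshold never increases retention", {
  cells <- data.frame(actinin_area_fraction = c(0.10, 0.05, 0.08, 0.07),
                      nucleus_area_um2 = c(6, 10, 4, 5))
  f <- filter_myocytes(cells)
  expect_equal(nrow(f), 2)          # rows 1 and 4; inclusive bounds keep (0.07, 5)
  expect_true(all(rownames(f) %in% c("1", "4")))
  grid_a <- seq(0, 0.15, by = 0.01)
  counts <- vapply(grid_a, function(a) nrow(filter_myocytes(cells, a)), 0L)
  expect_true(all(diff(counts) <= 0))
  grid_n <- seq(0, 12, by = 1)
  counts_n <- vapply(grid_n, function(n0)
    nrow(filter_myocytes(cells, min_nucleus_area_um2 = n0)), 0L)
  expect_true(all(diff(counts_n) <= 0))
})

test_that("sarcomere estimation gates on striation clarity and cell length", {
  img <- generate_tissue_image(image_params(n_cells = 4, myocyte_fraction = 1,
                                            sarcomere_period = 1.87,
                                            orientation_sd = 0, rng_seed = 9))
  cells <- cell_morphology(img$labels)
  sl <- sarcomere_length(img$channels$actinin, img$labels, cells[1, ])
  expect_equal(sl$sarcomere_um, 1.87, tolerance = 0.03)
  # a cell without striations is reported missing
  flat <- matrix(5, nrow(img$labels), ncol(img$labels))
  sl2 <- sarcomere_length(flat, img$labels, cells[1, ])
  expect_true(is.na(sl2$sarcomere_um))
  expect_equal(sl2$reason, "no striation")
  # a cell much shorter than three periods is rejected with a reason
  tiny <- cells[1, ]; tiny$length_um <- 3
  sl3 <- sarcomere_length(img$channels$actinin, img$labels, tiny)
  expect_match(sl3$reason, "shorter than 3 periods")
})

test_that("cross-section stats report the actinin-positive fraction", {
  mask <- matrix(FALSE, 10, 10); mask[1:4, ] <- TRUE
  cs <- cross_section_stats(mask, pixel_size = 0.1)
  expect_equal(cs$fraction, 0.4)
  expect_equal(cs$actinin_area_um2, 0.4)
  expect_equal(cross_section_stats(mask & FALSE)$fraction, 0)
})

test_that("rotating the image by 90 degrees shifts orientations by 90 mod 180", {
  img <- generate_tissue_image(image_params(n_cells = 6, orientation_sd = 15,
                                            rng_seed = 10))
  g1 <- cell_morphology(img$labels)
  rot <- t(img$labels)[ncol(img$labels):1, ]   # 90 degree rotation
  g2 <- cell_morphology(rot)
  o1 <- g1$orientation_deg[order(g1$cell)]
  o2 <- g2$orientation_deg[order(g2$cell)]
  expect_true(all(axial_diff(o1 + 90, o2) < 0.2))
  expect_equal(g2$area_um2[order(g2$cell)], g1$area_um2[order(g1$cell)])
  expect_equal(g2$length_um[order(g2$cell)], g1$length_um[order(g1$cell)],
               tolerance = 1e-6)
})
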