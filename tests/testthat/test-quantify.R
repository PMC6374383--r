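test_that("intensity binning matches the label-retention grading scheme", {
  expect_identical(as.character(classify_bin(c(50, 150, 220))),
                   c("low", "mid", "high"))
  # boundary convention: half-open bins, uppermost closed
  expect_identical(as.character(classify_bin(c(100, 200, 0, 255))),
                   c("mid", "high", "low", "high"))
  # full 8-bit enumeration against the comparison-chain oracle
  got <- as.character(classify_bin(0:255))
  want <- vapply(0:255, oracle_bin, character(1))
  expect_identical(got, want)
  expect_error(classify_bin(-1), "outside")
  expect_error(classify_bin(256), "outside")
  expect_error(intensity_bins(c(0, 200, 100, 255)))
})

test_that("percentages reproduce the printed worked example", {
  expect_identical(bin_percentages(c(low = 40, mid = 31, high = 20)),
                   c(low = 44L, mid = 34L, high = 22L))
  expect_identical(sum(c(40, 31, 20)), 91)
  expect_identical(bin_percentages(c(low = 0, mid = 0, high = 0)),
                   c(low = 0L, mid = 0L, high = 0L))
})

test_that("report conservation laws hold on arbitrary object tables", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    df <- data.frame(id = seq_len(n),
                     mean_GFP = round(runif(n, 0, 255), 2),
                     mean_DAPI = runif(n, 100, 250))
    rep <- count_subpopulations(df)
    expect_identical(sum(rep$per_bin), rep$lrc_total)
    expect_lte(rep$lrc_total, rep$total_nuclei)
    expect_identical(rep$total_nuclei, n)
  }
  # all objects in one bin
  df <- data.frame(mean_GFP = rep(250, 7))
  rep <- count_subpopulations(df)
  expect_identical(unname(rep$per_bin), c(0L, 0L, 7L))
  expect_identical(unname(rep$per_bin_pct), c(0L, 0L, 100L))
  # no LRCs at all: flagged, percentages zero, no division error
  none <- count_subpopulations(data.frame(mean_GFP = rep(0, 4)))
  expect_true(none$flag_no_lrc)
  expect_identical(unname(none$per_bin_pct), c(0L, 0L, 0L))
})

test_that("3-D labeling agrees with a brute-force flood fill", {
  set.seed(21)
  for (i in 1:6) {
    d <- c(sample(3:6, 1), sample(3:7, 1), sample(3:7, 1))
    mask <- array(runif(prod(d)) < 0.35, d)
    got <- array(iftomo:::.label_cc_3d(as.vector(mask), as.integer(d)), d)
    want <- oracle_cc_3d(mask)
    # same partition: label images must be equal up to relabeling
    expect_identical(max(got), max(want))
    expect_identical(got == 0L, want == 0L)
    if (max(got) > 0) {
      key <- tapply(want[mask], got[mask], function(v) length(unique(v)))
      expect_true(all(key == 1))
    }
  }
})

test_that("a single sphere segments to one object at its true centre", {
  cfg <- analytic_phantom_config(n_cells = 1L, seed = 2L,
                                 tissue_extent = c(30, 30, 16))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  obj <- segment_nuclei(vol, "DAPI", threshold = 50, min_volume_voxels = 5)
  expect_identical(nrow(obj$objects), 1L)
  expect_lt(abs(obj$objects$x_um - ph$truth$cells$x), 0.44)
  expect_lt(abs(obj$objects$y_um - ph$truth$cells$y), 0.44)
  expect_lt(abs(obj$objects$z_um - ph$truth$cells$z), 2)
})

test_that("non-touching nuclei are counted exactly; empty volumes give none", {
  cfg <- analytic_phantom_config(n_cells = 30L, seed = 14L)
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  obj <- segment_nuclei(vol, "DAPI", threshold = 50,
                        min_volume_voxels = min_nucleus_volume_voxels(3, 0.44, 2))
  expect_identical(nrow(obj$objects), 30L)

  empty <- assemble(list(section_image(array(0, c(10, 10, 1)), "DAPI")),
                    thickness = 2)
  expect_identical(nrow(segment_nuclei(empty, "DAPI", threshold = 10)$objects), 0L)
})

test_that("noise-free quantification equals brute force on the truth table", {
  cfg <- analytic_phantom_config(n_cells = 60L, seed = 25L,
                                 tissue_extent = c(110, 110, 40))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  obj <- segment_nuclei(vol, "DAPI", threshold = 50,
                        min_volume_voxels = min_nucleus_volume_voxels(3, 0.44, 2))
  rep <- count_subpopulations(obj)
  want <- oracle_truth_report(ph$truth)
  expect_identical(rep$total_nuclei, want$total)
  expect_identical(rep$lrc_total, want$lrc_total)
  expect_identical(rep$per_bin, want$per_bin)
})

test_that("otsu thresholding separates nuclei from background", {
  cfg <- phantom_config(n_cells = 20L, seed = 16L, noise_sd = 2,
                        misalignment_range = c(0, 0, 0),
                        tissue_extent = c(60, 60, 20))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  obj <- segment_nuclei(vol, "DAPI", threshold = "otsu",
                        min_volume_voxels = min_nucleus_volume_voxels(3, 0.44, 2))
  expect_gt(obj$threshold_used, 5)   # above background
  expect_lt(obj$threshold_used, 150) # below the dimmest nucleus interior
  expect_identical(nrow(obj$objects), 20L)
})

test_that("raising the threshold never grows the foreground", {
  cfg <- phantom_config(n_cells = 15L, seed = 18L, tissue_extent = c(50, 50, 16))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  fg <- vapply(c(20, 60, 120, 180), function(t)
    sum(get_volume_channel(vol, "DAPI") > t), numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("the three-threshold mean count behaves like its definition", {
  cfg <- analytic_phantom_config(n_cells = 12L, seed = 8L,
                                 tissue_extent = c(60, 60, 20))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  minv <- min_nucleus_volume_voxels(3, 0.44, 2)
  mt <- multi_threshold_count(vol, "DAPI", c(40, 80, 120), minv)
  expect_identical(mt$mean_count, mean(mt$counts))
  expect_identical(mt$mean_count, 12)
  same <- multi_threshold_count(vol, "DAPI", c(80, 80, 80), minv)
  expect_identical(same$mean_count,
                   nrow(segment_nuclei(vol, "DAPI", 80, minv)$objects) + 0)
  expect_error(multi_threshold_count(vol, "DAPI", c(120, 80, 40)), "thresholds")
  expect_error(multi_threshold_count(vol, "DAPI", c(40, 80)), "three")
})

test_that("reports serialize with per-object bins", {
  cfg <- analytic_phantom_config(n_cells = 10L, seed = 6L,
                                 tissue_extent = c(50, 50, 20))
  ph <- generate_phantom(cfg)
  vol <- assemble(ph$sections, thickness = 2)
  obj <- segment_nuclei(vol, "DAPI", 50,
                        min_nucleus_volume_voxels(3, 0.44, 2))
  rep <- count_subpopulations(obj)
  dir <- withr::local_tempdir()
  write_report(obj, rep, dir)
  csv <- utils::read.csv(file.path(dir, "objects.csv"))
  expect_identical(nrow(csv), 10L)
  expect_true(all(csv$bin %in% c("low", "mid", "high", "non_lrc")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  expect_equal(js$total_nuclei, rep$total_nuclei)
  expect_equal(js$lrc_total, rep$lrc_total)
})
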