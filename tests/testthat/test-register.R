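test_that("self-registration returns the identity with a perfect score", {
  img <- get_channel(dense_section(), "DAPI")
  res <- register_pair(img, img, max_rotation = 3)
  expect_lt(abs(res$transform$tx), 0.1)
  expect_lt(abs(res$transform$ty), 0.1)
  expect_lt(abs(res$transform$theta), 0.1)
  expect_gt(res$score, 0.98)
  expect_false(res$flagged)
})

test_that("a known rigid displacement is recovered within 0.5 px / 0.25 deg", {
  img <- get_channel(dense_section(), "DAPI")
  applied <- rigid_transform(5, -3, 2)
  moving <- warp_rigid(img, applied)
  res <- register_pair(img, moving, max_rotation = 5)
  want <- rt_inverse(applied)
  expect_lt(abs(res$transform$tx - want$tx), 0.5)
  expect_lt(abs(res$transform$ty - want$ty), 0.5)
  expect_lt(abs(res$transform$theta - want$theta), 0.25)
})

test_that("independent noise images are flagged and get the identity", {
  set.seed(6)
  a <- matrix(rnorm(256 * 256, 50, 10), 256, 256)
  b <- matrix(rnorm(256 * 256, 50, 10), 256, 256)
  expect_warning(res <- register_pair(a, b, max_rotation = 2,
                                      max_translation = 12),
                 "confidence floor")
  expect_identical(unclass(res$transform), unclass(rt_identity()))
  expect_identical(res$score, 0)
  expect_true(res$flagged)
})

test_that("zero-variance images cannot be registered", {
  expect_error(register_pair(matrix(3, 32, 32), matrix(5, 32, 32)),
               "zero-variance")
})

test_that("registration is symmetric within tolerance", {
  cfg <- phantom_config(n_cells = 60L, seed = 13L, noise_sd = 3,
                        misalignment_range = c(6, 6, 3), non_touching = FALSE,
                        tissue_extent = c(56.32, 56.32, 12))
  ph <- generate_phantom(cfg)
  a <- get_channel(ph$sections[[2]], "DAPI")
  b <- get_channel(ph$sections[[3]], "DAPI")
  ab <- register_pair(a, b, max_rotation = 8)$transform
  ba <- register_pair(b, a, max_rotation = 8)$transform
  inv <- rt_inverse(ba)
  expect_lt(abs(ab$tx - inv$tx), 0.5)
  expect_lt(abs(ab$ty - inv$ty), 0.5)
  expect_lt(abs(ab$theta - inv$theta), 0.25)
})

test_that("stacks of identical sections align to the identity", {
  sec <- dense_section()
  res <- align_stack(list(sec, sec, sec), max_rotation = 2)
  for (t in res$absolute) {
    expect_lt(abs(t$tx), 0.1)
    expect_lt(abs(t$ty), 0.1)
    expect_lt(abs(t$theta), 0.1)
  }
})

test_that("two sections give one pairwise transform and a chained absolute", {
  cfg <- phantom_config(n_cells = 40L, seed = 19L, non_touching = FALSE,
                        tissue_extent = c(56.32, 56.32, 16))
  ph <- generate_phantom(cfg)
  res <- align_stack(ph$sections[1:2], max_rotation = 4)
  expect_null(res$pairwise[[1]])
  expect_identical(unclass(res$absolute[[1]]), unclass(rt_identity()))
  expect_identical(unclass(res$absolute[[2]]), unclass(res$pairwise[[2]]))
})

test_that("chaining consistency holds exactly as stored", {
  cfg <- phantom_config(n_cells = 60L, seed = 23L, noise_sd = 3,
                        misalignment_range = c(5, 5, 2), non_touching = FALSE,
                        tissue_extent = c(56.32, 56.32, 16))
  ph <- generate_phantom(cfg)
  res <- align_stack(ph$sections, max_rotation = 6)
  for (i in 2:length(res$absolute)) {
    want <- rt_compose(res$absolute[[i - 1]], res$pairwise[[i]])
    expect_equal(unclass(res$absolute[[i]]), unclass(want), tolerance = 1e-9)
  }
})

test_that("known per-section misalignments are recovered on a phantom stack", {
  cfg <- phantom_config(n_cells = 60L, seed = 29L, noise_sd = 3,
                        misalignment_range = c(6, 6, 2),
                        tissue_extent = c(80, 80, 30))
  ph <- generate_phantom(cfg)
  res <- align_stack(ph$sections, max_rotation = 6, max_translation = 20)
  errs <- t(vapply(seq_along(res$absolute), function(i) {
    want <- rt_inverse(ph$truth$section_transforms[[i]])
    got <- res$absolute[[i]]
    c(sqrt((got$tx - want$tx)^2 + (got$ty - want$ty)^2),
      abs(got$theta - want$theta))
  }, numeric(2)))
  expect_lt(mean(errs[, 1]), 0.5)
  expect_lt(mean(errs[, 2]), 0.5)
})

test_that("transform serialization round-trips", {
  cfg <- phantom_config(n_cells = 40L, seed = 31L, non_touching = FALSE,
                        misalignment_range = c(4, 4, 1),
                        tissue_extent = c(44, 44, 16))
  ph <- generate_phantom(cfg)
  res <- align_stack(ph$sections, max_rotation = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_transforms(res, path)
  back <- read_transforms(path)
  expect_identical(back$reference_index, 1L)
  for (i in 2:length(res$absolute))
    expect_equal(unclass(back$absolute[[i]]), unclass(res$absolute[[i]]),
                 tolerance = 1e-12)
})

test_that("re-probe fusion carries round-1 channels plus new round-2 channels", {
  sec <- dense_section()
  dapi <- get_channel(sec, "DAPI")
  gfp <- get_channel(sec, "GFP")
  h <- nrow(dapi); w <- ncol(dapi)
  mk <- function(chs, imgs) {
    data <- array(0, dim = c(h, w, length(chs)))
    for (k in seq_along(imgs)) data[, , k] <- imgs[[k]]
    section_image(data, chs, sec$pixel_size, sec$thickness, 1L)
  }
  r1 <- mk(c("DAPI", "K5", "PPARg"), list(dapi, gfp, dapi * 0.5))
  r2 <- mk(c("DAPI", "K6", "Ki67"), list(dapi, dapi * 0.3, gfp * 0.8))
  fused <- fuse_reprobe(r1, r2)
  expect_identical(fused$channels, c("DAPI", "K5", "PPARg", "K6", "Ki67"))
  expect_identical(dim(fused$data)[3], 5L)

  # identical rounds: identity transform, clashing names suffixed
  same <- fuse_reprobe(r1, r1)
  tr <- attr(same, "fuse_transform")
  expect_lt(abs(tr$tx) + abs(tr$ty) + abs(tr$theta), 0.2)
  expect_identical(same$channels, c("DAPI", "K5", "PPARg", "K5_r2", "PPARg_r2"))

  # a shifted second round is realigned onto round 1
  shift <- rigid_transform(4, 4, 0)
  r2s <- mk(c("DAPI", "K6"), list(warp_rigid(dapi, shift),
                                  warp_rigid(dapi * 0.3, shift)))
  fused2 <- fuse_reprobe(r1, r2s)
  tr2 <- attr(fused2, "fuse_transform")
  expect_lt(abs(tr2$tx + 4), 0.5)
  expect_lt(abs(tr2$ty + 4), 0.5)
  interior <- as.matrix(expand.grid(20:100, 20:100))
  expect_lt(max(abs(fused2$data[, , 4][interior] - (dapi * 0.3)[interior])), 20)
})

test_that("unregistrable re-probe rounds refuse to fuse", {
  set.seed(10)
  h <- 256; w <- 256
  mk <- function(img) section_image(array(img, c(h, w, 1)), "DAPI")
  r1 <- mk(matrix(rnorm(h * w, 50, 10), h, w))
  r2 <- mk(matrix(rnorm(h * w, 50, 10), h, w))
  expect_error(suppressWarnings(fuse_reprobe(r1, r2, max_rotation = 2,
                                             max_translation = 12)),
               "refusing to fuse")
})
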