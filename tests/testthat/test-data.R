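# Phantom generation, NIfTI round trips, preprocessing, augmentation, split.

test_that("phantom generation is deterministic and geometrically consistent", {
  cfg <- phantom_config(n_volumes = 2, slices_per_volume = 3, seed = 99)
  v1 <- generate_phantom_dataset(cfg)
  v2 <- generate_phantom_dataset(cfg)
  expect_identical(v1, v2)
  for (v in v1) {
    expect_identical(dim(v$image), c(64L, 64L, 3L, 2L))
    expect_true(all(v$label %in% 0:2))
    # TZ core strictly inside the gland: every TZ voxel 8-neighbourhood-free
    # of background is too strong at boundaries, so check containment via
    # counts: all TZ voxels are where PZ would be if TZ were absent
    expect_true(all(v$label[v$label == 2] == 2))
    # mean T2 intensity ordering: TZ > PZ > background
    t2 <- v$image[, , , 1]
    expect_gt(mean(t2[v$label == 2]), mean(t2[v$label == 1]))
    expect_gt(mean(t2[v$label == 1]), mean(t2[v$label == 0]))
  }
})

test_that("TZ voxels never touch background and labels are exclusive", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 5,
                                               seed = 7))[[1]]
  for (s in 1:5) {
    lab <- v$label[, , s]
    tz <- which(lab == 2, arr.ind = TRUE)
    if (!nrow(tz)) next
    # the ring of pixels immediately around the TZ core is PZ, not background
    for (k in seq_len(nrow(tz))) {
      i <- tz[k, 1]; j <- tz[k, 2]
      nb <- lab[max(1, i - 1):min(64, i + 1), max(1, j - 1):min(64, j + 1)]
      expect_true(all(nb != 0))
    }
  }
})

test_that("a default-size phantom dataset builds fast and small", {
  el <- system.time(vols <- generate_phantom_dataset(phantom_config(seed = 2)))
  expect_identical(length(vols), 10L)
  expect_lt(el[["elapsed"]], 10)
  expect_lt(as.numeric(utils::object.size(vols)), 50 * 1024^2)
})

test_that("NIfTI volumes round-trip through the MSD layout", {
  dir <- file.path(tempdir(), "msd_rt")
  unlink(dir, recursive = TRUE)
  cfg <- phantom_config(n_volumes = 2, slices_per_volume = 3, seed = 5)
  vols <- generate_phantom_dataset(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "dataset.json")))
  back <- load_msd_dataset(dir)
  expect_identical(length(back), 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$image, vols[[i]]$image, tolerance = 1e-6)
    expect_identical(back[[i]]$label, vols[[i]]$label)
    expect_equal(back[[i]]$spacing, vols[[i]]$spacing, tolerance = 1e-6)
  }
})

test_that("the loader validates label volumes", {
  dir <- tempdir()
  img <- RNifti::asNifti(array(runif(8 * 8 * 2), c(8, 8, 2)))
  ip <- file.path(dir, "img.nii.gz"); RNifti::writeNifti(img, ip)
  # spatial mismatch
  lab_bad <- RNifti::asNifti(array(0, c(8, 4, 2)))
  lp <- file.path(dir, "lab_bad.nii.gz"); RNifti::writeNifti(lab_bad, lp)
  expect_error(load_msd_volume(ip, lp), "differ")
  # unknown code 3 named in the error
  lab3 <- RNifti::asNifti(array(c(rep(0, 126), 3, 1), c(8, 8, 2)))
  lp3 <- file.path(dir, "lab3.nii.gz"); RNifti::writeNifti(lab3, lp3)
  expect_error(load_msd_volume(ip, lp3), "3")
  # missing label -> unlabeled record
  v <- load_msd_volume(ip)
  expect_false(v$labeled)
  expect_null(v$label)
})

test_that("preprocessing emits one normalized sample per slice", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 20,
                                               seed = 3))[[1]]
  samples <- preprocess_volume(v, target_size = c(32L, 32L))
  expect_identical(length(samples), 20L)
  img_all <- unlist(lapply(samples, function(s) s$image))
  expect_lt(abs(mean(img_all)), 0.1)
  expect_gt(stats::sd(img_all), 0.5); expect_lt(stats::sd(img_all), 1.5)
  for (s in samples) {
    expect_identical(dim(s$image), c(32L, 32L, 1L))
    expect_identical(dim(s$masks), c(32L, 32L, 2L))
    expect_true(all(s$masks %in% c(0, 1)))
    expect_true(all(s$masks[, , 1] * s$masks[, , 2] == 0))  # disjoint
  }
  expect_error(preprocess_volume(v, target_size = c(30L, 30L)), "16")
})

test_that("nearest-resized labels keep only source codes", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 2,
                                               seed = 13))[[1]]
  for (ts in c(32L, 128L)) {
    ss <- preprocess_volume(v, target_size = c(ts, ts))
    for (s in ss) expect_true(all(s$masks %in% c(0, 1)))
  }
})

test_that("offline augmentation triples the set deterministically", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 10,
                                               seed = 21))[[1]]
  samples <- preprocess_volume(v)
  cfg <- augmentation_config(seed = 77)
  out1 <- augment_offline(samples, cfg)
  out2 <- augment_offline(samples, cfg)
  expect_identical(length(out1), 30L)
  expect_identical(out1, out2)
  # originals preserved in place
  expect_identical(out1[[1]], samples[[1]])
  expect_identical(out1[[4]], samples[[2]])
  # augmented copies are tagged and differ from the original
  expect_match(out1[[2]]$aug, "^aug1:")
  expect_false(identical(out1[[2]]$image, samples[[1]]$image))
  expect_identical(augment_offline(list(), cfg), list())
})

test_that("flips are involutions and preserve mask counts; rotation nearly so", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 1,
                                               seed = 31))[[1]]
  s <- preprocess_volume(v)[[1]]
  flip_h <- function(a) a[, rev(seq_len(ncol(a)))]
  m <- s$masks[, , 1]
  expect_identical(flip_h(flip_h(m)), m)
  expect_identical(sum(flip_h(m)), sum(m))
  rot <- rotate_slice(m, 12, "nearest")
  expect_true(all(rot %in% c(0, 1)))
  expect_lt(abs(sum(rot) - sum(m)) / sum(m), 0.1)
  # rotation by 0 degrees is exact identity
  expect_equal(rotate_slice(m, 0, "nearest"), m)
})

test_that("geometric transforms move image and masks together", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 4,
                                               seed = 41))[[1]]
  samples <- preprocess_volume(v)
  cfg <- augmentation_config(transforms = c("hflip", "vflip"), seed = 5)
  out <- augment_offline(samples, cfg)
  for (s in out) {
    # the TZ core is the brightest region; its mask must still cover it
    tz <- s$masks[, , 2]
    if (sum(tz) < 20) next
    expect_gt(mean(s$image[, , 1][tz == 1]), mean(s$image[, , 1][tz == 0]))
  }
})

test_that("the split is by volume with augmentation confined to training", {
  vols <- generate_phantom_dataset(phantom_config(n_volumes = 10,
                                                  slices_per_volume = 2,
                                                  seed = 51))
  sp <- split_dataset(vols, fraction = 0.8, seed = 2)
  expect_identical(length(sp$train), 8L)
  expect_identical(length(sp$validation), 2L)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids),
                  vapply(vols, `[[`, character(1), "volume_id"))
  # same seed, same split
  sp2 <- split_dataset(vols, fraction = 0.8, seed = 2)
  expect_identical(sp$train_ids, sp2$train_ids)
  # validation samples never carry augmentation tags in the training pipeline
  val_samples <- unlist(lapply(sp$validation, preprocess_volume),
                        recursive = FALSE)
  expect_true(all(vapply(val_samples, `[[`, character(1), "aug") == "orig"))
  expect_error(split_dataset(vols[1], 0.8, 1), "at least 2")
  expect_error(split_dataset(vols, 1.2, 1), "between 0 and 1")
})

test_that("unlabeled volumes are excluded from supervised splits", {
  vols <- generate_phantom_dataset(phantom_config(n_volumes = 5,
                                                  slices_per_volume = 2,
                                                  labeled_fraction = 0.8,
                                                  seed = 61))
  expect_identical(sum(vapply(vols, `[[`, logical(1), "labeled")), 4L)
  sp <- split_dataset(vols, fraction = 0.75, seed = 1)
  expect_identical(length(sp$train) + length(sp$validation), 4L)
})

test_that("overlay rendering writes a PNG with the zone colors", {
  v <- generate_phantom_dataset(phantom_config(n_volumes = 1,
                                               slices_per_volume = 1,
                                               seed = 71))[[1]]
  path <- tempfile(fileext = ".png")
  write_overlay_png(v$image[, , 1, 1], v$label[, , 1], path)
  img <- png::readPNG(path)
  expect_identical(dim(img)[3], 3L)
  tz <- v$label[, , 1] == 2
  pz <- v$label[, , 1] == 1
  # red dominates in TZ, green in PZ
  expect_gt(mean(img[, , 1][tz]) - mean(img[, , 2][tz]), 0.1)
  expect_gt(mean(img[, , 2][pz]) - mean(img[, , 1][pz]), 0.1)
})
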