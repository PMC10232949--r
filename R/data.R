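# Data handling: synthetic prostate phantoms, NIfTI volume I/O in the Medical
# Segmentation Decathlon (MSD) layout, per-volume preprocessing into 2-D slice
# samples, offline augmentation, and the by-volume train/validation split.

# ---------------------------------------------------------------------------
# deterministic RNG scoping
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# ---------------------------------------------------------------------------
# phantom generator

#' Phantom dataset configuration
#'
#' The phantom emulates the geometry the network is meant to segment: per
#' slice, a bright elliptical transition-zone (TZ) core nested inside a
#' peripheral-zone (PZ) annulus of intermediate intensity on a dark noisy
#' background, with the zone size tapering towards the first and last slices
#' the way a gland shrinks through-plane. Two modalities are written: a
#' T2-like channel (TZ > PZ > background) and an ADC-like channel with
#' inverted contrast.
#'
#' @param n_volumes Number of volumes.
#' @param slices_per_volume Axial slices per volume.
#' @param slice_size Square slice edge in pixels.
#' @param labeled_fraction Fraction of volumes that carry label volumes.
#' @param bg_mean,pz_mean,tz_mean T2-channel intensity means.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed; the full dataset is a pure function of the config.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(n_volumes = 10L, slices_per_volume = 15L,
                           slice_size = 64L, labeled_fraction = 1,
                           bg_mean = 0.20, pz_mean = 0.50, tz_mean = 0.80,
                           noise_sd = 0.05, seed = 1L) {
  stopifnot(n_volumes >= 1, slices_per_volume >= 1, slice_size >= 16)
  structure(list(n_volumes = as.integer(n_volumes),
                 slices_per_volume = as.integer(slices_per_volume),
                 slice_size = as.integer(slice_size),
                 labeled_fraction = labeled_fraction,
                 bg_mean = bg_mean, pz_mean = pz_mean, tz_mean = tz_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic prostate-phantom dataset
#'
#' Each volume gets a jittered zone geometry (PZ outer ellipse, TZ inner
#' ellipse with the same centre and strictly smaller axes, so TZ always lies
#' inside the PZ outer boundary and the label regions are disjoint by
#' construction), a per-slice through-plane size profile, and Gaussian noise.
#' Label codes: 0 background, 1 PZ annulus, 2 TZ core.
#'
#' @param cfg A [phantom_config()].
#' @param dir Optional directory; when given, volumes are written as NIfTI
#'   pairs in MSD layout (`imagesTr/`, `labelsTr/`, `dataset.json`).
#' @return List of volume records, each with `image` `(H, W, S, 2)` (T2 then
#'   ADC), integer `label` `(H, W, S)` (or `NULL` when unlabeled), `spacing`,
#'   `volume_id` and `labeled`.
#' @export
generate_phantom_dataset <- function(cfg = phantom_config(), dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$slice_size %% 16L != 0L)
    warning("slice size not divisible by 16; preprocessing will resize")
  n_lab <- round(cfg$labeled_fraction * cfg$n_volumes)
  vols <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_volumes), function(v) {
      make_phantom_volume(cfg, sprintf("phantom_%02d", v), labeled = v <= n_lab)
    })
  })
  if (!is.null(dir)) write_msd_dataset(vols, dir, cfg)
  vols
}

make_phantom_volume <- function(cfg, volume_id, labeled = TRUE) {
  n <- cfg$slice_size
  S <- cfg$slices_per_volume
  ci <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  cj <- n / 2 + stats::runif(1, -0.05, 0.05) * n
  a_pz <- stats::runif(1, 0.26, 0.34) * n   # PZ outer semi-axes
  b_pz <- stats::runif(1, 0.22, 0.30) * n
  tz_frac <- stats::runif(1, 0.45, 0.60)    # TZ axes as a fraction of PZ axes
  img <- array(0, c(n, n, S, 2L))
  lab <- array(0L, c(n, n, S))
  ii <- matrix(rep(seq_len(n), n), n, n)
  jj <- t(ii)
  mid <- (S + 1) / 2
  for (s in seq_len(S)) {
    prof <- sqrt(pmax(0.15, 1 - ((s - mid) / (0.65 * S))^2)) *
      (1 + stats::runif(1, -0.04, 0.04))
    ai <- a_pz * prof; bi <- b_pz * prof
    r_pz <- ((ii - ci) / ai)^2 + ((jj - cj) / bi)^2
    r_tz <- ((ii - ci) / (ai * tz_frac))^2 + ((jj - cj) / (bi * tz_frac))^2
    in_pz <- r_pz <= 1
    in_tz <- r_tz <= 1
    lab[, , s] <- ifelse(in_tz, 2L, ifelse(in_pz, 1L, 0L))
    t2 <- matrix(cfg$bg_mean, n, n)
    t2[in_pz] <- cfg$pz_mean
    t2[in_tz] <- cfg$tz_mean
    adc <- matrix(0.60, n, n)
    adc[in_pz] <- 0.55
    adc[in_tz] <- 0.35
    img[, , s, 1L] <- t2 + stats::rnorm(n * n, 0, cfg$noise_sd)
    img[, , s, 2L] <- adc + stats::rnorm(n * n, 0, cfg$noise_sd)
  }
  list(image = img, label = if (labeled) lab else NULL,
       spacing = c(0.6, 0.6, 4.0), volume_id = volume_id, labeled = labeled)
}

# ---------------------------------------------------------------------------
# NIfTI I/O (MSD layout)

write_msd_dataset <- function(vols, dir, cfg = NULL) {
  img_dir <- file.path(dir, "imagesTr")
  lab_dir <- file.path(dir, "labelsTr")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(vols, function(v) {
    ip <- file.path(img_dir, paste0(v$volume_id, ".nii.gz"))
    im <- RNifti::asNifti(v$image)
    RNifti::pixdim(im) <- c(v$spacing, 1)
    RNifti::writeNifti(im, ip)
    lp <- NULL
    if (v$labeled) {
      lp <- file.path(lab_dir, paste0(v$volume_id, ".nii.gz"))
      lb <- RNifti::asNifti(array(as.numeric(v$label), dim(v$label)))
      RNifti::pixdim(lb) <- v$spacing
      RNifti::writeNifti(lb, lp)
    }
    list(image = file.path("imagesTr", paste0(v$volume_id, ".nii.gz")),
         label = if (v$labeled) file.path("labelsTr", paste0(v$volume_id, ".nii.gz")))
  })
  manifest <- list(
    name = "SyntheticProstatePhantom",
    description = "synthetic TZ/PZ phantom volumes (not real MRI)",
    modality = list(`0` = "T2", `1` = "ADC"),
    labels = list(`0` = "background", `1` = "PZ", `2` = "TZ"),
    numTraining = length(entries),
    training = entries)
  if (!is.null(cfg)) manifest$generator <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load one MSD-style NIfTI volume
#'
#' Reads an image volume (3-D single-modality or 4-D with the modality axis
#' last: channel 1 T2, channel 2 ADC) and, when present, its integer label
#' volume, validating the label codes against the code map.
#'
#' @param image_path Path to the image NIfTI.
#' @param label_path Optional path to the label NIfTI; absent means an
#'   unlabeled volume.
#' @param label_codes Named integer map of zone codes in the label file.
#' @return A volume record (see [generate_phantom_dataset()]).
#' @export
load_msd_volume <- function(image_path, label_path = NULL,
                            label_codes = c(PZ = 1L, TZ = 2L)) {
  img <- RNifti::readNifti(image_path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # drop niftiImage attributes
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop(sprintf("unsupported image dimensionality: %d axes", length(dim(arr))),
         call. = FALSE)
  lab <- NULL
  if (!is.null(label_path)) {
    lraw <- as.array(RNifti::readNifti(label_path))
    lraw <- array(as.vector(lraw), dim(lraw))
    if (length(dim(lraw)) != 3L)
      stop("label volume must be 3-D", call. = FALSE)
    if (!all(dim(lraw) == dim(arr)[1:3]))
      stop(sprintf("image (%s) and label (%s) spatial dimensions differ",
                   paste(dim(arr)[1:3], collapse = "x"),
                   paste(dim(lraw), collapse = "x")), call. = FALSE)
    lab <- array(as.integer(round(lraw)), dim(lraw))
    allowed <- c(0L, as.integer(label_codes))
    bad <- setdiff(unique(as.vector(lab)), allowed)
    if (length(bad))
      stop(sprintf("unknown label code(s): %s (allowed: %s)",
                   paste(sort(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")), call. = FALSE)
  }
  list(image = arr, label = lab, spacing = as.numeric(spacing),
       volume_id = sub("\\.nii(\\.gz)?$", "", basename(image_path)),
       labeled = !is.null(lab))
}

#' Load an MSD-style dataset directory
#'
#' @param dir Directory containing `dataset.json` and the image/label files.
#' @return List of volume records.
#' @export
load_msd_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "dataset.json"))
  codes <- c(PZ = 1L, TZ = 2L)
  if (!is.null(mf$labels)) {
    lbl <- unlist(mf$labels)
    keep <- lbl != "background"
    codes <- stats::setNames(as.integer(names(lbl)[keep]), lbl[keep])
  }
  lapply(mf$training, function(e) {
    load_msd_volume(file.path(dir, e$image),
                    if (!is.null(e$label)) file.path(dir, e$label),
                    label_codes = codes)
  })
}

# ---------------------------------------------------------------------------
# preprocessing

resize_slice <- function(m, H, W, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (nrow(m) == H && ncol(m) == W) return(m)
  EBImage::resize(m, w = H, h = W,
                  filter = if (interp == "bilinear") "bilinear" else "none")
}

#' Preprocess one volume into 2-D slice samples
#'
#' Per-volume z-score normalization of the selected modality channels
#' (clipped to +/- 5 standard deviations), bilinear resizing of image slices
#' and nearest-neighbour resizing of label slices to `target_size`, and
#' expansion of the integer label into per-class binary masks (channel 1 PZ,
#' channel 2 TZ). The target size must be divisible by 16 so slices fit the
#' network's pooling lattice.
#'
#' @param v A volume record.
#' @param target_size `(H, W)` of the emitted slices.
#' @param modalities Indices of image channels to keep (default 1 = T2).
#' @return List of slice samples: `image` `(H, W, C)`, `masks` `(H, W, 2)`,
#'   `volume_id`, `slice`, `aug = "orig"`.
#' @export
preprocess_volume <- function(v, target_size = c(64L, 64L), modalities = 1L) {
  if (any(target_size %% 16L != 0L))
    stop("target_size must be divisible by 16", call. = FALSE)
  d <- dim(v$image)
  if (is.null(d) || length(d) != 4L || any(d == 0L) || d[3] == 0L)
    stop("empty or malformed volume", call. = FALSE)
  img <- v$image[, , , modalities, drop = FALSE]
  mu <- mean(img); sd <- stats::sd(as.vector(img))
  if (sd == 0) sd <- 1
  img <- pmin(pmax((img - mu) / sd, -5), 5)
  S <- d[3]
  lapply(seq_len(S), function(s) {
    im <- vapply(seq_along(modalities),
                 function(m) resize_slice(img[, , s, m], target_size[1],
                                          target_size[2], "bilinear"),
                 matrix(0, target_size[1], target_size[2]))
    dim(im) <- c(target_size, length(modalities))
    masks <- array(0, c(target_size, 2L))
    if (v$labeled) {
      ls <- resize_slice(v$label[, , s] + 0, target_size[1], target_size[2],
                         "nearest")
      masks[, , 1L] <- (ls == 1) * 1
      masks[, , 2L] <- (ls == 2) * 1
    }
    list(image = im, masks = masks, volume_id = v$volume_id,
         slice = s, aug = "orig")
  })
}

# ---------------------------------------------------------------------------
# augmentation

#' Offline augmentation configuration
#'
#' @param copies_per_image Augmented copies emitted per original slice
#'   (default 2, so the training set triples).
#' @param transforms Enabled transforms, drawn from `"hflip"`, `"vflip"`,
#'   `"rotate"`, `"noise"`, `"brightness"`, `"contrast"`.
#' @param rotation_range Max absolute rotation in degrees.
#' @param noise_sd_range Gaussian noise sd range, as a fraction of the image
#'   intensity sd.
#' @param brightness_range,contrast_range Multiplicative factor ranges.
#' @param seed RNG seed for the augmentation draw.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(copies_per_image = 2L,
                                transforms = c("hflip", "vflip", "rotate",
                                               "noise", "brightness", "contrast"),
                                rotation_range = 15,
                                noise_sd_range = c(0.01, 0.05),
                                brightness_range = c(0.8, 1.2),
                                contrast_range = c(0.8, 1.2),
                                seed = 1L) {
  transforms <- match.arg(transforms, several.ok = TRUE)
  structure(list(copies_per_image = as.integer(copies_per_image),
                 transforms = transforms, rotation_range = rotation_range,
                 noise_sd_range = noise_sd_range,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range, seed = as.integer(seed)),
            class = "augmentation_config")
}

reflect_index <- function(i, n) {
  # fold arbitrary integer indices back into 1..n (mirror boundary)
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1L) %% p
  ifelse(i < n, i + 1L, p - i + 1L)
}

#' Rotate a 2-D slice about its centre
#'
#' Inverse-mapped rotation with mirror (reflect) padding; bilinear sampling
#' for images, nearest-neighbour for label masks so codes are preserved.
#'
#' @param m Numeric matrix.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @param interp `"bilinear"` or `"nearest"`.
#' @return Rotated matrix of the same size.
#' @export
rotate_slice <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  oi <- matrix(rep(seq_len(H), W), H, W) - ci
  oj <- matrix(rep(seq_len(W), each = H), H, W) - cj
  si <- cos(th) * oi - sin(th) * oj + ci
  sj <- sin(th) * oi + cos(th) * oj + cj
  if (interp == "nearest") {
    ri <- reflect_index(round(si), H)
    rj <- reflect_index(round(sj), W)
    return(matrix(m[cbind(as.vector(ri), as.vector(rj))], H, W))
  }
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  g <- function(ii, jj) m[cbind(as.vector(reflect_index(ii, H)),
                                as.vector(reflect_index(jj, W)))]
  v <- (1 - fi) * (1 - fj) * g(i0, j0) + fi * (1 - fj) * g(i0 + 1, j0) +
    (1 - fi) * fj * g(i0, j0 + 1) + fi * fj * g(i0 + 1, j0 + 1)
  matrix(v, H, W)
}

apply_map <- function(x, f) {
  # apply a matrix -> matrix transform to every channel of (H, W, C)
  d <- dim(x)
  out <- vapply(seq_len(d[3]), function(c) f(x[, , c]), matrix(0, d[1], d[2]))
  dim(out) <- d
  out
}

augment_sample <- function(sm, cfg, tag) {
  chosen <- cfg$transforms[stats::runif(length(cfg$transforms)) < 0.5]
  if (!length(chosen)) chosen <- sample(cfg$transforms, 1L)
  img <- sm$image; masks <- sm$masks
  for (tr in chosen) {
    if (tr == "hflip") {
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      masks <- masks[, rev(seq_len(dim(masks)[2])), , drop = FALSE]
    } else if (tr == "vflip") {
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      masks <- masks[rev(seq_len(dim(masks)[1])), , , drop = FALSE]
    } else if (tr == "rotate") {
      ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
      img <- apply_map(img, function(m) rotate_slice(m, ang, "bilinear"))
      masks <- apply_map(masks, function(m) rotate_slice(m, ang, "nearest"))
    } else if (tr == "noise") {
      sdr <- stats::runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
      s <- stats::sd(as.vector(img)); if (!is.finite(s) || s == 0) s <- 1
      img <- img + array(stats::rnorm(length(img), 0, sdr * s), dim(img))
    } else if (tr == "brightness") {
      img <- img * stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    } else if (tr == "contrast") {
      f <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
      img <- (img - mean(img)) * f + mean(img)
    }
  }
  out <- sm
  out$image <- img
  out$masks <- masks
  out$aug <- paste0(tag, ":", paste(chosen, collapse = "+"))
  out
}

#' Offline augmentation of slice samples
#'
#' For every input slice the original is kept and `copies_per_image` augmented
#' variants are added, each applying a random subset of the enabled
#' transforms. Geometric transforms (flips, rotation) are applied identically
#' to the image and its masks (nearest interpolation for masks); intensity
#' transforms (noise, brightness, contrast) touch the image only. With the
#' default 2 copies the set triples. Deterministic given `cfg$seed`.
#'
#' @param samples List of slice samples from [preprocess_volume()].
#' @param cfg An [augmentation_config()].
#' @return List of `(1 + copies_per_image) * length(samples)` samples.
#' @export
augment_offline <- function(samples, cfg = augmentation_config()) {
  stopifnot(inherits(cfg, "augmentation_config"))
  if (!length(samples)) return(list())
  with_seed(cfg$seed, {
    out <- vector("list", length(samples) * (1L + cfg$copies_per_image))
    k <- 0L
    for (s in samples) {
      k <- k + 1L; out[[k]] <- s
      for (cc in seq_len(cfg$copies_per_image)) {
        k <- k + 1L
        out[[k]] <- augment_sample(s, cfg, paste0("aug", cc))
      }
    }
    out
  })
}

# ---------------------------------------------------------------------------
# splitting

#' Split volumes into train and validation sets by volume
#'
#' The split is always by volume (never by slice) so no subject contributes
#' slices to both sets; only labeled volumes are eligible. Augmented copies
#' are created later, from training volumes only, so validation contains only
#' original images.
#'
#' @param volumes List of volume records.
#' @param fraction Training fraction in (0, 1), default 0.8.
#' @param seed RNG seed for the volume shuffle.
#' @return A `dataset_split`: `train` and `validation` volume lists plus the
#'   id vectors and the seed.
#' @export
split_dataset <- function(volumes, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  labeled <- Filter(function(v) isTRUE(v$labeled), volumes)
  n <- length(labeled)
  if (n < 2L) stop("need at least 2 labeled volumes to split", call. = FALSE)
  n_train <- max(1L, min(n - 1L, round(fraction * n)))
  ids <- vapply(labeled, `[[`, character(1), "volume_id")
  train_ids <- with_seed(seed, sort(sample(ids, n_train)))
  val_ids <- sort(setdiff(ids, train_ids))
  structure(list(train = labeled[ids %in% train_ids],
                 validation = labeled[ids %in% val_ids],
                 train_ids = train_ids, val_ids = val_ids,
                 fraction = fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

# ---------------------------------------------------------------------------
# rendering

#' Write a PNG overlay of a segmentation on a grayscale slice
#'
#' Green marks the peripheral zone (code 1) and red the transition zone
#' (code 2), alpha-blended onto the intensity-normalized slice.
#'
#' @param image_slice Numeric matrix.
#' @param label_slice Integer matrix of codes 0/1/2, same size.
#' @param path Output PNG path.
#' @param alpha Blend weight of the overlay color.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image_slice, label_slice, path, alpha = 0.45) {
  stopifnot(all(dim(image_slice) == dim(label_slice)))
  rng <- range(image_slice)
  g <- if (diff(rng) > 0) (image_slice - rng[1]) / diff(rng) else image_slice * 0
  rgb <- array(rep(g, 3L), c(dim(g), 3L))
  pz <- label_slice == 1; tz <- label_slice == 2
  for (ch in 1:3) rgb[, , ch][pz | tz] <- (1 - alpha) * rgb[, , ch][pz | tz]
  rgb[, , 1][tz] <- rgb[, , 1][tz] + alpha   # red transition zone
  rgb[, , 2][pz] <- rgb[, , 2][pz] + alpha   # green peripheral zone
  png::writePNG(rgb, path)
  invisible(path)
}
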