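# Domain types, volume/mask I/O, grid resampling, cohort and fold splitting.

LOCATION_LABELS <- c("DUL", "DLL", "PUL", "PLL", "T", "UNKNOWN")

#' Construct an MR image volume
#'
#' A 3D scalar intensity grid ordered (slices, rows, cols) with per-axis voxel
#' spacing in mm. All physical distances in the package (e.g. [hd95()]) are
#' computed from `spacing`.
#'
#' @param voxels 3D numeric array, dimension (slices, rows, cols), finite.
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm, all > 0.
#' @param exam_id Opaque exam identifier string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), exam_id = "exam") {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array", call. = FALSE)
  if (dim(voxels)[1] < 1) stop("volume needs at least one slice", call. = FALSE)
  stop_if_not_finite(voxels, "image volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (dz, dy, dx)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 exam_id = as.character(exam_id)),
            class = "image_volume")
}

#' Construct a binary segmentation mask
#'
#' Voxel value 1 marks tumor, 0 background. Grid shape and spacing must match
#' the image volume the mask annotates.
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @inheritParams image_volume
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, spacing = c(1, 1, 1), exam_id = "exam") {
  if (length(dim(voxels)) != 3) stop("mask voxels must be a 3D array", call. = FALSE)
  if (!all(voxels %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 exam_id = as.character(exam_id)),
            class = "segmentation_mask")
}

#' Construct an exam (image + mask + metadata)
#'
#' @param image An [image_volume()].
#' @param mask A [segmentation_mask()] congruent with `image`.
#' @param location_label Anatomical location of the tumor, one of
#'   `"DUL"`, `"DLL"`, `"PUL"`, `"PLL"`, `"T"`, `"UNKNOWN"` (distal/proximal
#'   upper/lower limb, trunk). Carried as plain metadata for per-location
#'   reporting.
#' @param site_tag Opaque acquisition-site tag.
#' @return An object of class `exam`.
#' @export
exam <- function(image, mask, location_label = "UNKNOWN", site_tag = "site0") {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "segmentation_mask"))
  if (!identical(dim(image$voxels), dim(mask$voxels)))
    stop("image and mask grid shapes differ", call. = FALSE)
  if (max(abs(image$spacing - mask$spacing)) > 1e-9)
    stop("image and mask spacing differ", call. = FALSE)
  location_label <- as.character(location_label)
  if (!location_label %in% LOCATION_LABELS)
    stop("location_label must be one of: ", paste(LOCATION_LABELS, collapse = ", "),
         call. = FALSE)
  structure(list(image = image, mask = mask,
                 location_label = location_label,
                 site_tag = as.character(site_tag)),
            class = "exam")
}

#' @export
print.exam <- function(x, ...) {
  d <- dim(x$image$voxels)
  cat(sprintf("<exam %s> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, location %s, site %s\n",
              x$image$exam_id, d[1], d[2], d[3],
              x$image$spacing[1], x$image$spacing[2], x$image$spacing[3],
              x$location_label, x$site_tag))
  invisible(x)
}

# ---- I/O ---------------------------------------------------------------

nifti_to_array <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3) stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  pix <- RNifti::pixdim(img)
  if (length(pix) < 3) pix <- c(pix, rep(1, 3 - length(pix)))
  # NIfTI arrays are (x, y, z); internal order is (slice=z, row=y, col=x)
  list(voxels = aperm(a, c(3, 2, 1)), spacing = rev(pix[1:3]))
}

#' Write an image volume to a NIfTI file
#'
#' Voxels are stored as 32-bit floats, mirroring the raw float32 working
#' format; spacing is written to pixdim.
#'
#' @param volume An [image_volume()] or [segmentation_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  a <- aperm(volume$voxels, c(3, 2, 1))  # back to (x, y, z)
  img <- RNifti::asNifti(
    a, reference = list(pixdim = c(-1, rev(volume$spacing), 0, 0, 0, 0)),
    datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an exam as a NIfTI image/mask pair
#'
#' @param x An [exam()].
#' @param image_path,mask_path Output paths.
#' @return `c(image_path, mask_path)`, invisibly.
#' @export
write_exam_nifti <- function(x, image_path, mask_path) {
  write_volume_nifti(x$image, image_path)
  write_volume_nifti(x$mask, mask_path)
  invisible(c(image_path, mask_path))
}

#' Write/read the raw float32 cache format
#'
#' One `.raw` file of little-endian 32-bit floats in (slices, rows, cols)
#' order plus a JSON sidecar `.json` holding shape, spacing and exam id.
#'
#' @param volume An [image_volume()] or [segmentation_mask()].
#' @param stem Path stem; `<stem>.raw` and `<stem>.json` are written.
#' @return The stem, invisibly (writer); an [image_volume()] (reader).
#' @export
write_volume_raw <- function(volume, stem) {
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$voxels), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(shape = dim(volume$voxels), spacing = volume$spacing,
         exam_id = volume$exam_id),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(stem) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$shape)
  con <- file(paste0(stem, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  image_volume(array(v, dim = hdr$shape), spacing = hdr$spacing,
               exam_id = hdr$exam_id)
}

read_any_volume <- function(path) {
  if (dir.exists(path))
    stop("directory inputs (DICOM series) are not supported; ",
         "convert to NIfTI or the raw float32 cache format", call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    v <- nifti_to_array(path)
    return(image_volume(v$voxels, v$spacing,
                        exam_id = sub("\\.nii(\\.gz)?$", "", basename(path))))
  }
  stem <- sub("\\.raw$", "", path)
  if (file.exists(paste0(stem, ".raw")) && file.exists(paste0(stem, ".json")))
    return(read_volume_raw(stem))
  stop("unrecognized volume format (expected .nii/.nii.gz or .raw+.json): ",
       path, call. = FALSE)
}

#' Read an exam from image and mask files
#'
#' Accepts NIfTI (`.nii`/`.nii.gz`) or the raw float32 cache format. The mask
#' is checked to contain only values in \[0, 1\] and binarized at > 0.5;
#' values outside that range (e.g. a stray label 2) are an error. Image and
#' mask must agree in grid shape and spacing.
#'
#' @param image_path,mask_path Paths to the image and mask volumes.
#' @param location_label,site_tag Metadata, see [exam()].
#' @return An [exam()].
#' @export
read_exam <- function(image_path, mask_path,
                      location_label = "UNKNOWN", site_tag = "site0") {
  img <- read_any_volume(image_path)
  msk <- read_any_volume(mask_path)
  stop_if_not_finite(img$voxels, "image")
  stop_if_not_finite(msk$voxels, "mask")
  if (any(msk$voxels < -1e-6) || any(msk$voxels > 1 + 1e-6))
    stop("mask contains values outside {0, 1}", call. = FALSE)
  mv <- ifelse(msk$voxels > 0.5, 1, 0)
  if (!identical(dim(img$voxels), dim(mv)))
    stop("image/mask shape mismatch", call. = FALSE)
  if (max(abs(img$spacing - msk$spacing)) > 1e-6)
    stop("image/mask spacing mismatch", call. = FALSE)
  exam(img,
       segmentation_mask(mv, spacing = img$spacing, exam_id = img$exam_id),
       location_label = location_label, site_tag = site_tag)
}

# ---- Resampling --------------------------------------------------------

#' Resample an exam to a square in-plane grid
#'
#' Each slice is scaled isotropically so its larger in-plane dimension equals
#' `target`, then symmetrically zero-padded to `target x target`. Image slices
#' are interpolated bilinearly, mask slices by nearest neighbour (so the mask
#' stays binary). In-plane spacing is divided by the scale factor; the slice
#' axis is never resampled (the networks are 2D slice-wise).
#'
#' @param x An [exam()].
#' @param target Side length of the output grid (default 512).
#' @return A resampled [exam()].
#' @export
resample_to_grid <- function(x, target = 512L) {
  target <- as.integer(target)
  if (is.na(target) || target <= 0) stop("target must be a positive integer", call. = FALSE)
  d <- dim(x$image$voxels)
  nr <- d[2]; nc <- d[3]
  if (nr == target && nc == target) return(x)
  s <- target / max(nr, nc)
  new_r <- if (nr >= nc) target else as.integer(round(nr * s))
  new_c <- if (nc >= nr) target else as.integer(round(nc * s))
  pad_r0 <- (target - new_r) %/% 2L
  pad_c0 <- (target - new_c) %/% 2L
  out_img <- array(0, c(d[1], target, target))
  out_msk <- array(0, c(d[1], target, target))
  for (k in seq_len(d[1])) {
    out_img[k, pad_r0 + seq_len(new_r), pad_c0 + seq_len(new_c)] <-
      resize2d(x$image$voxels[k, , ], new_r, new_c, "bilinear")
    out_msk[k, pad_r0 + seq_len(new_r), pad_c0 + seq_len(new_c)] <-
      resize2d(x$mask$voxels[k, , ], new_r, new_c, "nearest")
  }
  sp <- x$image$spacing
  new_spacing <- c(sp[1], sp[2] / s, sp[3] / s)
  exam(image_volume(out_img, new_spacing, x$image$exam_id),
       segmentation_mask(out_msk, new_spacing, x$mask$exam_id),
       location_label = x$location_label, site_tag = x$site_tag)
}

# ---- Cohort splitting --------------------------------------------------

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    # ties broken by position for determinism
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Split a cohort into train / tune / test partitions
#'
#' Exam ids are shuffled by a seeded generator and partitioned with
#' largest-remainder rounding of `n * fractions`, which reproduces the
#' 148/17/20 split of a 185-exam cohort at fractions (0.80, 0.09, 0.11).
#'
#' @param exam_ids Character vector of exam ids.
#' @param fractions Length-3 non-negative vector `(train, tune, test)` summing to 1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return An object of class `data_split` with elements `train_ids`,
#'   `tune_ids`, `test_ids`.
#' @export
split_cohort <- function(exam_ids, fractions = c(0.80, 0.09, 0.11), seed = 0L) {
  exam_ids <- as.character(exam_ids)
  if (length(exam_ids) == 0) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(exam_ids)) stop("duplicate exam ids", call. = FALSE)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative numbers summing to 1", call. = FALSE)
  n <- length(exam_ids)
  sizes <- largest_remainder(n, fractions)
  shuffled <- with_local_seed(seed, sample(exam_ids))
  structure(list(
    train_ids = shuffled[seq_len(sizes[1])],
    tune_ids = shuffled[sizes[1] + seq_len(sizes[2])],
    test_ids = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])]
  ), class = "data_split")
}

#' Assign training exams to cross-validation folds
#'
#' Seeded shuffle followed by near-equal partition: the first `n %% k` folds
#' have `ceiling(n / k)` exams, the rest `floor(n / k)`.
#'
#' @param train_ids Character vector of training exam ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: a named integer vector
#'   mapping exam id to fold index in `1..k`.
#' @export
make_folds <- function(train_ids, k = 5L, seed = 0L) {
  train_ids <- as.character(train_ids)
  n <- length(train_ids)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of training exams", call. = FALSE)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  shuffled <- with_local_seed(seed, sample(train_ids))
  fold_of <- rep(seq_len(k), times = sizes)
  structure(setNames(fold_of, shuffled), class = "fold_assignment")
}
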