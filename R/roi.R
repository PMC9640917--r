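# ROI preprocessing: from segmented per-channel volumes (or single slices)
# with binary lesion masks to normalised, fixed-size, channel-stacked 2D
# patches.  Conventions: volumes are `slices x rows x cols` arrays; bounding
# boxes are 0-based, half-open intervals; patches live in [0, 1].

#' Construct an annotated per-channel volume
#'
#' @param image 3D numeric array (`slices x rows x cols`); a 2D matrix is
#'   treated as a single-slice volume.
#' @param mask Binary array of the same shape (lesion segmentation).
#' @param channel_name One of the CT channel names (`plain`, `AP`, `PVP`) or
#'   MRI channel names (`T2WI`, `DWI`, `T1pre`, `T1AP`, `T1PVP`, `T1EP`).
#' @param spacing Optional voxel spacing (physical units), kept as metadata.
#' @return An `annotated_volume` object.
#' @export
annotated_volume <- function(image, mask, channel_name, spacing = NULL) {
  if (is.matrix(image)) dim(image) <- c(1L, dim(image))
  if (is.matrix(mask)) dim(mask) <- c(1L, dim(mask))
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask shapes differ")
  }
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  if (!channel_name %in% c(CT_CHANNELS, MRI_CHANNELS)) {
    stop("unknown channel name: ", channel_name)
  }
  structure(list(image = image, mask = mask, channel_name = channel_name,
                 spacing = spacing),
            class = "annotated_volume")
}

#' Index of the slice with the largest lesion area
#'
#' Returns the 0-based index of the slice whose mask has the most nonzero
#' pixels; ties break toward the lowest index.
#'
#' @param volume An [annotated_volume()].
#' @return Integer 0-based slice index.
#' @export
select_largest_lesion_slice <- function(volume) {
  stopifnot(inherits(volume, "annotated_volume"))
  areas <- apply(volume$mask, 1, sum)
  if (all(areas == 0)) stop("empty mask: no lesion voxels")
  as.integer(which.max(areas) - 1L)
}

#' Crop the tight mask bounding box (plus margin) out of a slice
#'
#' @param slice_image 2D numeric array.
#' @param slice_mask 2D binary array of the same shape.
#' @param margin Pixels of context added on every side, clipped to the image.
#' @return List with `pixels` (the cropped image) and `box`, the 0-based
#'   half-open bounding box `list(rows = c(r0, r1), cols = c(c0, c1))`.
#' @export
crop_roi <- function(slice_image, slice_mask, margin = 4L) {
  stopifnot(is.matrix(slice_image), identical(dim(slice_image), dim(slice_mask)),
            margin >= 0)
  idx <- which(slice_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask: no lesion pixels in slice")
  r0 <- max(min(idx[, 1]) - 1L - margin, 0L)
  r1 <- min(max(idx[, 1]) + margin, nrow(slice_image))
  c0 <- max(min(idx[, 2]) - 1L - margin, 0L)
  c1 <- min(max(idx[, 2]) + margin, ncol(slice_image))
  list(pixels = slice_image[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE],
       box = list(rows = c(r0, r1), cols = c(c0, c1)))
}

#' Min-max rescale a patch to [0, 1]
#'
#' A constant patch maps to all zeros (degenerate range convention).
#'
#' @param patch 2D numeric array with finite values.
#' @return Patch rescaled to `[0, 1]`.
#' @export
normalize_greyscale <- function(patch) {
  if (!all(is.finite(patch))) stop("non-finite values in patch")
  rng <- range(patch)
  if (rng[1] == rng[2]) return(patch * 0)
  (patch - rng[1]) / (rng[2] - rng[1])
}

#' Bilinear resampling of a patch to a square side length
#'
#' @param patch 2D numeric array.
#' @param side Output side length `S`.
#' @return `side x side` numeric matrix.
#' @export
resample_bilinear <- function(patch, side) {
  h <- nrow(patch); w <- ncol(patch)
  # map output pixel centres onto input pixel centres
  ri <- pmin(pmax((seq_len(side) - 0.5) * h / side - 0.5, 0), h - 1)
  ci <- pmin(pmax((seq_len(side) - 0.5) * w / side - 0.5, 0), w - 1)
  r0 <- pmin(floor(ri), h - 1); r1 <- pmin(r0 + 1, h - 1); fr <- ri - r0
  c0 <- pmin(floor(ci), w - 1); c1 <- pmin(c0 + 1, w - 1); fc <- ci - c0
  a <- patch[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- patch[r1 + 1, c0 + 1, drop = FALSE] * outer(fr, 1 - fc)
  d <- patch[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - fr, fc)
  e <- patch[r1 + 1, c1 + 1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

#' Assemble per-channel patches into a modality stack
#'
#' Channels are reordered into the canonical convention — CT:
#' `(plain, AP, PVP)`; MRI: `(T2WI, DWI, T1pre, T1AP, T1PVP, T1EP)` — and
#' missing, duplicate or unknown channel names are rejected.
#'
#' @param patches Named list of 2D arrays (one per channel, equal side).
#' @param modality `"ct"` or `"mri"`.
#' @return A `modality_stack`: `S x S x C` array with channel metadata.
#' @export
assemble_modality_stack <- function(patches, modality = c("ct", "mri")) {
  modality <- match.arg(modality)
  wanted <- modality_channels(modality)
  nms <- names(patches)
  if (is.null(nms) || any(nms == "")) stop("patches must be a named list")
  if (anyDuplicated(nms)) {
    stop("duplicate channel: ", nms[duplicated(nms)][1])
  }
  unknown <- setdiff(nms, wanted)
  if (length(unknown)) stop("unknown channel ", unknown[1], " for ", modality)
  missing <- setdiff(wanted, nms)
  if (length(missing)) stop("missing channel ", missing[1])
  sides <- unname(vapply(patches, function(p) dim(p)[1], numeric(1)))
  widths <- unname(vapply(patches, function(p) dim(p)[2], numeric(1)))
  if (length(unique(c(sides, widths))) != 1) {
    stop("all channel patches must be square with a common side")
  }
  px <- array(0, c(sides[1], sides[1], length(wanted)))
  for (i in seq_along(wanted)) px[, , i] <- patches[[wanted[i]]]
  structure(list(pixels = px, modality = modality, channel_names = wanted),
            class = "modality_stack")
}

#' Full ROI pipeline for one annotated volume
#'
#' Selects the largest-lesion slice, crops the mask box plus margin,
#' resamples bilinearly to `side` and min-max normalises.
#'
#' @param volume An [annotated_volume()].
#' @param side Output patch side `S`.
#' @param margin Crop margin in pixels.
#' @param mask_out Zero the pixels outside the lesion mask before cropping.
#' @return List with `pixels` (`side x side`, in `[0, 1]`), `slice_index` and
#'   the crop `box`.
#' @export
extract_roi_patch <- function(volume, side = 64L, margin = 4L,
                              mask_out = FALSE) {
  k <- select_largest_lesion_slice(volume)
  img <- volume$image[k + 1L, , ]
  msk <- volume$mask[k + 1L, , ]
  if (mask_out) img <- img * msk
  cr <- crop_roi(img, msk, margin)
  list(pixels = normalize_greyscale(resample_bilinear(cr$pixels, side)),
       slice_index = k, box = cr$box)
}

# Lesion records ---------------------------------------------------------------

#' Construct a lesion record
#'
#' One lesion: identifier, MVI label, modality availability and the modality
#' stacks present.
#'
#' @param lesion_id Identifier (character).
#' @param label MVI status, 0 (negative) or 1 (positive).
#' @param ct,mri `modality_stack`s or `NULL`.
#' @param provenance Optional list of generating parameters (synthetic data).
#' @return A `lesion_record` whose `availability` is `"ct"`, `"mri"` or
#'   `"both"` according to the stacks present.
#' @export
lesion_record <- function(lesion_id, label, ct = NULL, mri = NULL,
                          provenance = NULL) {
  stopifnot(label %in% c(0, 1))
  if (is.null(ct) && is.null(mri)) stop("record must carry at least one modality")
  if (!is.null(ct) && ct$modality != "ct") stop("ct slot must hold a CT stack")
  if (!is.null(mri) && mri$modality != "mri") stop("mri slot must hold an MRI stack")
  availability <- if (!is.null(ct) && !is.null(mri)) "both"
                  else if (!is.null(ct)) "ct" else "mri"
  structure(list(lesion_id = as.character(lesion_id), label = as.integer(label),
                 availability = availability, ct = ct, mri = mri,
                 provenance = provenance),
            class = "lesion_record")
}

read_image_any <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    aperm(arr, c(3, 1, 2)) # z becomes the leading slice axis
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1] # collapse grey-encoded RGB
    arr <- array(img, c(1L, dim(img)))
    arr
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Load a cohort from a manifest CSV
#'
#' The manifest is long-format with one row per lesion channel and columns
#' `lesion_id`, `label`, `modality` (`ct`/`mri`), `channel` (canonical channel
#' name), `image`, `mask` (paths, relative to the manifest location; NIfTI or
#' PNG).  Every channel volume is pushed through the ROI pipeline and the
#' resulting patches are assembled into modality stacks.
#'
#' @param manifest Path to the manifest CSV.
#' @param side Patch side `S`.
#' @param margin Crop margin in pixels.
#' @param mask_out Zero pixels outside the lesion mask.
#' @return List of [lesion_record()]s.
#' @export
load_cohort <- function(manifest, side = 64L, margin = 4L, mask_out = FALSE) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("lesion_id", "label", "modality", "channel", "image", "mask")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  root <- dirname(normalizePath(manifest))
  records <- list()
  for (id in unique(man$lesion_id)) {
    rows <- man[man$lesion_id == id, ]
    label <- unique(rows$label)
    if (length(label) != 1) stop("inconsistent label for lesion ", id)
    stacks <- list(ct = NULL, mri = NULL)
    for (mod in intersect(c("ct", "mri"), rows$modality)) {
      sub <- rows[rows$modality == mod, ]
      patches <- list()
      for (i in seq_len(nrow(sub))) {
        vol <- annotated_volume(
          read_image_any(file.path(root, sub$image[i])),
          round(read_image_any(file.path(root, sub$mask[i]))),
          sub$channel[i]
        )
        patches[[sub$channel[i]]] <-
          extract_roi_patch(vol, side, margin, mask_out)$pixels
      }
      stacks[[mod]] <- assemble_modality_stack(patches, mod)
    }
    records[[length(records) + 1L]] <-
      lesion_record(id, label, ct = stacks$ct, mri = stacks$mri)
  }
  records
}

# Helpers used across modules --------------------------------------------------

#' MVI labels of a record list
#'
#' @param records List of [lesion_record()]s.
#' @return Integer vector of 0/1 labels.
#' @export
record_labels <- function(records) {
  vapply(records, function(r) r$label, integer(1))
}

# Stack the given modality of a record list into an H x W x C x N array.
stack_array <- function(records, modality) {
  stacks <- lapply(records, function(r) r[[modality]])
  if (any(vapply(stacks, is.null, logical(1)))) {
    stop("some records lack the ", modality, " modality")
  }
  d <- dim(stacks[[1]]$pixels)
  x <- array(0, c(d, length(stacks)))
  for (i in seq_along(stacks)) x[, , , i] <- stacks[[i]]$pixels
  x
}
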