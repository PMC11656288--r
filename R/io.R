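#' Preprocessing specification
#'
#' Resample to a common spacing, center-crop/pad to fixed extents, min-max
#' normalize to [0, 1] -- the standard preparation for both liver
#' (1.5 mm, 256x256x64) and prostate (0.7 mm) profiles.
#'
#' @param target_spacing mm triple.
#' @param target_extents Voxel triple.
#' @param normalize Min-max normalize intensities (constant volumes map to
#'   all-zeros).
#' @return A `preprocess_spec`.
#' @export
preprocess_spec <- function(target_spacing = c(1.5, 1.5, 1.5),
                            target_extents = c(256L, 256L, 64L),
                            normalize = TRUE) {
  stopifnot(all(target_spacing > 0), all(target_extents > 0))
  structure(list(target_spacing = target_spacing,
                 target_extents = as.integer(target_extents),
                 normalize = isTRUE(normalize)),
            class = "preprocess_spec")
}

# trilinear (volumes) / nearest (labels) resampling onto a new grid whose
# voxel i centers at source coordinate (i - 0.5) * new_sp / old_sp + 0.5
.resample <- function(vol, new_dim, old_sp, new_sp, method = "trilinear") {
  d <- dim(vol)
  coord <- lapply(1:3, function(ax) {
    (seq_len(new_dim[ax]) - 0.5) * new_sp[ax] / old_sp[ax] + 0.5
  })
  if (method == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(coord[[ax]]), 1L), d[ax]))
    return(vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(ax) pmin(pmax(floor(coord[[ax]]), 1L), d[ax]))
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1L, d[ax]))
  w <- lapply(1:3, function(ax) pmin(pmax(coord[[ax]] - lo[[ax]], 0), 1))
  out <- array(0, new_dim)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) w[[1]] else 1 - w[[1]]
    wy <- if (cy) w[[2]] else 1 - w[[2]]
    wz <- if (cz) w[[3]] else 1 - w[[3]]
    wgt <- array(rep(wx, times = new_dim[2] * new_dim[3]), new_dim) *
      array(rep(rep(wy, each = new_dim[1]), times = new_dim[3]), new_dim) *
      array(rep(wz, each = new_dim[1] * new_dim[2]), new_dim)
    out <- out + wgt * vol[ix, iy, iz, drop = FALSE]
  }
  out
}

# center crop/pad to target extents; returns the volume plus the offsets
# (source index of target voxel 1 minus 1; negative = padding)
.crop_pad <- function(vol, target, fill = 0) {
  d <- dim(vol)
  off <- as.integer(floor((d - target) / 2))
  out <- array(fill, target)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(target[ax]) + off[ax]
    s[s >= 1 & s <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    s <- seq_len(target[ax])
    s[(s + off[ax]) >= 1 & (s + off[ax]) <= d[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  list(out = out, offsets = off)
}

#' Load and preprocess a NIfTI volume
#'
#' Resamples (trilinear for images, nearest for labels), center-crops/pads
#' and min-max normalizes, recording the original geometry so that
#' [save_segmentation()] can write results back on the original grid.
#'
#' @param path NIfTI file.
#' @param spec A [preprocess_spec()], or `NULL` for raw loading.
#' @param label Treat the volume as a label map (nearest-neighbor, no
#'   normalization).
#' @return List: `volume`, `geometry` (original dim/spacing/affine, the
#'   resampled dim and crop offsets).
#' @export
load_volume <- function(path, spec = NULL, label = FALSE) {
  nii <- read_nifti(path)
  vol <- nii$data
  geometry <- list(orig_dim = dim(vol), orig_spacing = nii$spacing,
                   affine = nii$affine, resampled_dim = dim(vol),
                   offsets = c(0L, 0L, 0L), spec = spec)
  if (!is.null(spec)) {
    new_dim <- pmax(1L, as.integer(round(dim(vol) * nii$spacing /
                                           spec$target_spacing)))
    vol <- .resample(vol, new_dim, nii$spacing, spec$target_spacing,
                     method = if (label) "nearest" else "trilinear")
    geometry$resampled_dim <- dim(vol)
    cp <- .crop_pad(vol, spec$target_extents)
    vol <- cp$out
    geometry$offsets <- cp$offsets
    if (!label && spec$normalize) {
      rng <- range(vol)
      vol <- if (rng[2] > rng[1]) (vol - rng[1]) / (rng[2] - rng[1]) else
        array(0, dim(vol))
    }
  }
  list(volume = vol, geometry = geometry)
}

#' Write a segmentation back on the original grid
#'
#' Inverts the center crop/pad and the resampling (nearest neighbor) and
#' writes a 0/1 NIfTI with the original spacing and affine.
#'
#' @param mask Binary array on the preprocessed grid.
#' @param geometry Geometry record from [load_volume()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
save_segmentation <- function(mask, geometry, path) {
  spec <- geometry$spec
  if (!is.null(spec)) {
    if (!all(dim(mask) == spec$target_extents)) {
      stop("mask extents ", paste(dim(mask), collapse = "x"),
           " do not match the recorded geometry (",
           paste(spec$target_extents, collapse = "x"), ")")
    }
    # undo center crop/pad
    rd <- geometry$resampled_dim
    off <- geometry$offsets
    un <- array(0, rd)
    src <- lapply(1:3, function(ax) {
      s <- seq_len(rd[ax])
      s[(s - off[ax]) >= 1 & (s - off[ax]) <= dim(mask)[ax]]
    })
    un[src[[1]], src[[2]], src[[3]]] <-
      mask[src[[1]] - off[1], src[[2]] - off[2], src[[3]] - off[3]]
    # undo resampling
    mask <- .resample(un, geometry$orig_dim, spec$target_spacing,
                      geometry$orig_spacing, method = "nearest")
  } else if (!all(dim(mask) == geometry$orig_dim)) {
    stop("mask extents do not match the recorded geometry")
  }
  mask <- binarize(mask, 0.5)
  write_nifti(mask, path, spacing = geometry$orig_spacing,
              affine = geometry$affine, dtype = "uint8")
  invisible(path)
}
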