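#' Merge multiple acquisition series into a single volume
#'
#' Whole-body scans acquired as several axial series with varying
#' resolutions are resampled to a common target spacing (trilinear for
#' scalar data, nearest-neighbour for labels), overlapping slice ranges are
#' de-duplicated per the chosen policy, and the series are stacked into one
#' volume.
#'
#' @param stack List of series, each a list with `voxels` (3-D array,
#'   (z, y, x)), `z_offset_mm` and `spacing` (z, y, x in mm).
#' @param dedup Overlap policy: `"keep_first"` uses the earliest series in
#'   list order; `"mean"` averages all covering series.
#' @param target_spacing Output spacing; default is the finest available
#'   spacing per axis.
#' @param interp `"trilinear"` for scalar data, `"nearest"` for labels.
#' @return A `body_volume` with merged voxels.
#' @export
merge_series <- function(stack, dedup = c("keep_first", "mean"),
                         target_spacing = NULL,
                         interp = c("trilinear", "nearest")) {
  dedup <- match.arg(dedup)
  interp <- match.arg(interp)
  stopifnot(length(stack) >= 1)
  for (s in stack) stopifnot(all(s$spacing > 0), length(dim(s$voxels)) == 3)
  sp_mat <- do.call(rbind, lapply(stack, `[[`, "spacing"))
  tsp <- target_spacing %||% apply(sp_mat, 2, min)

  # Resample each series in-plane to the target (y, x) spacing.
  stack <- lapply(stack, function(s) {
    d <- dim(s$voxels)
    ny2 <- max(1L, round(d[2] * s$spacing[2] / tsp[2]))
    nx2 <- max(1L, round(d[3] * s$spacing[3] / tsp[3]))
    if (ny2 != d[2] || nx2 != d[3]) {
      v2 <- array(0, c(d[1], ny2, nx2))
      for (z in seq_len(d[1])) {
        if (interp == "trilinear") {
          v2[z, , ] <- .bilinear_resize(s$voxels[z, , ], ny2, nx2)
        } else {
          v2[z, , ] <- resize_nn(s$voxels[z, , ], ny2, nx2)
        }
      }
      s$voxels <- v2
    }
    s
  })

  z_start <- vapply(stack, `[[`, numeric(1), "z_offset_mm")
  z_end <- z_start + vapply(stack, function(s)
    (dim(s$voxels)[1] - 1) * s$spacing[1], numeric(1))
  z0 <- min(z_start)
  nz <- floor((max(z_end) - z0) / tsp[1] + 1e-9) + 1L
  zg <- z0 + (seq_len(nz) - 1) * tsp[1]

  dims_yx <- vapply(stack, function(s) dim(s$voxels)[2:3], integer(2))
  if (any(dims_yx != dims_yx[, 1]))
    stop("series disagree on in-plane extent after resampling")
  ny <- dims_yx[1, 1]
  nx <- dims_yx[2, 1]
  out <- array(0, c(nz, ny, nx))
  cnt <- integer(nz)
  for (s in stack) {
    d1 <- dim(s$voxels)[1]
    zs <- s$z_offset_mm + (seq_len(d1) - 1) * s$spacing[1]
    covered <- which(zg >= zs[1] - 1e-9 & zg <= zs[d1] + 1e-9)
    for (zi in covered) {
      if (dedup == "keep_first" && cnt[zi] > 0L) next
      pos <- (zg[zi] - zs[1]) / s$spacing[1]
      i0 <- min(floor(pos), d1 - 1)
      w <- pos - i0
      if (interp == "nearest") {
        sl <- s$voxels[i0 + 1 + round(w), , ]
      } else if (w < 1e-9) {
        sl <- s$voxels[i0 + 1, , ]
      } else {
        sl <- (1 - w) * s$voxels[i0 + 1, , ] + w * s$voxels[i0 + 2, , ]
      }
      if (dedup == "mean" && cnt[zi] > 0L) {
        out[zi, , ] <- (out[zi, , ] * cnt[zi] + sl) / (cnt[zi] + 1L)
      } else {
        out[zi, , ] <- sl
      }
      cnt[zi] <- cnt[zi] + 1L
    }
  }
  gaps <- which(cnt == 0L)
  if (length(gaps)) {
    # a single missing slice between series is bridged by interpolation
    runs <- split(gaps, cumsum(c(1, diff(gaps) != 1)))
    if (any(lengths(runs) > 1)) stop("non-contiguous series")
    for (zi in gaps) {
      lo <- max(zi - 1, 1); hi <- min(zi + 1, nz)
      out[zi, , ] <- (out[lo, , ] + out[hi, , ]) / 2
    }
  }
  body_volume(voxels = out, spacing = tsp)
}

#' @noRd
.bilinear_resize <- function(m, nr, nc) {
  yi <- (seq_len(nr) - 0.5) * nrow(m) / nr - 0.5
  xi <- (seq_len(nc) - 0.5) * ncol(m) / nc - 0.5
  y0 <- pmin(pmax(floor(yi), 0), nrow(m) - 1)
  x0 <- pmin(pmax(floor(xi), 0), ncol(m) - 1)
  wy <- pmin(pmax(yi - y0, 0), 1)
  wx <- pmin(pmax(xi - x0, 0), 1)
  y1 <- pmin(y0 + 1, nrow(m) - 1)
  x1 <- pmin(x0 + 1, ncol(m) - 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
  b <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
  cc <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  d <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  a + b + cc + d
}

#' Segment the body on a 2-D axial slice
#'
#' Thresholds the slice (Otsu by default), removes small spurious
#' components (anything below `min_component_frac` of the largest
#' 4-connected foreground component — on lower-body slices the anatomy is
#' legitimately two components, one per leg, so only the largest would be
#' wrong), and fills interior holes. A background-only slice yields an
#' all-zero mask rather than an error.
#'
#' @param slice2d Numeric matrix of finite pixel intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value when `method = "fixed"`.
#' @param min_component_frac Components smaller than this fraction of the
#'   largest are discarded as noise.
#' @return Binary integer matrix of the same shape.
#' @export
segment_axial <- function(slice2d, method = c("otsu", "fixed"),
                          threshold = NULL, min_component_frac = 0.25) {
  method <- match.arg(method)
  if (any(!is.finite(slice2d))) stop("nonfinite pixels")
  rng <- range(slice2d)
  if (diff(rng) == 0) return(matrix(0L, nrow(slice2d), ncol(slice2d)))
  if (method == "otsu") {
    norm <- (slice2d - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    mask <- norm > th
  } else {
    if (is.null(threshold)) stop("threshold required for method = 'fixed'")
    mask <- slice2d > threshold
  }
  if (!any(mask)) return(matrix(0L, nrow(slice2d), ncol(slice2d)))
  lab <- .label_components_2d(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep_ids <- which(sizes >= min_component_frac * max(sizes))
  keep <- matrix(lab %in% keep_ids & lab > 0L, nrow(lab), ncol(lab))
  filled <- EBImage::fillHull(EBImage::Image(keep * 1))
  matrix(as.integer(filled > 0.5), nrow(slice2d), ncol(slice2d))
}

#' Orthogonal binary projection of a volume
#'
#' The coronal projection marks `[z, x]` whenever any voxel along the
#' anterior-posterior axis is set; the sagittal projection marks `[z, y]`
#' whenever any voxel along the left-right axis is set.
#'
#' @param vol Binary 3-D array (z, y, x) or a `body_volume` whose labels
#'   define the body mask.
#' @param plane `"coronal"` or `"sagittal"`.
#' @return Binary integer matrix.
#' @export
project <- function(vol, plane = c("coronal", "sagittal")) {
  plane <- match.arg(plane)
  if (inherits(vol, "body_volume")) vol <- (vol$labels %||% vol$voxels) > 0
  if (is.logical(vol)) {
    v <- vol
  } else {
    rng <- range(vol)
    if (!all(rng %in% c(0, 1))) stop("non-binary input")
    v <- vol != 0
    dim(v) <- dim(vol)
  }
  out <- if (plane == "sagittal") {
    rowSums(v, dims = 2) > 0                 # collapse x -> [z, y]
  } else {
    rowSums(aperm(v, c(1, 3, 2)), dims = 2) > 0  # collapse y -> [z, x]
  }
  matrix(as.integer(out), nrow(out), ncol(out))
}

#' Rescale a binary image so pixels are isotropic
#'
#' Nearest-neighbour rescale to the finer pitch of the two axes; binarity
#' is preserved exactly.
#'
#' @param img Binary matrix (rows = first axis).
#' @param spacing Length-2 mm spacing (row pitch, column pitch).
#' @return Binary integer matrix.
#' @export
aspect_correct <- function(img, spacing) {
  stopifnot(length(spacing) == 2, all(spacing > 0))
  if (spacing[1] == spacing[2]) return(img)
  target <- min(spacing)
  nr <- round(nrow(img) * spacing[1] / target)
  nc <- round(ncol(img) * spacing[2] / target)
  resize_nn(img, nr, nc)
}

#' Compose coronal and sagittal panels into the model input silhouette
#'
#' Each panel is rescaled preserving aspect (nearest-neighbour, then
#' re-thresholded at 0.5) and centered into its frame; the two frames are
#' concatenated side by side, coronal left, to the fixed 237 x 256 input
#' size.
#'
#' @param coronal,sagittal Non-empty binary matrices.
#' @param height Output height in pixels.
#' @param panel_widths Widths of the coronal and sagittal frames.
#' @return A `silhouette_image`: binary matrix of dimension
#'   `height x sum(panel_widths)`.
#' @export
compose_silhouette <- function(coronal, sagittal, height = 237L,
                               panel_widths = c(128L, 128L)) {
  place <- function(panel, w) {
    if (sum(panel) == 0) stop("empty silhouette")
    f <- min(height / nrow(panel), w / ncol(panel))
    nr <- max(1L, round(nrow(panel) * f))
    nc <- max(1L, round(ncol(panel) * f))
    small <- resize_nn(panel, nr, nc)
    small <- matrix(as.integer(small >= 0.5), nr, nc)
    frame <- matrix(0L, height, w)
    r0 <- floor((height - nr) / 2)
    c0 <- floor((w - nc) / 2)
    frame[r0 + seq_len(nr), c0 + seq_len(nc)] <- small
    frame
  }
  out <- cbind(place(coronal, panel_widths[1]),
               place(sagittal, panel_widths[2]))
  structure(out, class = c("silhouette_image", class(out)),
            version = silfat_version())
}

#' @export
print.silhouette_image <- function(x, ...) {
  cat(sprintf("<silhouette_image> %d x %d, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Reduce a binary panel to its 1-pixel boundary
#' @noRd
.outline_panel <- function(panel) {
  p <- panel != 0
  inner <- p
  inner[] <- FALSE
  nr <- nrow(p); nc <- ncol(p)
  if (nr > 2 && nc > 2) {
    core <- p[2:(nr - 1), 2:(nc - 1)] & p[1:(nr - 2), 2:(nc - 1)] &
      p[3:nr, 2:(nc - 1)] & p[2:(nr - 1), 1:(nc - 2)] & p[2:(nr - 1), 3:nc]
    inner[2:(nr - 1), 2:(nc - 1)] <- core
  }
  matrix(as.integer(p & !inner), nr, nc)
}

#' Build the two-panel silhouette from a volumetric image
#'
#' Full pipeline: per-slice body segmentation (skipped when the volume
#' already carries labels and no scalar data), orthogonal projection in the
#' coronal and sagittal planes, aspect correction for anisotropic voxels,
#' and composition into the fixed 237 x 256 binary input image.
#'
#' @param vol A `body_volume`, a 3-D array (with `spacing` supplied), or a
#'   NIfTI file path.
#' @param spacing Voxel spacing when `vol` is a bare array.
#' @param out_png Optional PNG output path (a JSON provenance sidecar is
#'   written alongside).
#' @param outline If `TRUE`, panels are reduced to their 1-pixel boundary
#'   before composition.
#' @param method,threshold Segmentation options, see [segment_axial()].
#' @param id Participant identifier recorded in provenance.
#' @return A `silhouette_image`.
#' @export
volume_to_silhouette <- function(vol, spacing = NULL, out_png = NULL,
                                 outline = FALSE,
                                 method = c("otsu", "fixed"),
                                 threshold = NULL, id = NULL) {
  method <- match.arg(method)
  if (is.character(vol)) vol <- read_body_volume(vol)
  if (!inherits(vol, "body_volume")) {
    stopifnot(!is.null(spacing))
    vol <- body_volume(voxels = vol, spacing = spacing)
  }
  sp <- vol$spacing
  if (!is.null(vol$voxels)) {
    d <- dim(vol$voxels)
    mask <- array(0L, d)
    for (z in seq_len(d[1]))
      mask[z, , ] <- segment_axial(vol$voxels[z, , ], method, threshold)
    cor <- project(mask, "coronal")
    sag <- project(mask, "sagittal")
  } else {
    pr <- .project_mask(vol$labels, dim(vol$labels))
    cor <- pr$coronal
    sag <- pr$sagittal
  }
  cor <- aspect_correct(cor, c(sp[1], sp[3]))
  sag <- aspect_correct(sag, c(sp[1], sp[2]))
  if (outline) {
    cor <- .outline_panel(cor)
    sag <- .outline_panel(sag)
  }
  sil <- compose_silhouette(cor, sag)
  attr(sil, "id") <- id
  if (!is.null(out_png)) write_silhouette(sil, out_png)
  sil
}

#' Write a silhouette as an 8-bit grayscale PNG with a provenance sidecar
#'
#' @param sil A `silhouette_image`.
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(sil, path) {
  png::writePNG(matrix(as.numeric(sil), nrow(sil), ncol(sil)), path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(id = attr(sil, "id"),
                            version = attr(sil, "version") %||% silfat_version(),
                            shape = dim(sil), foreground = sum(sil)),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a silhouette PNG written by [write_silhouette()]
#'
#' @param path PNG path.
#' @return A `silhouette_image`.
#' @export
read_silhouette <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  out <- matrix(as.integer(img >= 0.5), nrow(img), ncol(img))
  structure(out, class = c("silhouette_image", class(out)))
}
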