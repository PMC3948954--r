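#' Load an ROI coordinate table
#'
#' Reads a tab-separated table of spherical ROI definitions: one row per ROI
#' with a short label, the resting-state network it belongs to, a stereotaxic
#' center in mm and an optional sphere radius (default 12 mm). Row order is
#' preserved and fixes the row/column index of every downstream k x k
#' connectivity matrix. The label+network pair must be unique: nodes shared
#' between networks (e.g. the posterior cingulate appearing in both the
#' default-mode and the hippocampal-cortical memory network, with different
#' centers) are kept as distinct ROIs.
#'
#' The package ships a 33-ROI table covering four networks (12 DMN, 6 HCMN,
#' 6 DAN, 9 FPCN); see `cpgc_roi_table()`.
#'
#' @param path Path to a TSV file with columns `name`, `network`, `x`, `y`,
#'   `z` and optionally `radius` (mm).
#' @return A `roi_set`: a data frame with columns `name`, `network`, `x`,
#'   `y`, `z`, `radius`.
#' @export
#' @examples
#' rois <- load_roi_table(cpgc_roi_table())
#' nrow(rois)                 # 33
#' table(rois$network)
load_roi_table <- function(path) {
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot read ROI table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("ROI table '", path, "' is empty", call. = FALSE)
  required <- c("name", "network", "x", "y", "z")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("ROI table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"radius" %in% names(tab)) tab$radius <- 12
  tab$radius[is.na(tab$radius)] <- 12

  for (col in c("x", "y", "z", "radius")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           " (", tab$name[bad[1]], ")", call. = FALSE)
    if (anyNA(v))
      stop("missing value in column '", col, "' at row ",
           which(is.na(v))[1], call. = FALSE)
    tab[[col]] <- v
  }
  if (any(tab$radius <= 0))
    stop("ROI radius must be positive", call. = FALSE)

  key <- paste(tab$name, tab$network, sep = "@")
  if (anyDuplicated(key))
    stop("duplicate ROI name+network pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)

  out <- tab[, c("name", "network", "x", "y", "z", "radius")]
  rownames(out) <- NULL
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Path to the shipped 33-ROI coordinate table
#'
#' @return File path of the packaged TSV fixture.
#' @export
cpgc_roi_table <- function() {
  system.file("extdata", "roi_table_33.tsv", package = "cpgc",
              mustWork = TRUE)
}

#' ROI labels of a roi_set
#'
#' Labels are `name@network` so that nodes shared between networks stay
#' distinct; they name the rows/columns of all connectivity matrices.
#'
#' @param rois A `roi_set`.
#' @return Character vector of labels.
#' @export
roi_labels <- function(rois) paste(rois$name, rois$network, sep = "@")

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x), "ROIs in",
      length(unique(x$network)), "network(s)\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Define a voxel grid
#'
#' A regular grid given by its dimensions, voxel spacing and the mm
#' coordinate of the center of voxel (1,1,1). Equivalent to a diagonal
#' affine; an arbitrary 4x4 affine can be supplied instead.
#'
#' @param dim Integer vector (nx, ny, nz).
#' @param spacing Voxel size in mm (length 1 or 3).
#' @param origin mm coordinate of the first voxel center (default places the
#'   grid symmetrically around 0).
#' @param affine Optional 4x4 voxel-index-to-mm affine (1-based indices);
#'   overrides `spacing`/`origin`.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(dim, spacing = 3, origin = NULL, affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    stopifnot(all(spacing > 0))
    if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin - spacing  # voxel index 1 maps to origin
  } else {
    affine <- as.matrix(affine)
    stopifnot(all(dim(affine) == c(4L, 4L)))
    if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
      stop("grid affine is not invertible")
  }
  structure(list(dim = dim, affine = affine), class = "grid_spec")
}

# mm coordinates of the centers of the given voxel indices (n x 3 matrix)
voxel_to_mm <- function(grid, idx) {
  idx <- rbind(idx)
  mm <- cbind(idx, 1) %*% t(grid$affine[1:3, , drop = FALSE])
  unname(mm)
}

#' Build a spherical ROI voxel mask
#'
#' Selects every voxel whose center lies within `radius` mm (Euclidean,
#' closed ball) of the ROI center, optionally intersected with a brain mask.
#' A sphere falling entirely outside the grid or the brain mask yields an
#' empty mask with a warning, not an error.
#'
#' @param roi One row of a `roi_set` (or any list with `x`, `y`, `z`,
#'   `radius`, `name`).
#' @param grid A `grid_spec`.
#' @param brain_mask Optional logical array of dimension `grid$dim`, or a
#'   `voxel_mask`; voxels outside it are excluded.
#' @return A `voxel_mask`: list with `dim`, `affine`, integer voxel index
#'   matrix `voxels` (n x 3), `roi` label and logical `empty` flag.
#' @export
build_sphere_mask <- function(roi, grid, brain_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  center <- as.numeric(c(roi$x, roi$y, roi$z))
  radius <- as.numeric(roi$radius)
  stopifnot(length(center) == 3L, is.finite(radius), radius > 0)

  # bounding box of the sphere in voxel indices
  inv <- solve(grid$affine)
  corners <- as.matrix(expand.grid(center[1] + c(-radius, radius),
                                   center[2] + c(-radius, radius),
                                   center[3] + c(-radius, radius)))
  vox_corners <- cbind(corners, 1) %*% t(inv[1:3, , drop = FALSE])
  lo <- pmax(floor(apply(vox_corners, 2, min)), 1)
  hi <- pmin(ceiling(apply(vox_corners, 2, max)), grid$dim)

  voxels <- matrix(integer(0), 0, 3)
  if (all(lo <= hi)) {
    cand <- as.matrix(expand.grid(seq(lo[1], hi[1]), seq(lo[2], hi[2]),
                                  seq(lo[3], hi[3])))
    mm <- voxel_to_mm(grid, cand)
    d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
      (mm[, 3] - center[3])^2
    keep <- d2 <= radius^2
    if (!is.null(brain_mask)) {
      bm <- if (inherits(brain_mask, "voxel_mask"))
        mask_to_array(brain_mask) else brain_mask
      stopifnot(all(dim(bm) == grid$dim))
      keep <- keep & bm[cand]
    }
    voxels <- cand[keep, , drop = FALSE]
  }
  empty <- nrow(voxels) == 0L
  if (empty)
    warning("ROI '", roi$name %||% "?", "': sphere mask is empty ",
            "(outside the grid or the brain mask)", call. = FALSE)
  structure(list(dim = grid$dim, affine = grid$affine,
                 voxels = unname(voxels),
                 roi = as.character(roi$name %||% NA_character_),
                 empty = empty),
            class = "voxel_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a voxel mask to a logical array
#'
#' @param mask A `voxel_mask`.
#' @return Logical array of the mask's grid dimension.
#' @export
mask_to_array <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- array(FALSE, dim = mask$dim)
  if (nrow(mask$voxels)) arr[mask$voxels] <- TRUE
  arr
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("voxel mask", if (!is.na(x$roi)) paste0("'", x$roi, "'") else "",
      ": ", nrow(x$voxels), " voxels on a ",
      paste(x$dim, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}
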