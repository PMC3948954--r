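#' ROI time-series container
#'
#' Holds the multivariate series X(t) for one subject: a T x k numeric matrix
#' (rows = frames, columns = ROIs, named `name@network`) together with the
#' repetition time and a subject id.
#'
#' @param data T x k numeric matrix; column names label the ROIs.
#' @param tr Repetition time in seconds.
#' @param subject Subject identifier.
#' @return A `roi_ts` object.
#' @export
roi_ts <- function(data, tr = cpgc_defaults()$tr, subject = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series matrix must be numeric")
  if (anyNA(data) || any(!is.finite(data)))
    stop("time-series matrix contains missing or non-finite values")
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("roi", seq_len(ncol(data)))
  structure(list(data = data, tr = tr, subject = subject), class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("ROI time series: subject ", x$subject, ", ",
      nrow(x$data), " frames x ", ncol(x$data), " ROIs, TR ", x$tr, " s\n",
      sep = "")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

# Accept either a roi_ts or a bare matrix (+ tr); return a roi_ts.
as_roi_ts <- function(x, tr = NULL) {
  if (inherits(x, "roi_ts")) return(x)
  if (is.matrix(x)) {
    if (is.null(tr)) tr <- cpgc_defaults()$tr
    return(roi_ts(x, tr = tr))
  }
  stop("expected a 'roi_ts' or a numeric matrix")
}

#' Standardize ROI time series
#'
#' Centers each column to mean zero and scales to unit sample variance
#' (denominator T-1). Standardization is required before fitting the mMVAR
#' model. Idempotent.
#'
#' @param ts A `roi_ts` or T x k matrix.
#' @return Standardized `roi_ts`.
#' @export
#' @examples
#' standardize(matrix(c(1, 2, 3), ncol = 1))$data  # (-1, 0, 1)
standardize <- function(ts) {
  ts <- as_roi_ts(ts)
  sds <- apply(ts$data, 2, sd)
  if (any(sds == 0))
    stop("zero-variance ROI series: ",
         paste(colnames(ts$data)[sds == 0], collapse = ", "))
  ts$data <- scale(ts$data, center = TRUE, scale = sds)
  attr(ts$data, "scaled:center") <- NULL
  attr(ts$data, "scaled:scale") <- NULL
  ts
}

is_standardized <- function(x, tol = 1e-6) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  all(abs(mu) < tol) && all(abs(s - 1) < tol)
}

#' Extract ROI mean time series from a 4D volume
#'
#' Column j at time t is the arithmetic mean of the voxel values inside
#' mask j at frame t.
#'
#' @param volume4d 4D numeric array (x, y, z, t), or a path to a NIfTI file
#'   (read via the RNifti package if installed).
#' @param masks List of `voxel_mask` objects on the volume's grid.
#' @param tr Repetition time in seconds.
#' @param subject Subject identifier.
#' @return A `roi_ts` with one column per mask.
#' @export
extract_roi_series <- function(volume4d, masks, tr = cpgc_defaults()$tr,
                               subject = NA_character_) {
  if (is.character(volume4d)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI paths requires the RNifti package")
    volume4d <- as.array(RNifti::readNifti(volume4d))
  }
  stopifnot(is.array(volume4d), length(dim(volume4d)) == 4L)
  vdim <- dim(volume4d)[1:3]
  Tn <- dim(volume4d)[4]
  out <- matrix(NA_real_, Tn, length(masks))
  labels <- character(length(masks))
  for (j in seq_along(masks)) {
    m <- masks[[j]]
    stopifnot(inherits(m, "voxel_mask"))
    if (!all(m$dim == vdim))
      stop("mask grid does not match volume grid for ROI '", m$roi, "'")
    if (nrow(m$voxels) == 0L)
      stop("empty mask for ROI '", m$roi, "'")
    labels[j] <- m$roi
    flat <- m$voxels[, 1] + vdim[1] * (m$voxels[, 2] - 1) +
      vdim[1] * vdim[2] * (m$voxels[, 3] - 1)
    vol2d <- matrix(volume4d, prod(vdim), Tn)
    out[, j] <- colMeans(vol2d[flat, , drop = FALSE])
  }
  colnames(out) <- labels
  roi_ts(out, tr = tr, subject = subject)
}
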