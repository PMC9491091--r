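#' Cumulative integral of a time-activity curve
#'
#' For frame-averaged data the running integral is exact: the value at the
#' end of frame i is `sum_{j <= i} values[j] * duration[j]`. Units are
#' activity x seconds (durations are stored in seconds).
#'
#' @param x a [tac()].
#' @return Numeric vector of cumulative integrals at frame end times.
#' @export
cumulative_integral <- function(x) {
  stopifnot(inherits(x, "tac"))
  cumsum(x$values * x$schedule$duration)
}

#' Logan reference-region graphical fit
#'
#' Linearizes the target/reference relation: for frames with mid-time at or
#' beyond `tstar` (minutes), ordinary least squares of
#' `y_i = int_0^{t_i} CT / CT(t_i)` on
#' `x_i = (int_0^{t_i} Cref + Cref(t_i)/k2prime) / CT(t_i)`
#' (integrals evaluated at frame end times, in minutes; the `k2prime` term
#' is omitted when `k2prime` is `NULL`, the classic simplified reference
#' formulation). The asymptotic slope is the distribution volume ratio
#' (DVR); the intercept is in minutes.
#'
#' @param target,reference [tac()] objects sharing one schedule.
#' @param tstar linearity onset in minutes; only frames with mid-time >=
#'   `tstar` enter the fit (default 30, the final ~7 frames of the
#'   60-minute schedule).
#' @param k2prime optional reference-region efflux rate (1/min) for the
#'   full reference-Logan term; `NULL` omits it.
#' @return An object of class `logan_fit` with components `dvr` (slope),
#'   `intercept` (min), `tstar`, `k2prime`, `n_points`, `r2`, and the fit
#'   points `x`, `y`.
#' @examples
#' sch <- pk11195_frame_schedule()
#' ref <- reference_tac(sch)
#' fit <- logan_fit(ref, ref)   # self-reference: DVR exactly 1
#' coef(fit)
#' @export
logan_fit <- function(target, reference, tstar = 30, k2prime = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!isTRUE(all.equal(target$schedule$start, reference$schedule$start)) ||
      !isTRUE(all.equal(target$schedule$duration,
                        reference$schedule$duration)))
    stop("target and reference TACs must share one frame schedule")
  sch <- target$schedule
  use <- which(frame_mid_min(sch) >= tstar)
  if (length(use) == 0)
    stop("no frames at or beyond t* = ", tstar, " min")
  if (length(use) < 3)
    stop("fewer than 3 frames at or beyond t* = ", tstar, " min")
  if (any(target$values[use] <= 0))
    stop("non-positive target activity in the fit window")
  pts <- logan_points(target$values, reference$values, sch, use, k2prime)
  fit <- stats::lm.fit(cbind(1, pts$x), pts$y)
  r2 <- 1 - sum(fit$residuals^2) / sum((pts$y - mean(pts$y))^2)
  structure(list(dvr = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 tstar = tstar, k2prime = k2prime,
                 n_points = length(use), r2 = r2,
                 x = pts$x, y = pts$y),
            class = "logan_fit")
}

# Logan coordinates for a set of frames; integrals converted to minutes so
# the slope is dimensionless and the intercept is in minutes
logan_points <- function(target_values, reference_values, schedule, use,
                         k2prime = NULL) {
  int_t <- cumsum(target_values * schedule$duration)[use] / 60
  int_r <- cumsum(reference_values * schedule$duration)[use] / 60
  if (!is.null(k2prime)) int_r <- int_r + reference_values[use] / k2prime
  list(x = int_r / target_values[use], y = int_t / target_values[use])
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("Logan reference fit: DVR = %.4f (intercept %.3f min)\n",
              x$dvr, x$intercept))
  cat(sprintf("  t* = %g min, %d frames, R^2 = %.5f%s\n", x$tstar,
              x$n_points, x$r2,
              if (is.null(x$k2prime)) "" else
                sprintf(", k2' = %g /min", x$k2prime)))
  invisible(x)
}

#' @export
coef.logan_fit <- function(object, ...) {
  c(dvr = object$dvr, intercept = object$intercept)
}

#' @export
summary.logan_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @param x a `logan_fit`.
#' @param ... passed to [graphics::plot()].
#' @rdname logan_fit
#' @export
plot.logan_fit <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = "int Cref / CT (min)", ylab = "int CT / CT (min)",
                 main = sprintf("Logan plot (DVR = %.3f)", x$dvr), ...)
  graphics::abline(x$intercept, x$dvr, col = "red3")
  invisible(x)
}

#' Voxelwise Logan DVR map
#'
#' Computes the reference TAC as the mean over the atlas reference-region
#' voxels, then applies the Logan reference fit to every voxel inside the
#' union of the atlas role masks. Voxels with any non-positive activity in
#' the fit window are left undefined (`NaN`) and excluded from all
#' downstream statistics; everything outside the role masks is `NaN`.
#'
#' @param image a [dynamic_image()].
#' @param atlas a [label_atlas()] on the same grid.
#' @inheritParams logan_fit
#' @return An object of class `dvr_map`: list with `data` (3D array of DVR,
#'   `NaN` where undefined), `affine`, `tstar`, `k2prime`,
#'   `reference_label`, `n_defined`.
#' @export
dvr_map <- function(image, atlas, tstar = 30, k2prime = NULL) {
  stopifnot(inherits(image, "dynamic_image"), inherits(atlas, "label_atlas"))
  d <- dim(image$data)
  check_same_grid(d, image$affine, dim(atlas$labels), atlas$affine,
                  "image and atlas")
  sch <- image$schedule
  ref_mask <- role_mask(atlas, "reference_region")
  if (!any(ref_mask)) stop("empty reference region")
  flat <- matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
  ref_values <- colMeans(flat[as.vector(ref_mask), , drop = FALSE])

  use <- which(frame_mid_min(sch) >= tstar)
  if (length(use) < 3)
    stop("fewer than 3 frames at or beyond t* = ", tstar, " min")

  fit_mask <- as.vector(atlas$labels > 0)
  vox <- which(fit_mask)
  tv <- flat[vox, use, drop = FALSE]              # voxels x window frames
  ok <- rowSums(tv <= 0) == 0
  out <- rep(NaN, prod(d[1:3]))
  if (any(ok)) {
    tv <- tv[ok, , drop = FALSE]
    # running integral per voxel as one matrix product with the
    # lower-triangular summation matrix (exact for frame-averaged data)
    L <- outer(seq_len(d[4]), seq_len(d[4]), `<=`) * 1
    wt <- sweep(flat[vox[ok], , drop = FALSE], 2, sch$duration, `*`)
    int_t <- (wt %*% L)[, use, drop = FALSE] / 60
    int_r <- cumsum(ref_values * sch$duration)[use] / 60
    xr <- if (is.null(k2prime)) int_r else int_r + ref_values[use] / k2prime
    y <- int_t / tv
    x <- matrix(xr, nrow = nrow(tv), ncol = length(use), byrow = TRUE) / tv
    n <- length(use)
    sx <- rowSums(x); sy <- rowSums(y)
    slope <- (n * rowSums(x * y) - sx * sy) / (n * rowSums(x * x) - sx^2)
    out[vox[ok]] <- slope
  }
  n_undef <- sum(fit_mask) - sum(ok)
  if (n_undef > 0)
    message(n_undef, " voxel(s) undefined (non-positive activity in fit window)")
  structure(list(data = array(out, dim = d[1:3]), affine = image$affine,
                 tstar = tstar, k2prime = k2prime,
                 reference_label = atlas$roles$reference_region,
                 n_defined = sum(ok)),
            class = "dvr_map")
}

#' @export
print.dvr_map <- function(x, ...) {
  cat(sprintf("DVR map: %s grid, %d defined voxels (t* = %g min)\n",
              paste(dim(x$data), collapse = "x"), x$n_defined, x$tstar))
  invisible(x)
}

#' Write / read a DVR map as NIfTI with a JSON provenance sidecar
#'
#' @param map a [dvr_map()].
#' @param path NIfTI output path; the provenance sidecar takes the same
#'   path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_dvr_map <- function(map, path) {
  stopifnot(inherits(map, "dvr_map"))
  nii <- as_nifti_with_affine(map$data, map$affine)
  RNifti::writeNifti(nii, path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(tstar = map$tstar,
         k2prime = if (is.null(map$k2prime)) NA else map$k2prime,
         reference_label = map$reference_label, n_defined = map$n_defined),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dvr_map
#' @export
read_dvr_map <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected 3D DVR map")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  prov <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  dat <- array(as.numeric(img), dim = d)
  structure(list(data = dat, affine = affine,
                 tstar = prov$tstar %||% NA,
                 k2prime = if (is.null(prov$k2prime) || is.na(prov$k2prime))
                   NULL else prov$k2prime,
                 reference_label = prov$reference_label %||% NA,
                 n_defined = sum(is.finite(dat))),
            class = "dvr_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
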