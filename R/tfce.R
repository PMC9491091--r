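#' Voxelwise two-sample pooled-variance t map
#'
#' Unpaired two-sample t statistic (group A minus group B, pooled
#' variance) at every mask voxel. Voxels where any subject's map is
#' undefined are dropped from the analysis mask.
#'
#' @param maps_A,maps_B lists of [dvr_map()] objects (or 3D arrays), one
#'   per subject; at least 2 per group.
#' @param mask 3D logical analysis mask.
#' @return A list: `t` (3D array, `NaN` outside the effective mask),
#'   `mask` (effective 3D logical mask after NaN exclusion).
#' @export
tstat_map <- function(maps_A, maps_B, mask) {
  XA <- stack_maps(maps_A, mask)
  XB <- stack_maps(maps_B, mask)
  if (nrow(XA) < 2 || nrow(XB) < 2)
    stop("each group needs at least 2 subjects")
  keep <- colSums(!is.finite(XA)) == 0 & colSums(!is.finite(XB)) == 0
  if (!any(keep)) stop("empty effective mask (all voxels undefined)")
  tvals <- pooled_t(XA[, keep, drop = FALSE], XB[, keep, drop = FALSE])
  out <- array(NaN, dim = dim(mask))
  eff <- array(FALSE, dim = dim(mask))
  idx <- which(mask)[keep]
  out[idx] <- tvals
  eff[idx] <- TRUE
  list(t = out, mask = eff)
}

# subjects x mask-voxels matrix from a list of dvr_map/arrays
stack_maps <- function(maps, mask) {
  rows <- lapply(maps, function(m) {
    a <- if (inherits(m, "dvr_map")) m$data else m
    if (!all(dim(a) == dim(mask))) stop("map grid does not match mask")
    a[mask]
  })
  do.call(rbind, rows)
}

# pooled-variance two-sample t on subjects x voxels matrices (A minus B);
# zero pooled variance yields 0 (identical constant groups), not NaN
pooled_t <- function(XA, XB) {
  nA <- nrow(XA); nB <- nrow(XB)
  mA <- colMeans(XA); mB <- colMeans(XB)
  ssA <- colSums(sweep(XA, 2, mA)^2)
  ssB <- colSums(sweep(XB, 2, mB)^2)
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tv <- (mA - mB) / se
  tv[se == 0] <- 0
  tv
}

#' Configuration for TFCE permutation inference
#'
#' @param E cluster-extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` (default) adapts to max-statistic/100.
#' @param connectivity 3D neighbourhood: 6, 18 or 26 (default 26).
#' @param n_perm number of random permutations (default 5000); the
#'   observed labeling always counts as one additional member of the null,
#'   and when `n_perm` meets or exceeds the number of distinct relabelings
#'   the test switches to exhaustive enumeration.
#' @param seed integer seed for the permutation sampler.
#' @param alpha family-wise significance level (default 0.05).
#' @param direction `"A>B"` or `"B>A"`; each direction is a separate
#'   one-sided test with its own correction.
#' @return A list of class `tfce_config`.
#' @export
tfce_config <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26,
                        n_perm = 5000, seed = 1L, alpha = 0.05,
                        direction = c("A>B", "B>A")) {
  direction <- match.arg(direction)
  if (E <= 0 || H <= 0) stop("E and H must be positive")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (!(connectivity %in% c(6, 18, 26)))
    stop("connectivity must be 6, 18 or 26")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  structure(list(E = E, H = H, dh = dh, connectivity = connectivity,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alpha = alpha, direction = direction),
            class = "tfce_config")
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each voxel, integrates `extent(h)^E * h^H` over thresholds
#' `h = dh, 2dh, ...` up to the voxel's statistic, where `extent(h)` is
#' the size of the connected supra-threshold component containing the
#' voxel. Voxels with non-positive statistics (and voxels outside the
#' mask) score zero.
#'
#' @param stat_map 3D numeric statistic map (finite inside the mask).
#' @param mask 3D logical mask.
#' @param E,H,dh,connectivity see [tfce_config()]; `dh = NULL` uses
#'   max-statistic/100.
#' @return 3D numeric TFCE map.
#' @export
tfce_transform <- function(stat_map, mask, E = 0.5, H = 2, dh = NULL,
                           connectivity = 26) {
  if (!all(dim(stat_map) == dim(mask))) stop("stat map and mask grids differ")
  sv <- stat_map[mask]
  if (any(!is.finite(sv))) stop("non-finite statistic inside mask")
  mx <- max(c(0, sv))
  if (mx <= 0) return(array(0, dim = dim(mask)))
  if (is.null(dh)) dh <- mx / 100
  s <- stat_map
  s[!mask] <- 0
  out <- .tfce_cpp(as.numeric(s), as.integer(dim(mask)),
                   as.logical(mask), E, H, dh, as.integer(connectivity))
  array(out, dim = dim(mask))
}

#' Permutation max-TFCE family-wise error corrected group comparison
#'
#' One-sided two-sample test: the observed group labeling's t map is
#' TFCE-enhanced, and compared voxelwise against the permutation null of
#' the mask-wide maximum TFCE under random relabelings. The null always
#' contains the observed labeling; with `m` total relabelings the
#' corrected p-value at voxel v is
#' `p(v) = #\{ null max >= TFCE_obs(v) \} / m`, so `p >= 1/m` everywhere.
#' When `config$n_perm` meets or exceeds the number of distinct
#' relabelings the null is enumerated exhaustively (`m` = number of
#' distinct relabelings); otherwise `m = n_perm + 1` (observed plus
#' sampled).
#'
#' @param maps list of [dvr_map()] objects (or 3D arrays), one per subject.
#' @param groups character/factor of length `length(maps)` with exactly two
#'   levels; the first level is group "A" of the configured direction.
#' @param mask 3D logical analysis mask.
#' @param config a [tfce_config()].
#' @param exhaustive force exhaustive enumeration (errors if `n_perm` is
#'   smaller than the number of distinct relabelings).
#' @return An object of class `tfce_result`: `t_map`, `tfce_map`,
#'   `null_max`, `p_fwe_map`, `sig_mask`, `mask`, `config`, `n_null`.
#' @export
permutation_fwe <- function(maps, groups, mask, config = tfce_config(),
                            exhaustive = FALSE) {
  stopifnot(inherits(config, "tfce_config"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels, got ", nlevels(groups))
  if (length(maps) != length(groups))
    stop("one map per subject required")
  if (min(table(groups)) < 2) stop("each group needs at least 2 subjects")

  X <- stack_maps(maps, mask)
  keep <- colSums(!is.finite(X)) == 0
  if (!any(keep)) stop("empty effective mask (all voxels undefined)")
  X <- X[, keep, drop = FALSE]
  eff_mask <- array(FALSE, dim = dim(mask))
  eff_mask[which(mask)[keep]] <- TRUE

  isA <- groups == levels(groups)[1]
  sign <- if (config$direction == "A>B") 1 else -1
  n <- length(groups); nA <- sum(isA)

  # relabelings: observed first, then sampled or enumerated
  n_distinct <- choose(n, nA)
  use_exhaustive <- exhaustive || config$n_perm >= n_distinct
  if (exhaustive && config$n_perm > n_distinct)
    stop("n_perm (", config$n_perm, ") exceeds the number of distinct ",
         "relabelings (", n_distinct, ") in exhaustive mode")
  if (use_exhaustive) {
    combs <- utils::combn(n, nA)
    relab <- lapply(seq_len(ncol(combs)), function(j) {
      z <- rep(FALSE, n); z[combs[, j]] <- TRUE; z
    })
    m <- n_distinct
  } else {
    set.seed(config$seed)
    relab <- c(list(isA), lapply(seq_len(config$n_perm), function(j) {
      z <- rep(FALSE, n); z[sample.int(n, nA)] <- TRUE; z
    }))
    m <- config$n_perm + 1L
  }

  # fixed dh across all permutations so null and observed are comparable
  t_obs <- sign * pooled_t(X[isA, , drop = FALSE], X[!isA, , drop = FALSE])
  dh <- config$dh %||% (max(c(t_obs, 0)) / 100)
  # observed map wholly non-positive: TFCE_obs is 0 everywhere, so every
  # p is 1 whatever the null; any positive dh keeps the sweep cheap
  if (dh <= 0) dh <- 1

  tfce_of <- function(tv) {
    s <- array(0, dim = dim(mask))
    s[eff_mask] <- tv
    tfce_transform(s, eff_mask, E = config$E, H = config$H, dh = dh,
                   connectivity = config$connectivity)
  }
  tfce_obs <- tfce_of(t_obs)

  null_max <- vapply(relab, function(a) {
    tv <- sign * pooled_t(X[a, , drop = FALSE], X[!a, , drop = FALSE])
    max(tfce_of(tv))
  }, numeric(1))

  obs_vals <- tfce_obs[eff_mask]
  # p(v) = share of null maxima at or above the observed TFCE
  p_vals <- (length(null_max) -
               findInterval(obs_vals - 1e-12, sort(null_max))) /
    length(null_max)
  p_map <- array(NaN, dim = dim(mask))
  p_map[eff_mask] <- p_vals
  t_map <- array(NaN, dim = dim(mask))
  t_map[eff_mask] <- t_obs
  sig <- array(FALSE, dim = dim(mask))
  sig[eff_mask] <- p_vals < config$alpha

  structure(list(t_map = t_map, tfce_map = tfce_obs, null_max = null_max,
                 p_fwe_map = p_map, sig_mask = sig, mask = eff_mask,
                 config = config, n_null = m,
                 exhaustive = use_exhaustive),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf(
    "TFCE permutation result (%s, %s): %d null relabelings\n",
    x$config$direction, if (x$exhaustive) "exhaustive" else "sampled",
    x$n_null))
  cat(sprintf("  min corrected p = %.4g; %d significant voxel(s) at alpha %g\n",
              min(x$p_fwe_map[x$mask]), sum(x$sig_mask), x$config$alpha))
  invisible(x)
}
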