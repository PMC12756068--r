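# Whole-lesion segmentation: fuzzy C-means intensity clustering grown from
# a manually supplied 2D seed ROI on the b = 800 s/mm^2 volume, plus the
# ROI utilities (connected components, map extraction).

#' ROI masks on the image grid
#'
#' A boolean voxel set on the DWI grid, tagged as a single-slice 2D seed
#' or a 3D whole-lesion mask.
#'
#' @param mask 3D logical array on the image grid. For a 2D ROI, all TRUE
#'   voxels must lie on one z-slice.
#' @param type `"2d"` (seed) or `"3d"` (whole lesion).
#' @return Object of class `roi_mask` with `mask`, `type` and, for 2D,
#'   the `slice` index.
#' @export
roi_mask <- function(mask, type = c("3d", "2d")) {
  type <- match.arg(type)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("ROI mask is empty")
  slice <- NA_integer_
  if (type == "2d") {
    zs <- unique(which(mask, arr.ind = TRUE)[, 3])
    if (length(zs) != 1L) stop("a 2D ROI must lie on exactly one slice")
    slice <- zs
  }
  structure(list(mask = mask, type = type, slice = slice),
            class = "roi_mask")
}

#' Build a 2D seed ROI from an in-plane mask and slice index
#' @param mask2d Logical matrix (in-plane mask).
#' @param slice z-index of the slice the mask sits on.
#' @param grid 3-vector, full image grid dimensions.
#' @return A 2D [roi_mask()].
#' @export
seed_roi <- function(mask2d, slice, grid) {
  stopifnot(length(grid) == 3L, all(dim(mask2d) == grid[1:2]),
            slice >= 1L, slice <= grid[3])
  m <- array(FALSE, grid)
  m[, , slice] <- mask2d
  roi_mask(m, "2d")
}

#' Fuzzy C-means configuration
#'
#' @param n_clusters Number of clusters, >= 2; default 2
#'   (lesion vs background).
#' @param m Fuzzifier, > 1; default 2.
#' @param tolerance Convergence threshold on the largest centroid shift.
#' @param max_iter Iteration cap.
#' @param seed Integer seed (used only for jittered restarts).
#' @param margin In-plane bounding-box dilation (voxels) around the 2D
#'   seed defining the clustering domain; default 10.
#' @return Object of class `fcm_config`.
#' @export
fcm_config <- function(n_clusters = 2L, m = 2.0, tolerance = 1e-5,
                       max_iter = 100L, seed = 1L, margin = 10L) {
  stopifnot(n_clusters >= 2L, m > 1, tolerance > 0, max_iter >= 1L,
            margin >= 0L)
  structure(list(n_clusters = as.integer(n_clusters), m = m,
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), margin = as.integer(margin)),
            class = "fcm_config")
}

#' Fuzzy C-means clustering of a 1D intensity sample
#'
#' Minimises the standard FCM objective
#' \eqn{J = \sum_{i,k} u_{ik}^m \|x_k - c_i\|^2} by alternating the
#' closed-form membership and centroid updates. Centroids are initialised
#' deterministically at evenly spaced quantiles of the data (the 10th and
#' 90th percentiles for two clusters), so repeated runs are identical.
#'
#' @param values Numeric vector of intensities (needs at least
#'   `n_clusters` distinct values).
#' @param config An [fcm_config()].
#' @return List with `membership` (n x c matrix, rows sum to 1),
#'   `centroids` (ascending), `objective` (value per iteration,
#'   non-increasing), `n_iter`, `converged`.
#' @export
fcm_cluster <- function(values, config = fcm_config()) {
  stopifnot(inherits(config, "fcm_config"))
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("non-finite intensities")
  c <- config$n_clusters
  if (length(unique(x)) < c)
    stop("degenerate input: fewer distinct values than clusters")
  probs <- seq(0.1, 0.9, length.out = c)
  centroids <- as.numeric(stats::quantile(x, probs, names = FALSE))
  # quantile init can collide on spiky data; nudge apart deterministically
  if (any(duplicated(centroids)))
    centroids <- centroids + seq_len(c) * diff(range(x)) * 1e-6
  objective <- numeric(0)
  u <- NULL
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    d2 <- outer(x, centroids, function(a, b) (a - b)^2)   # n x c
    d2 <- pmax(d2, .Machine$double.xmin)
    inv <- d2^(-1 / (config$m - 1))
    u <- inv / rowSums(inv)
    objective <- c(objective, sum(u^config$m * d2))
    um <- u^config$m
    new_centroids <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift < config$tolerance) { converged <- TRUE; break }
  }
  ord <- order(centroids)
  list(membership = u[, ord, drop = FALSE], centroids = centroids[ord],
       objective = objective, n_iter = length(objective),
       converged = converged)
}

# 26-connected component containing any of the `seed_idx` voxels, within
# the candidate set `cand` (3D logical). BFS flood fill.
connected_component_26 <- function(cand, seed_idx) {
  grid <- dim(cand)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lin_offs <- offs[, 1] + offs[, 2] * grid[1] + offs[, 3] * grid[1] * grid[2]
  comp <- array(FALSE, grid)
  frontier <- intersect(seed_idx, which(cand))
  comp[frontier] <- TRUE
  arr_of <- function(i) arrayInd(i, grid)
  while (length(frontier)) {
    ai <- arr_of(frontier)
    nxt <- integer(0)
    for (j in seq_along(lin_offs)) {
      # drop steps that would wrap across a grid edge
      ok <- ai[, 1] + offs[j, 1] >= 1 & ai[, 1] + offs[j, 1] <= grid[1] &
            ai[, 2] + offs[j, 2] >= 1 & ai[, 2] + offs[j, 2] <= grid[2] &
            ai[, 3] + offs[j, 3] >= 1 & ai[, 3] + offs[j, 3] <= grid[3]
      cnd <- frontier[ok] + lin_offs[j]
      cnd <- cnd[cand[cnd] & !comp[cnd]]
      comp[cnd] <- TRUE
      nxt <- c(nxt, cnd)
    }
    frontier <- unique(nxt)
  }
  comp
}

#' Grow a 2D seed ROI into a 3D whole-lesion ROI by fuzzy C-means
#'
#' Clusters the intensities of the b = 800 s/mm^2 volume inside a search
#' region (the seed's in-plane bounding box dilated by `config$margin`
#' voxels, across all slices), picks the cluster with the highest mean
#' membership over the seed, binarises at membership >= 0.5 and keeps the
#' 26-connected component overlapping the seed.
#'
#' @param vol 3D numeric array, the b = 800 volume.
#' @param roi2d A 2D [roi_mask()] seed on the same grid.
#' @param config An [fcm_config()].
#' @return A 3D [roi_mask()]. Errors if the selected component is empty
#'   or recovers less than half of the seed voxels.
#' @export
segment_lesion_3d <- function(vol, roi2d, config = fcm_config()) {
  stopifnot(length(dim(vol)) == 3L, inherits(roi2d, "roi_mask"),
            roi2d$type == "2d")
  if (!all(dim(roi2d$mask) == dim(vol)))
    stop("seed ROI is not on the volume grid")
  grid <- dim(vol)
  seed_idx <- which(roi2d$mask)
  ai <- arrayInd(seed_idx, grid)
  mar <- config$margin
  xr <- c(max(1L, min(ai[, 1]) - mar), min(grid[1], max(ai[, 1]) + mar))
  yr <- c(max(1L, min(ai[, 2]) - mar), min(grid[2], max(ai[, 2]) + mar))
  region <- array(FALSE, grid)
  region[xr[1]:xr[2], yr[1]:yr[2], ] <- TRUE
  reg_idx <- which(region)
  fcm <- fcm_cluster(vol[reg_idx], config)
  # membership rows are in reg_idx order; find the seed rows
  seed_rows <- match(seed_idx, reg_idx)
  lesion_cluster <- which.max(colMeans(
    fcm$membership[seed_rows, , drop = FALSE]))
  cand <- array(FALSE, grid)
  cand[reg_idx] <- fcm$membership[, lesion_cluster] >= 0.5
  comp <- connected_component_26(cand, seed_idx)
  n_comp <- sum(comp)
  seed_kept <- sum(comp[seed_idx])
  if (n_comp == 0L)
    stop("segmentation failure: selected cluster component is empty ",
         sprintf("(centroids %s)", paste(signif(fcm$centroids, 4),
                                         collapse = ", ")))
  if (seed_kept < 0.5 * length(seed_idx))
    stop(sprintf(paste0("segmentation failure: component keeps only ",
                        "%d/%d seed voxels"), seed_kept, length(seed_idx)))
  roi_mask(comp, "3d")
}

#' Extract parameter-map values inside a 3D ROI
#'
#' Copies the whole-lesion ROI onto fitted parameter maps and returns the
#' ordered voxel values per parameter, excluding voxels whose fit failed
#' (and, for `mu`, voxels flagged mu-unidentifiable when
#' `exclude_unidentifiable_mu` is set).
#'
#' @param roi3d A 3D [roi_mask()].
#' @param maps A `parameter_maps` object from [fit_volume()].
#' @param exclude_unidentifiable_mu Drop mu values at voxels where beta
#'   made mu unidentifiable; default TRUE.
#' @return List with `values` (named list of numeric vectors, one per
#'   parameter map), `n_roi` (ROI voxel count), and `n_excluded` (named
#'   integer vector of per-parameter exclusion counts).
#' @export
copy_roi_to_maps <- function(roi3d, maps, exclude_unidentifiable_mu = TRUE) {
  stopifnot(inherits(roi3d, "roi_mask"), inherits(maps, "parameter_maps"))
  if (!all(dim(roi3d$mask) == dim(maps$fitted)))
    stop("ROI and parameter maps are on different grids")
  idx <- which(roi3d$mask)
  ok <- maps$fitted[idx]
  values <- lapply(names(maps$maps), function(nm) {
    keep <- ok
    if (nm == "mu" && exclude_unidentifiable_mu)
      keep <- keep & !maps$mu_unidentifiable[idx]
    maps$maps[[nm]][idx[keep]]
  })
  names(values) <- names(maps$maps)
  n_excl <- vapply(names(values),
                   function(nm) length(idx) - length(values[[nm]]),
                   integer(1))
  list(values = values, n_roi = length(idx), n_excluded = n_excl)
}

#' Dice overlap between two masks
#' @param a,b 3D logical arrays or [roi_mask()] objects.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "roi_mask")) a <- a$mask
  if (inherits(b, "roi_mask")) b <- b$mask
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
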