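#' @include AllClasses.R pico.R
NULL

#' Canonical streamline of a set
#'
#' The most representative pathway of a streamline collection: among the first
#' `nUse` successful streamlines (successful = retained by all filters applied
#' upstream), the one with the greatest number of points of agreement with all
#' the others, where agreement between two streamlines is the number of voxels
#' their voxelised paths share. Ties go to the earliest emitted streamline.
#' The winner is typically used as the line of interest (LOI) for along-tract
#' profiles.
#'
#' @param streams A non-empty [StreamlineSet].
#' @param nUse Number of leading streamlines entered into the comparison
#'   (default 100).
#' @return A [Streamline-class] object.
#' @export
canonicalStreamline <- function(streams, nUse = 100L) {
  stopifnot(is(streams, "StreamlineSet"))
  n <- min(length(streams), as.integer(nUse))
  if (n < 1L) stop("no successful streamlines to choose from")
  sets <- lapply(streams@paths[seq_len(n)], unique)
  score <- numeric(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      si <- sets[[i]]
      for (j in (i + 1L):n) {
        ov <- length(intersect(si, sets[[j]]))
        score[i] <- score[i] + ov
        score[j] <- score[j] + ov
      }
    }
  }
  streams[[which.max(score)]]
}

# ordered voxel path (n x 3 -> linear) of a Streamline or voxel matrix
.loiPath <- function(loi) {
  if (is(loi, "Streamline")) return(loi@voxels)
  stopifnot(is.matrix(loi), ncol(loi) == 3L)
  loi
}

#' Along-tract profile of a map over a line of interest
#'
#' Walks the voxelised path of the LOI outward from the seed region and
#' records the map value at every distinct voxel. Distance is counted in
#' distinct-voxel steps: the last seed voxel on the LOI (the seed boundary) is
#' distance 0, the first extra-seed voxel distance 1, and so on; revisited
#' voxels are collapsed. When the LOI extends on both sides of the seed (a
#' bidirectional streamline), the longer side is profiled.
#'
#' @param map A [PICoMap], [IntraTractConfidenceMap] or numeric 3-D array.
#' @param loi A [Streamline-class] (e.g. from [canonicalStreamline()]) or an
#'   ordered n x 3 voxel matrix; must intersect the seed.
#' @param seed The seed [Region].
#' @return A [TractProfile].
#' @export
extractProfile <- function(map, loi, seed) {
  stopifnot(is(seed, "Region"))
  values <- if (is(map, "PICoMap")) map@values else map
  stopifnot(length(dim(values)) == 3L)
  .stopifnotSameGrid(dim(values), seed@dims)
  path <- .loiPath(loi)
  lins <- .lin(path, seed@dims)
  lut <- .regionLookup(seed)
  inSeed <- lut[lins]
  if (!any(inSeed)) stop("the line of interest does not intersect the seed")
  iFirst <- min(which(inSeed))
  iLast <- max(which(inSeed))
  fwd <- lins[iLast:length(lins)]
  bwd <- lins[iFirst:1L]
  walk <- if (length(unique(fwd)) >= length(unique(bwd))) fwd else bwd
  walk <- walk[!duplicated(walk)]
  TractProfile(distance = as.numeric(seq_along(walk) - 1L),
               value = values[walk],
               loiVoxels = .coords(walk, seed@dims))
}

#' Linear path-length compensation of a profile
#'
#' Multiplies each profile value by its voxel distance from the seed region
#' (the classic linear correction for path-length dependency). The seed
#' boundary sample (distance 0) is scaled by 1 rather than annihilated. The
#' operation is exactly invertible for distances >= 1. Because the decay of
#' probabilistic tractography is non-linear wherever the tract traverses
#' complex regions, this correction cannot flatten such profiles — the
#' behaviour ICE-T is designed to fix.
#'
#' @param profile A [TractProfile].
#' @return A [TractProfile] with compensated values.
#' @export
linearCompensation <- function(profile) {
  stopifnot(is(profile, "TractProfile"))
  TractProfile(distance = profile@distance,
               value = profile@value * pmax(profile@distance, 1),
               loiVoxels = profile@loiVoxels)
}

#' Rank-correlation decline statistic of a profile
#'
#' Spearman rank correlation between distance and value, in [-1, 1]: -1 for a
#' strictly decreasing profile (the path-length-dependency signature), 0 by
#' convention for a constant profile.
#'
#' @param profile A [TractProfile] with at least 3 samples.
#' @return A number in [-1, 1].
#' @export
declineStatistic <- function(profile) {
  stopifnot(is(profile, "TractProfile"))
  if (length(profile@distance) < 3L) stop("profile must have >= 3 samples")
  if (length(unique(profile@value)) == 1L) return(0)
  stats::cor(profile@distance, profile@value, method = "spearman")
}

#' Cross-sectional area profile of a region along a centerline
#'
#' Assigns every region voxel to its nearest centerline point and counts
#' voxels per centerline arc-length bin (one bin per centerline point, in
#' order). A tract segmentation free of path-length dependency shows an
#' approximately constant count along its length.
#'
#' @param region A non-empty [Region].
#' @param centerline Ordered n x 3 voxel matrix (or [Streamline-class]).
#' @return A data.frame with columns `distance` (bin index, 0-based) and
#'   `count`.
#' @export
crossSectionProfile <- function(region, centerline) {
  stopifnot(is(region, "Region"))
  if (regionSize(region) == 0L) stop("region is empty")
  cl <- .loiPath(centerline)
  v <- region@voxels
  # nearest centerline point per region voxel
  d2 <- outer(rowSums(v^2), rep(1, nrow(cl))) +
    outer(rep(1, nrow(v)), rowSums(cl^2)) - 2 * v %*% t(cl)
  nearest <- max.col(-d2, ties.method = "first")
  counts <- tabulate(nearest, nbins = nrow(cl))
  data.frame(distance = seq_len(nrow(cl)) - 1L, count = counts)
}

#' Near-seed false-positive flare metric
#'
#' Fraction of segmented voxels lying within `nearRadius` of the seed region
#' that fall outside the ground-truth bundle mask. Plain probabilistic
#' tractography thresholded low enough to reach the distal tract shows a
#' near-seed flare (high values); an ICE-T segmentation at matched extent
#' should not.
#'
#' @param region The segmentation [Region] under test.
#' @param seed The seed [Region].
#' @param bundleMask Ground-truth logical array.
#' @param nearRadius Neighbourhood radius around the seed, voxels.
#' @return A fraction in [0, 1] (0 when no segmented voxel is near the seed).
#' @export
flareMetric <- function(region, seed, bundleMask, nearRadius) {
  stopifnot(is(region, "Region"), is(seed, "Region"))
  .stopifnotSameGrid(region@dims, seed@dims)
  .stopifnotSameGrid(region@dims, dim(bundleMask))
  if (regionSize(region) == 0L || regionSize(seed) == 0L) return(0)
  v <- region@voxels
  s <- seed@voxels
  d2 <- outer(rowSums(v^2), rep(1, nrow(s))) +
    outer(rep(1, nrow(v)), rowSums(s^2)) - 2 * v %*% t(s)
  near <- sqrt(pmax(apply(d2, 1L, min), 0)) <= nearRadius
  if (!any(near)) return(0)
  outside <- !bundleMask[.lin(v, region@dims)]
  sum(near & outside) / sum(near)
}

#' Dice overlap coefficient of two regions
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty regions have Dice 1 by
#' convention.
#'
#' @param a,b [Region] objects on the same grid.
#' @return A number in [0, 1].
#' @examples
#' r <- Region(rbind(c(1, 1, 1)), dims = c(2, 2, 2))
#' diceCoefficient(r, r)
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "Region"), is(b, "Region"))
  .stopifnotSameGrid(a@dims, b@dims)
  na <- regionSize(a)
  nb <- regionSize(b)
  if (na + nb == 0L) return(1)
  ov <- length(intersect(.lin(a@voxels, a@dims), .lin(b@voxels, b@dims)))
  2 * ov / (na + nb)
}
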