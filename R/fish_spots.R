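#' Label connected components in a 3D mask (26-connectivity)
#'
#' Union-find over the true voxels: for each of the 26 neighbour offsets,
#' voxels whose neighbour is also in the mask are merged. Fast enough for
#' spot masks, which contain at most a few thousand voxels.
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered 1..k in first-voxel order.
#' @export
label_components_3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask)
  out <- array(0L, d)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- arrayInd(idx, d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0 & offsets$dz == 0), ]
  # only the 13 "forward" offsets are needed; each unordered pair is seen once
  offsets <- offsets[seq_len(13L), ]
  for (k in seq_len(nrow(offsets))) {
    nx <- pos[, 1L] + offsets$dx[k]
    ny <- pos[, 2L] + offsets$dy[k]
    nz <- pos[, 3L] + offsets$dz[k]
    ok <- nx >= 1L & nx <= d[1L] & ny >= 1L & ny <= d[2L] &
      nz >= 1L & nz <= d[3L]
    if (!any(ok)) next
    nb_lin <- nx[ok] + (ny[ok] - 1L) * d[1L] + (nz[ok] - 1L) * d[1L] * d[2L]
    j <- match(nb_lin, idx)
    hit <- which(!is.na(j))
    src <- which(ok)[hit]
    dst <- j[hit]
    for (m in seq_along(src)) {
      a <- find(src[m]); b <- find(dst[m])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  labels <- match(roots, unique(roots))
  out[idx] <- labels
  out
}

#' Detect probe spots in an image channel
#'
#' Thresholds the channel, labels 26-connected components, discards
#' components smaller than `min_voxels` (treated as noise), and returns
#' the intensity-weighted centroid of each remaining component in
#' physical micrometres (voxel-centre convention, anisotropic voxel
#' scaling applied).
#'
#' @param stack an [image_stack].
#' @param channel channel name.
#' @param method threshold method (see [threshold_mask()]); the default
#'   `fraction_of_max` at 0.3 suits bright spots on a dark background.
#' @param fraction,value threshold parameters.
#' @param min_voxels minimum component size (voxels).
#' @return data.frame: spot, x, y, z (um), n_voxels, intensity. Empty
#'   (zero-row) if nothing is detected, with a message.
#' @export
detect_spots <- function(stack, channel, method = "fraction_of_max",
                         fraction = 0.3, value = NULL, min_voxels = 2L) {
  vm <- withCallingHandlers(
    threshold_mask(stack, channel, method = method,
                   value = value, fraction = fraction),
    warning = function(w) invokeRestart("muffleWarning"))
  img <- stack_channel(stack, channel)
  lab <- label_components_3d(vm$mask)
  empty <- data.frame(spot = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_voxels = integer(0),
                      intensity = numeric(0))
  if (!any(lab > 0L)) {
    message(sprintf("detect_spots: no spots on channel '%s'", channel))
    return(empty)
  }
  vs <- stack$voxel_size
  idx <- which(lab > 0L)
  comp <- lab[idx]
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0L) {
    message(sprintf("detect_spots: no spots >= %d voxels on channel '%s'",
                    min_voxels, channel))
    return(empty)
  }
  pos <- arrayInd(idx, dim(vm$mask))
  w <- img[idx]
  out <- lapply(seq_along(keep), function(s) {
    sel <- comp == keep[s]
    ws <- w[sel]
    ctr <- colSums(pos[sel, , drop = FALSE] * ws) / sum(ws)
    data.frame(spot = s,
               x = (ctr[1L] - 0.5) * vs[1L],
               y = (ctr[2L] - 0.5) * vs[2L],
               z = (ctr[3L] - 0.5) * vs[3L],
               n_voxels = sum(sel), intensity = sum(ws))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair spots across two channels and measure 3D distances
#'
#' Greedy mutual-nearest pairing: repeatedly take the globally closest
#' (A, B) pair, remove both spots, until one channel is exhausted.
#' Distances are Euclidean in physical micrometres. Unmatched leftover
#' spots are reported with a message.
#'
#' @param spots_a,spots_b data.frames with x, y, z columns (um), e.g.
#'   from [detect_spots()].
#' @return data.frame: pair, ax..bz coordinates, distance (um).
#' @export
pair_spot_distances <- function(spots_a, spots_b) {
  if (nrow(spots_a) == 0L || nrow(spots_b) == 0L) {
    stop_("both spot lists must be non-empty")
  }
  A <- as.matrix(spots_a[, c("x", "y", "z")])
  B <- as.matrix(spots_b[, c("x", "y", "z")])
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j) {
    sqrt((A[i, 1L] - B[j, 1L])^2 + (A[i, 2L] - B[j, 2L])^2 +
         (A[i, 3L] - B[j, 3L])^2)
  })
  n_pairs <- min(nrow(A), nrow(B))
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    hit <- arrayInd(which.min(dmat), dim(dmat))
    i <- hit[1L]; j <- hit[2L]
    out[[p]] <- data.frame(pair = p,
                           ax = A[i, 1L], ay = A[i, 2L], az = A[i, 3L],
                           bx = B[j, 1L], by = B[j, 2L], bz = B[j, 3L],
                           distance = dmat[i, j])
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
  }
  leftover <- abs(nrow(A) - nrow(B))
  if (leftover > 0L) {
    message(sprintf("pair_spot_distances: %d unmatched spot(s) left over",
                    leftover))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Measure probe-pair distances across a set of stacks
#'
#' Per-nucleus convenience chain: detect spots on both probe channels and
#' pair them greedily; returns one row per paired spot couple.
#'
#' @param stacks list of [image_stack]s (e.g. from [gen_probe_stack()]).
#' @param channels length-2 channel names.
#' @param ... arguments passed to [detect_spots()].
#' @return data.frame: nucleus, pair, distance (um).
#' @export
measure_pair_distances <- function(stacks,
                                   channels = c("probe_a", "probe_b"), ...) {
  out <- lapply(seq_along(stacks), function(i) {
    sa <- detect_spots(stacks[[i]], channels[1L], ...)
    sb <- detect_spots(stacks[[i]], channels[2L], ...)
    if (nrow(sa) == 0L || nrow(sb) == 0L) {
      message(sprintf("nucleus %d: missing spots, skipped", i))
      return(NULL)
    }
    cbind(nucleus = i, pair_spot_distances(sa, sb))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
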