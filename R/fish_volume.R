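#' Threshold an image channel into a voxel mask
#'
#' Applies an intensity threshold to one channel of a stack to separate
#' real signal from background, the masking step underlying all
#' territory-volume measurements. Three methods are supported:
#' \describe{
#'   \item{otsu}{histogram-based threshold maximizing between-class
#'     variance (256 bins over the observed intensity range); the default,
#'     reproducible and parameter-free.}
#'   \item{fixed}{a user-supplied threshold `value`.}
#'   \item{fraction_of_max}{`fraction` times the channel maximum.}
#' }
#' The mask keeps voxels strictly above the threshold. When `within` is
#' given (typically the DNA/DAPI mask), the threshold is estimated from
#' intensities inside that mask only, i.e. per-nucleus thresholding.
#'
#' @param stack an [image_stack].
#' @param channel channel name.
#' @param method `"otsu"`, `"fixed"` or `"fraction_of_max"`.
#' @param value threshold for `method = "fixed"`.
#' @param fraction fraction of the maximum for `method = "fraction_of_max"`.
#' @param within optional `voxel_mask` restricting threshold estimation.
#' @return A `voxel_mask`: list with `mask` (logical array), `channel`,
#'   `threshold` (recorded for provenance) and `voxel_size`.
#' @export
threshold_mask <- function(stack, channel,
                           method = c("otsu", "fixed", "fraction_of_max"),
                           value = NULL, fraction = NULL, within = NULL) {
  method <- match.arg(method)
  img <- stack_channel(stack, channel)
  est <- img
  if (!is.null(within)) {
    stopifnot(inherits(within, "voxel_mask"))
    if (!identical(dim(within$mask), dim(img))) {
      stop_("'within' mask shape differs from the stack")
    }
    est <- img[within$mask]
  }
  thr <- switch(method,
    otsu = otsu_threshold(as.vector(est)),
    fixed = {
      if (is.null(value)) stop_("method 'fixed' needs a threshold value")
      value
    },
    fraction_of_max = {
      if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
        stop_("method 'fraction_of_max' needs fraction in (0, 1)")
      }
      fraction * max(est)
    })
  mask <- img > thr
  if (!sum(mask)) {
    warning(sprintf("threshold %g yields an empty mask on channel '%s'",
                    thr, channel), call. = FALSE)
  }
  structure(list(mask = mask, channel = channel, threshold = thr,
                 method = method, voxel_size = stack$voxel_size),
            class = "voxel_mask")
}

# Otsu's method on a 256-bin histogram: pick the bin edge maximizing
# between-class variance of the induced binary split.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rng[1L] - .Machine$double.eps)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  k <- which.max(between[-n_bins])
  edges[k + 1L]
}

#' Percent of nuclear volume occupied by a territory
#'
#' The core territory statistic: 100 times the voxel count of the
#' territory mask restricted to the nucleus mask, over the nucleus voxel
#' count. Territory voxels outside the nucleus are clipped, so a
#' territory can never exceed 100\% of its nucleus.
#'
#' @param territory,nucleus `voxel_mask` objects on the same grid.
#' @return Percent nuclear volume (0--100).
#' @export
percent_volume <- function(territory, nucleus) {
  stopifnot(inherits(territory, "voxel_mask"), inherits(nucleus, "voxel_mask"))
  if (!identical(dim(territory$mask), dim(nucleus$mask))) {
    stop_("territory and nucleus masks must share the same grid")
  }
  n_nuc <- sum(nucleus$mask)
  if (n_nuc == 0L) stop_("empty nucleus mask")
  100 * sum(territory$mask & nucleus$mask) / n_nuc
}

#' Measure territory occupancy across a set of nucleus stacks
#'
#' Convenience pipeline: per nucleus, threshold the DNA channel (nucleus
#' mask), threshold the paint channel within the DNA mask (territory
#' mask), and compute percent nuclear volume.
#'
#' @param stacks list of [image_stack]s (e.g. from [gen_nucleus_stack()]).
#' @param dna_channel,paint_channel channel names.
#' @param method threshold method passed to [threshold_mask()].
#' @param group optional group label (recycled) for downstream summaries.
#' @param ... further arguments to [threshold_mask()].
#' @return data.frame: nucleus, group, percent, thresholds used.
#' @export
measure_territory <- function(stacks, dna_channel = "dna",
                              paint_channel = "paint",
                              method = "otsu", group = NA_character_, ...) {
  group <- rep_len(group, length(stacks))
  out <- lapply(seq_along(stacks), function(i) {
    nuc <- threshold_mask(stacks[[i]], dna_channel, method = method, ...)
    terr <- threshold_mask(stacks[[i]], paint_channel, method = method,
                           within = nuc, ...)
    data.frame(nucleus = i, group = group[i],
               percent = percent_volume(terr, nuc),
               dna_threshold = nuc$threshold,
               paint_threshold = terr$threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize territory measurements by group
#'
#' Per-group mean, sample standard deviation and n of percent nuclear
#' volumes. With `group_by = c("embryo", ...)` and a `stage` column
#' present, the per-embryo means are returned ordered by cell stage,
#' giving the developmental time-course series.
#'
#' @param measurements data.frame with a `percent` column and the
#'   grouping columns.
#' @param group_by character vector of grouping column names.
#' @return data.frame: grouping columns, mean_percent, sd_percent, n
#'   (sd is 0 for single-measurement groups).
#' @export
summarize_volumes <- function(measurements, group_by = "group") {
  if (!("percent" %in% names(measurements))) {
    stop_("measurements need a 'percent' column")
  }
  missing_cols <- setdiff(group_by, names(measurements))
  if (length(missing_cols)) {
    stop_(sprintf("grouping column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  keys <- measurements[, group_by, drop = FALSE]
  split_f <- interaction(keys, drop = TRUE, lex.order = TRUE)
  parts <- split(seq_len(nrow(measurements)), split_f)
  out <- lapply(parts, function(idx) {
    row <- measurements[idx[1L], group_by, drop = FALSE]
    if ("stage" %in% names(measurements)) {
      row$stage <- measurements$stage[idx[1L]]
    }
    row$mean_percent <- mean(measurements$percent[idx])
    row$sd_percent <- sd0(measurements$percent[idx])
    row$n <- length(idx)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if ("stage" %in% names(out)) out <- out[order(out$stage), , drop = FALSE]
  out
}
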