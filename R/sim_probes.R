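#' Simulate two-probe FISH spot stacks
#'
#' Generates image stacks with two probe channels containing Gaussian
#' spots at a fixed physical separation, mimicking a pair of locus FISH
#' probes 1.2 Mb apart on the X. Each nucleus carries `spots_per_probe`
#' homologous pairs (2 for the tetraploid hypodermal nuclei analysed in
#' adult worms); pair centres are kept at least `min_pair_sep_um` apart so
#' spot-to-spot assignment is unambiguous. True spot coordinates (um,
#' voxel-centre convention) are recorded for every pair.
#'
#' Per-pair separations are jittered with sd `separation_sd` around the
#' planted value (truncated at 0.05 um), mimicking cell-to-cell variation
#' in locus distance; set it to 0 for exact separations.
#'
#' @param separation_um planted physical probe separation (um), >= 0.
#' @param n_nuclei number of nuclei.
#' @param spots_per_probe homologous copies per probe per nucleus (>= 1).
#' @param spot_sigma_um Gaussian spot sd (um, isotropic in physical space).
#' @param amplitude peak spot intensity above background.
#' @param background_level baseline intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param separation_sd per-pair jitter sd on the separation (um).
#' @param voxel_size um per voxel (x, y, z); default anisotropic in z.
#' @param grid_um physical field of view (um).
#' @param margin_um minimum spot distance from the grid boundary.
#' @param min_pair_sep_um minimum distance between pair centres.
#' @param seed RNG seed.
#' @return list with `stacks` (channels `probe_a`, `probe_b`) and `truth`
#'   (nucleus, pair, ax..bz in um, separation_true).
#' @export
gen_probe_stack <- function(separation_um,
                            n_nuclei = 20,
                            spots_per_probe = 2,
                            spot_sigma_um = 0.12,
                            amplitude = 100,
                            background_level = 5,
                            noise_sd = 3,
                            separation_sd = 0.1,
                            voxel_size = c(0.1, 0.1, 0.25),
                            grid_um = c(5, 5, 6),
                            margin_um = 0.4,
                            min_pair_sep_um = 2,
                            seed = 1) {
  if (separation_um < 0) stop_("separation_um must be >= 0")
  if (spots_per_probe < 1) stop_("spots_per_probe must be >= 1")
  if (n_nuclei < 1) stop_("n_nuclei must be >= 1")
  dims <- as.integer(round(grid_um / voxel_size))
  lo <- rep(margin_um + separation_um / 2, 3L)
  hi <- grid_um - lo
  if (any(hi <= lo)) {
    stop_("grid too small for the requested separation and margin")
  }
  centers <- voxel_centers(dims, voxel_size)

  render_spot <- function(arr, p, sigma) {
    # additive Gaussian blob evaluated on a +/- 4 sigma local window
    win <- lapply(1:3, function(a) {
      which(abs(centers[[a]] - p[a]) <= 4 * sigma)
    })
    if (any(vapply(win, length, 1L) == 0L)) return(arr)
    gx <- exp(-(centers[[1L]][win[[1L]]] - p[1L])^2 / (2 * sigma^2))
    gy <- exp(-(centers[[2L]][win[[2L]]] - p[2L])^2 / (2 * sigma^2))
    gz <- exp(-(centers[[3L]][win[[3L]]] - p[3L])^2 / (2 * sigma^2))
    blob <- amplitude * outer(outer(gx, gy), gz)
    arr[win[[1L]], win[[2L]], win[[3L]]] <-
      arr[win[[1L]], win[[2L]], win[[3L]]] + blob
    arr
  }

  with_seed(seed, {
    stacks <- vector("list", n_nuclei)
    truth <- list()
    redraws <- 0L
    for (i in seq_len(n_nuclei)) {
      pa <- array(background_level, dims)
      pb <- array(background_level, dims)
      pair_centers <- matrix(NA_real_, 0L, 3L)
      for (k in seq_len(spots_per_probe)) {
        for (try in seq_len(200L)) {
          ctr <- stats::runif(3L, lo, hi)
          sep_k <- max(separation_um + stats::rnorm(1L, 0, separation_sd),
                       if (separation_um > 0) 0.05 else 0)
          u <- as.vector(runit3(1L))
          a <- ctr + u * sep_k / 2
          b <- ctr - u * sep_k / 2
          in_bounds <- all(a > margin_um) && all(b > margin_um) &&
            all(a < grid_um - margin_um) && all(b < grid_um - margin_um)
          far_enough <- nrow(pair_centers) == 0L ||
            min(sqrt(rowSums((pair_centers -
                              matrix(ctr, nrow(pair_centers), 3L,
                                     byrow = TRUE))^2))) >= min_pair_sep_um
          if (in_bounds && far_enough) break
          redraws <- redraws + 1L
        }
        pair_centers <- rbind(pair_centers, ctr)
        pa <- render_spot(pa, a, spot_sigma_um)
        pb <- render_spot(pb, b, spot_sigma_um)
        truth[[length(truth) + 1L]] <- data.frame(
          nucleus = i, pair = k,
          ax = a[1L], ay = a[2L], az = a[3L],
          bx = b[1L], by = b[2L], bz = b[3L],
          separation_true = sep_k)
      }
      if (noise_sd > 0) {
        nv <- prod(dims)
        pa <- pa + stats::rnorm(nv, 0, noise_sd)
        pb <- pb + stats::rnorm(nv, 0, noise_sd)
        pa[pa < 0] <- 0
        pb[pb < 0] <- 0
      }
      stacks[[i]] <- image_stack(list(probe_a = pa, probe_b = pb), voxel_size)
    }
    if (redraws > 0L) {
      message(sprintf("gen_probe_stack: %d placement redraws (boundary/pair-separation)",
                      redraws))
    }
    list(stacks = stacks, truth = do.call(rbind, truth),
         params = list(separation_um = separation_um, n_nuclei = n_nuclei,
                       spots_per_probe = spots_per_probe,
                       spot_sigma_um = spot_sigma_um,
                       separation_sd = separation_sd,
                       voxel_size = voxel_size, seed = seed))
  })
}
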