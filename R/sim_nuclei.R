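#' Simulate nuclei with a painted chromosome territory
#'
#' Generates multi-channel 3D image stacks mimicking chromosome-paint
#' FISH: each nucleus is an ellipsoid of DNA counterstain signal, and a
#' connected sub-region of it (a "spherical cap" of the ellipsoid, cut by
#' a randomly oriented plane) carries the paint signal. The cap is chosen
#' so that its voxel count over the nucleus voxel count equals the
#' requested occupancy up to voxel discretization; the realized occupancy
#' of every nucleus is recorded in the truth table, so downstream
#' territory measurements can be checked by parameter recovery.
#'
#' Nucleus-to-nucleus biological variation is modelled by jittering the
#' target occupancy with a Gaussian of sd `occupancy_sd` (in occupancy
#' units), truncated to (0.005, 0.95).
#'
#' @param occupancy target territory fraction of nuclear volume (0--1).
#' @param n_nuclei number of nuclei (one stack per nucleus).
#' @param radius_vox ellipsoid semi-axes in voxels (x, y, z); each >= 4.
#' @param voxel_size micrometres per voxel (x, y, z).
#' @param signal_to_background ratio of in-object to background intensity.
#' @param background_level background intensity.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param occupancy_sd between-nucleus sd of the true occupancy.
#' @param seed RNG seed.
#' @return list with `stacks` (list of [image_stack] with channels `dna`
#'   and `paint`) and `truth` (data.frame: nucleus, occupancy_target,
#'   occupancy_true, realized occupancy and voxel counts).
#' @export
gen_nucleus_stack <- function(occupancy,
                              n_nuclei = 20,
                              radius_vox = c(16, 16, 12),
                              voxel_size = c(0.2, 0.2, 0.3),
                              signal_to_background = 10,
                              background_level = 10,
                              noise_sd = 8,
                              occupancy_sd = 0.012,
                              seed = 1) {
  if (!is.numeric(occupancy) || occupancy <= 0 || occupancy >= 1) {
    stop_("occupancy must lie strictly between 0 and 1")
  }
  if (any(radius_vox < 4)) stop_("ellipsoid radii must be >= 4 voxels")
  if (n_nuclei < 1) stop_("n_nuclei must be >= 1")
  if (occupancy_sd < 0 || noise_sd < 0) stop_("sds must be non-negative")

  dims <- as.integer(2 * ceiling(radius_vox) + 3L)
  ctr <- (dims + 1) / 2
  ax <- (seq_len(dims[1L]) - ctr[1L]) / radius_vox[1L]
  ay <- (seq_len(dims[2L]) - ctr[2L]) / radius_vox[2L]
  az <- (seq_len(dims[3L]) - ctr[3L]) / radius_vox[3L]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  nucleus <- r2 <= 1
  n_nuc_vox <- sum(nucleus)
  if (round(occupancy * n_nuc_vox) < 1) {
    stop_(sprintf(
      "occupancy %.4g unrealizable: territory would span <1 of %d nucleus voxels",
      occupancy, n_nuc_vox))
  }
  nuc_idx <- which(nucleus)
  nuc_coord <- arrayInd(nuc_idx, dims)
  signal <- background_level * signal_to_background

  with_seed(seed, {
    stacks <- vector("list", n_nuclei)
    truth <- data.frame(
      nucleus = seq_len(n_nuclei),
      occupancy_target = occupancy,
      occupancy_true = NA_real_,
      occupancy_realized = NA_real_,
      n_nucleus_vox = n_nuc_vox,
      n_territory_vox = NA_integer_)
    for (i in seq_len(n_nuclei)) {
      occ_i <- occupancy + stats::rnorm(1L, 0, occupancy_sd)
      occ_i <- min(max(occ_i, 0.005), 0.95)
      k <- max(1L, as.integer(round(occ_i * n_nuc_vox)))
      u <- runit3(1L)
      proj <- nuc_coord %*% t(u)
      terr_idx <- nuc_idx[order(proj, decreasing = TRUE)[seq_len(k)]]

      dna <- array(background_level, dims)
      dna[nuc_idx] <- signal
      paint <- array(background_level, dims)
      paint[terr_idx] <- signal
      if (noise_sd > 0) {
        nv <- prod(dims)
        dna <- dna + stats::rnorm(nv, 0, noise_sd)
        paint <- paint + stats::rnorm(nv, 0, noise_sd)
        dna[dna < 0] <- 0
        paint[paint < 0] <- 0
      }
      stacks[[i]] <- image_stack(list(dna = dna, paint = paint), voxel_size)
      attr(stacks[[i]], "territory_idx") <- terr_idx
      attr(stacks[[i]], "nucleus_idx") <- nuc_idx
      truth$occupancy_true[i] <- occ_i
      truth$occupancy_realized[i] <- k / n_nuc_vox
      truth$n_territory_vox[i] <- k
    }
    list(stacks = stacks, truth = truth,
         params = list(occupancy = occupancy, n_nuclei = n_nuclei,
                       radius_vox = radius_vox, voxel_size = voxel_size,
                       signal_to_background = signal_to_background,
                       background_level = background_level,
                       noise_sd = noise_sd, occupancy_sd = occupancy_sd,
                       seed = seed))
  })
}
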