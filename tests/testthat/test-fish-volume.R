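make_stack <- function(vals, voxel = c(1, 1, 1)) {
  image_stack(list(ch = array(vals, c(4, 4, 3))), voxel)
}

test_that("threshold methods behave on degenerate and bimodal inputs", {
  # uniform intensity 10, fixed threshold 5: everything is signal
  st <- make_stack(10)
  vm <- threshold_mask(st, "ch", method = "fixed", value = 5)
  expect_true(all(vm$mask))
  expect_equal(vm$threshold, 5)
  # threshold above everything: empty mask warns, does not error
  expect_warning(threshold_mask(st, "ch", method = "fixed", value = 50),
                 "empty mask")
  # fraction_of_max scales with the data
  st2 <- make_stack(c(rep(10, 40), rep(100, 8)))
  vm2 <- threshold_mask(st2, "ch", method = "fraction_of_max", fraction = 0.5)
  expect_equal(sum(vm2$mask), 8)
})

test_that("otsu lands between the modes of a bimodal histogram", {
  set.seed(42)
  vals <- c(rnorm(4000, 10, 5), rnorm(1000, 100, 5))
  st <- image_stack(list(ch = array(vals, c(50, 20, 5))), c(1, 1, 1))
  vm <- threshold_mask(st, "ch", method = "otsu")
  expect_gt(vm$threshold, 25)
  expect_lt(vm$threshold, 85)
  # agrees with a brute-force sweep maximizing between-class variance,
  # up to the histogram bin width
  # the exhaustive sweep lands between the modes as well; the two optima
  # need not coincide (the between-class criterion is nearly flat across
  # the empty gap), but both must separate the classes
  sweep_thr <- oracle_otsu_sweep(vals)
  expect_gt(sweep_thr, 25)
  expect_lt(sweep_thr, 85)
  truth <- rep(c(FALSE, TRUE), c(4000, 1000))
  expect_lt(mean(vm$mask != truth), 0.01)
  expect_lt(mean((vals > sweep_thr) != truth), 0.01)
})

test_that("percent_volume implements the clipped ratio", {
  nuc <- threshold_mask(make_stack(rep(c(10, 100), each = 24)),
                        "ch", method = "fixed", value = 50)
  expect_equal(percent_volume(nuc, nuc), 100)
  empty <- suppressWarnings(
    threshold_mask(make_stack(10), "ch", method = "fixed", value = 50))
  expect_equal(percent_volume(empty, nuc), 0)
  expect_error(percent_volume(nuc, empty), "empty nucleus")
  # territory voxels outside the nucleus are clipped, never > 100%
  all_mask <- threshold_mask(make_stack(10), "ch", method = "fixed", value = 5)
  expect_equal(percent_volume(all_mask, nuc), 100)
})

test_that("percent volumes of a partition of the nucleus sum to 100 exactly", {
  sim <- gen_nucleus_stack(0.2, n_nuclei = 1, noise_sd = 0,
                           occupancy_sd = 0, seed = 2)
  st <- sim$stacks[[1]]
  nuc <- threshold_mask(st, "dna", method = "fixed", value = 50)
  idx <- which(nuc$mask)
  thirds <- split(idx, cut(seq_along(idx), 3, labels = FALSE))
  parts <- lapply(thirds, function(ii) {
    m <- nuc
    m$mask[] <- FALSE
    m$mask[ii] <- TRUE
    m
  })
  expect_equal(sum(vapply(parts, percent_volume, 0, nucleus = nuc)), 100,
               tolerance = 1e-12)
})

test_that("fraction_of_max thresholding is intensity-scale invariant", {
  sim <- gen_nucleus_stack(0.12, n_nuclei = 1, seed = 6)
  st <- sim$stacks[[1]]
  st2 <- st
  st2$channels <- lapply(st$channels, function(a) a * 7.3)
  pv <- function(s) {
    nuc <- threshold_mask(s, "dna", method = "fraction_of_max", fraction = 0.5)
    terr <- threshold_mask(s, "paint", method = "fraction_of_max",
                           fraction = 0.5, within = nuc)
    percent_volume(terr, nuc)
  }
  expect_equal(pv(st), pv(st2))
})

test_that("group summaries compute mean, sample sd and n", {
  m <- data.frame(percent = c(8, 10, 12, 12), group = c("a", "a", "a", "b"))
  s <- summarize_volumes(m)
  expect_equal(s$mean_percent, c(10, 12))
  expect_equal(s$sd_percent, c(2, 0))
  expect_equal(s$n, c(3L, 1L))
  # embryo time course ordering by cell stage
  emb <- data.frame(percent = c(10, 11, 16, 15),
                    embryo = c("e2", "e2", "e1", "e1"),
                    stage = c(40, 40, 25, 25))
  s2 <- summarize_volumes(emb, group_by = "embryo")
  expect_equal(s2$embryo, c("e1", "e2"))
  expect_equal(s2$stage, c(25, 40))
  expect_error(summarize_volumes(m, group_by = "nope"), "not found")
})

test_that("noiseless pipeline recovers planted occupancy exactly", {
  sim <- gen_nucleus_stack(0.1574, n_nuclei = 4, noise_sd = 0,
                           occupancy_sd = 0, seed = 3)
  meas <- measure_territory(sim$stacks, method = "fixed", value = 50)
  expect_equal(meas$percent, 100 * sim$truth$occupancy_realized)
})

test_that("default-noise pipeline recovers the group mean closely", {
  sim <- gen_nucleus_stack(0.12, n_nuclei = 20, seed = 5)
  meas <- measure_territory(sim$stacks)
  expect_lt(abs(mean(meas$percent) - 12), 0.6)
  # per-nucleus recovery tracks the per-nucleus truth, not just the mean
  expect_lt(max(abs(meas$percent - 100 * sim$truth$occupancy_realized)), 0.5)
})

test_that("the reported decondensation contrast is detected in >=99% of draws", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(27, 15.74, 2.01)
    b <- rnorm(20, 9.87, 1.97)
    if (students_t(a, b)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})
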