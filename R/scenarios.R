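# End-to-end scenario runner: simulate -> analyze -> report. Packaged
# YAML configs under inst/scenarios encode the study conditions (group
# sizes and planted effect sizes) for each assay, so a full
# parameter-recovery run is one call.

scenario_types <- list(
  fish_volume = c("occupancy", "n_nuclei", "noise_sd", "occupancy_sd",
                  "radius_vox", "voxel_size", "signal_to_background",
                  "background_level"),
  probe_distance = c("separation_um", "n_nuclei", "spots_per_probe",
                     "separation_sd", "spot_sigma_um", "noise_sd",
                     "voxel_size", "grid_um"),
  chip_ratio = c("total_reads", "target_x_ratio"),
  chip_peaks = c("total_reads", "target_x_ratio", "islands_per_mb_x",
                 "islands_per_mb_autosome", "island_fold",
                 "island_width_bp", "bin_size", "z_min", "merge_gap",
                 "min_len"),
  expression_xa = c("x_ratio", "genes_per_mb", "n_replicates",
                    "library_size", "dispersion", "baseline_sdlog"),
  expression_contrast = c("x_log2_median", "x_log2_sd",
                          "autosome_log2_median", "autosome_log2_sd",
                          "direction", "genes_per_mb", "n_replicates",
                          "library_size", "dispersion", "x_ratio"),
  expression_quadrant = c("quadrant_probs", "magnitude", "null_sd",
                          "genes_per_mb", "n_replicates", "library_size",
                          "dispersion"),
  viability_chisq = c("rate_a", "n_a", "rate_b", "n_b")
)

#' List packaged scenario names
#' @return character vector of scenario config names shipped with the
#'   package.
#' @export
scenario_names <- function() {
  files <- list.files(system.file("scenarios", package = "xdosage"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load a scenario configuration
#'
#' Reads a packaged scenario by name (see [scenario_names()]) or any
#' YAML config from a path, and validates it against the scenario schema
#' (unknown keys are rejected; basic parameter ranges are checked before
#' any computation).
#'
#' @param name scenario name or path to a YAML file.
#' @return validated scenario config (list).
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("scenarios", paste0(name, ".yaml"), package = "xdosage")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_(sprintf("unknown scenario '%s' (packaged: %s)", name,
                  paste(scenario_names(), collapse = ", ")))
  }
  validate_scenario(yaml::read_yaml(path))
}

#' Validate a scenario configuration
#'
#' @param config scenario list (name, type, optional karyotype/seed/
#'   description, params).
#' @return the config, invisibly amended with defaults.
#' @export
validate_scenario <- function(config) {
  known_top <- c("name", "type", "karyotype", "seed", "params",
                 "description")
  extra <- setdiff(names(config), known_top)
  if (length(extra)) {
    stop_(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  if (is.null(config$name) || is.null(config$type)) {
    stop_("config needs 'name' and 'type'")
  }
  if (!config$type %in% names(scenario_types)) {
    stop_(sprintf("unknown scenario type '%s'", config$type))
  }
  bad <- setdiff(names(config$params), scenario_types[[config$type]])
  if (length(bad)) {
    stop_(sprintf("unknown parameter(s) for type %s: %s", config$type,
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(config$karyotype) && !config$karyotype %in% c("XX", "XO")) {
    stop_("karyotype must be 'XX' or 'XO'")
  }
  p <- config$params
  check_pos <- function(field, lo = 0, hi = Inf, open = TRUE) {
    v <- p[[field]]
    if (is.null(v)) return(invisible(NULL))
    ok <- all(is.finite(v)) &&
      if (open) all(v > lo & v < hi) else all(v >= lo & v <= hi)
    if (!ok) stop_(sprintf("parameter '%s' out of range", field))
  }
  check_pos("occupancy", 0, 1)
  check_pos("n_nuclei", 0)
  check_pos("separation_um", -Inf)
  if (!is.null(p$separation_um) && p$separation_um < 0) {
    stop_("separation_um must be >= 0")
  }
  check_pos("total_reads", 0)
  check_pos("x_ratio", 0)
  check_pos("target_x_ratio", 0)
  for (f in c("rate_a", "rate_b")) check_pos(f, 0, 1)
  if (!is.null(p$quadrant_probs) && sum(unlist(p$quadrant_probs)) > 1) {
    stop_("quadrant_probs must sum to <= 1")
  }
  config$seed <- config$seed %||% 1
  config
}

#' Run a packaged analysis scenario end to end
#'
#' Executes the configured generator plus the matching analysis chain
#' and returns a run report with provenance (scenario, parameters, seed,
#' package version) and the summary statistics of the corresponding
#' assay. Deterministic given config and seed. When `out_dir` is
#' given, per-stage tables are written as TSV and the report as JSON.
#'
#' @param config a scenario name, YAML path, or validated config list.
#' @param seed overrides the config seed when given.
#' @param out_dir optional output directory for intermediates.
#' @return A `run_report` list: name, type, seed, params, `summary`
#'   (named numbers), `tables` (data.frames).
#' @export
run_scenario <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- load_scenario(config)
  config <- validate_scenario(config)
  seed <- seed %||% config$seed
  p <- config$params
  kar <- celegans_karyotype(config$karyotype %||% "XX")

  result <- switch(config$type,
    fish_volume = {
      sim <- gen_nucleus_stack(
        occupancy = p$occupancy, n_nuclei = p$n_nuclei,
        noise_sd = p$noise_sd %||% 8,
        occupancy_sd = p$occupancy_sd %||% 0.012, seed = seed)
      meas <- measure_territory(sim$stacks, group = config$name)
      summ <- summarize_volumes(meas)
      list(summary = list(mean_percent = summ$mean_percent[1L],
                          sd_percent = summ$sd_percent[1L],
                          n = summ$n[1L],
                          planted_percent = 100 * p$occupancy),
           tables = list(measurements = meas, summary = summ,
                         truth = sim$truth),
           analog = "territory-volume group summary")
    },
    probe_distance = {
      sim <- gen_probe_stack(
        separation_um = p$separation_um, n_nuclei = p$n_nuclei,
        spots_per_probe = p$spots_per_probe %||% 2,
        separation_sd = p$separation_sd %||% 0.1, seed = seed)
      dist <- measure_pair_distances(sim$stacks)
      list(summary = list(median_um = stats::median(dist$distance),
                          iqr_um = stats::IQR(dist$distance),
                          n_nuclei = p$n_nuclei,
                          n_distances = nrow(dist),
                          planted_um = p$separation_um),
           tables = list(distances = dist, truth = sim$truth),
           analog = "probe-pair 3D distance summary")
    },
    chip_ratio = {
      dens <- 1
      if (!is.null(p$target_x_ratio)) {
        dens <- c(X = solve_x_density_factor(kar, p$target_x_ratio))
      }
      sim <- gen_chip_reads(kar, total_reads = p$total_reads,
                            density = dens, seed = seed)
      rat <- read_fraction_ratio(sim$chip, kar)
      list(summary = list(x_ratio = rat$ratio[rat$chrom == "X"],
                          expected_ratio = p$target_x_ratio %||% 1),
           tables = list(ratios = rat),
           analog = "X read-fraction ratio")
    },
    chip_peaks = {
      dens <- 1
      if (!is.null(p$target_x_ratio)) {
        dens <- c(X = solve_x_density_factor(kar, p$target_x_ratio))
      }
      ipm <- stats::setNames(rep(p$islands_per_mb_autosome %||% 0,
                                 nrow(kar)), kar$chrom)
      ipm["X"] <- p$islands_per_mb_x %||% 0
      ipm["MtDNA"] <- 0
      sim <- gen_chip_reads(
        kar, total_reads = p$total_reads, density = dens,
        islands_per_mb = ipm,
        island_width_bp = unlist(p$island_width_bp %||% c(400, 1200)),
        island_fold = p$island_fold %||% 8, seed = seed)
      bs <- p$bin_size %||% 50
      chip <- bin_coverage(sim$chip, kar, bs)
      input <- bin_coverage(sim$input, kar, bs)
      enr <- normalize_ploidy_aware(chip, input, kar)
      z <- zscore_standardize(enr, kar)
      peaks <- call_broad_peaks(z, z_min = p$z_min %||% 2.5,
                                merge_gap = p$merge_gap %||% 500,
                                min_len = p$min_len %||% 200)
      dens_out <- peak_density(peaks, kar)
      planted <- peak_density(sim$islands, kar)
      list(summary = list(x_peaks_per_mb = dens_out$x_density,
                          autosome_peaks_per_mb = dens_out$autosome_density,
                          planted_x_per_mb = planted$x_density,
                          planted_autosome_per_mb = planted$autosome_density,
                          n_peaks = nrow(peaks)),
           tables = list(density = dens_out$per_chromosome,
                         peaks = as.data.frame(peaks)),
           analog = "peak density per chromosome")
    },
    expression_xa = {
      ann <- gen_genome_annotation(kar,
                                   genes_per_mb = p$genes_per_mb %||% 200,
                                   seed = seed)
      sim <- gen_expression_counts(
        ann, conditions = list(control = list()),
        x_ratio = p$x_ratio %||% 1,
        baseline_sdlog = p$baseline_sdlog %||% 0.45,
        dispersion = p$dispersion %||% 0.05,
        n_replicates = p$n_replicates %||% 3,
        library_size = p$library_size %||% 3e7, seed = seed + 1)
      tab <- compute_rpkm(sim$counts$control, sim$genes,
                          library_sizes = sim$library_sizes)
      xa <- median_xa_ratio(tab)
      list(summary = list(xa_ratio = xa$ratio, planted = p$x_ratio %||% 1,
                          n_x = xa$n_x, n_autosome = xa$n_autosome),
           tables = list(per_chromosome = xa$per_chromosome),
           analog = "X:A expression ratio")
    },
    expression_contrast = {
      ann <- gen_genome_annotation(kar,
                                   genes_per_mb = p$genes_per_mb %||% 200,
                                   seed = seed)
      sim <- gen_expression_counts(
        ann,
        conditions = list(
          control = list(),
          treatment = list(
            x_log2 = list(median = p$x_log2_median,
                          sd = p$x_log2_sd %||% 0.25),
            autosome_log2 = list(median = p$autosome_log2_median %||% 0,
                                 sd = p$autosome_log2_sd %||% 0.1))),
        x_ratio = p$x_ratio %||% 1,
        dispersion = p$dispersion %||% 0.05,
        n_replicates = p$n_replicates %||% 3,
        library_size = p$library_size %||% 3e7, seed = seed + 1)
      ta <- compute_rpkm(sim$counts$treatment, sim$genes,
                         library_sizes = sim$library_sizes)
      tb <- compute_rpkm(sim$counts$control, sim$genes,
                         library_sizes = sim$library_sizes)
      ctr <- contrast_log2(ta, tb, min_rpkm = 1)
      on_x <- ctr$chrom == "X"
      shift <- chromosome_shift_test(ctr,
                                     direction = p$direction %||% "greater")
      list(summary = list(
             x_median = stats::median(ctr$log2_ratio[on_x]),
             autosome_median = stats::median(ctr$log2_ratio[!on_x]),
             planted_x = p$x_log2_median,
             planted_autosome = p$autosome_log2_median %||% 0,
             p_x_vs_autosomes =
               shift$p_value[shift$comparison == "X_vs_autosomes"]),
           tables = list(shift_tests = shift),
           analog = "chromosome log2 expression-ratio shift",
           contrast = ctr)
    },
    expression_quadrant = {
      ann <- gen_genome_annotation(kar,
                                   genes_per_mb = p$genes_per_mb %||% 200,
                                   seed = seed)
      qp <- unlist(p$quadrant_probs)
      # each contrast has its own control, as in the underlying design
      # (two independent mutant-vs-control comparisons); sharing one
      # control would correlate the two axes through its sampling noise
      sim <- gen_expression_counts(
        ann,
        conditions = list(controlA = list(), condA = list(),
                          controlB = list(), condB = list()),
        joint_x = list(conditions = c("condA", "condB"),
                       quadrant_probs = qp,
                       magnitude = unlist(p$magnitude %||% c(0.4, 1.2)),
                       null_sd = p$null_sd %||% 0.02),
        dispersion = p$dispersion %||% 0.005,
        n_replicates = p$n_replicates %||% 3,
        library_size = p$library_size %||% 6e7, seed = seed + 1)
      tabs <- lapply(sim$counts, compute_rpkm, genes = sim$genes,
                     library_sizes = sim$library_sizes)
      ca <- contrast_log2(tabs$condA, tabs$controlA, min_rpkm = 1)
      cb <- contrast_log2(tabs$condB, tabs$controlB, min_rpkm = 1)
      qt <- quadrant_classify(ca, cb)
      top <- top_percent_sets(ca, cb)
      conc <- qt$percent[qt$class == "X" & qt$quadrant == "up_down"]
      list(summary = list(
             x_concordant_percent = conc,
             planted_percent = 100 * unname(qp["up_down"])),
           tables = list(quadrants = as.data.frame(qt),
                         top_sets = top$summary),
           analog = "two-contrast quadrant concordance")
    },
    viability_chisq = {
      surv <- c(round(p$rate_a * p$n_a), round(p$rate_b * p$n_b))
      tab <- cbind(survived = surv, died = c(p$n_a, p$n_b) - surv)
      res <- chisq_proportions(tab)
      list(summary = list(statistic = res$statistic, p_value = res$p_value,
                          proportion_a = res$proportions[[1L]],
                          proportion_b = res$proportions[[2L]]),
           tables = list(counts = as.data.frame(tab)),
           analog = "survival proportion comparison")
    })

  report <- structure(
    c(list(name = config$name, type = config$type, seed = seed,
           karyotype = config$karyotype %||% "XX", params = p,
           package_version = as.character(utils::packageVersion("xdosage"))),
      result),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report '%s' (%s, seed %s) -- %s\n", x$name, x$type,
              x$seed, x$analog))
  for (nm in names(x$summary)) {
    cat(sprintf("  %-24s %s\n", nm,
                format(x$summary[[nm]], digits = 6)))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    utils::write.table(report$tables[[nm]],
                       file.path(out_dir, paste0(report$name, "_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- report[c("name", "type", "seed", "karyotype", "params",
                   "package_version", "summary", "analog")]
  jsonlite::write_json(json, file.path(out_dir, paste0(report$name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
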