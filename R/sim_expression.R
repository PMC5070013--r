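#' Simulate negative-binomial expression count tables
#'
#' Generates gene x replicate count matrices for one or more conditions
#' over the genes of a synthetic annotation. Per-gene baseline expression
#' levels are lognormal; X-linked baselines are multiplied by `x_ratio`
#' so the population median X:A RPKM ratio equals the planted value.
#' Condition effects are per-gene log2 fold changes drawn from
#' chromosome-class-specific Gaussians (median/sd), e.g. a strong
#' X-specific derepression (median +0.447) for a DCC mutant or a mild
#' X-specific repression (median -0.021) for a HAT knockdown. Counts are
#' negative binomial with var = mu + dispersion * mu^2.
#'
#' For joint two-condition analyses (quadrant concordance), `joint_x`
#' assigns X genes to response categories across two named conditions:
#' each category is a sign pattern for (condition A, condition B) effects
#' with magnitudes uniform in `magnitude`; unassigned genes get
#' near-null effects (sd `null_sd`). This plants a known fraction of
#' X genes in each quadrant of the contrast-vs-contrast plane.
#'
#' @param annotation a `genome_annotation` from [gen_genome_annotation()].
#' @param conditions named list; each element is either an empty list
#'   (no effects, e.g. the control) or a list with optional elements
#'   `x_log2` and `autosome_log2`, each `list(median=, sd=)`.
#' @param x_ratio planted median X:A baseline ratio (1 = no skew).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline parameters
#'   (natural log scale) of per-gene expression (RPKM-equivalent units).
#' @param dispersion NB dispersion alpha (0 gives Poisson counts).
#' @param n_replicates replicates per condition.
#' @param library_size sequencing depth per replicate (scalar or vector).
#' @param joint_x optional list(conditions = c(nameA, nameB),
#'   quadrant_probs = c(up_up=, up_down=, down_up=, down_down=),
#'   magnitude = c(lo, hi), null_sd = 0.02).
#' @param seed RNG seed.
#' @return list with `counts` (named list of gene x replicate integer
#'   matrices), `genes` (gene_id, chrom, exonic_bp), `library_sizes`,
#'   `truth` (per-gene baseline and per-condition log2 effects) and
#'   `params`.
#' @export
gen_expression_counts <- function(annotation,
                                  conditions = list(control = list()),
                                  x_ratio = 1,
                                  baseline_meanlog = log(50),
                                  baseline_sdlog = 0.45,
                                  dispersion = 0.05,
                                  n_replicates = 3,
                                  library_size = 3e7,
                                  joint_x = NULL,
                                  seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (dispersion < 0) stop_("dispersion must be >= 0")
  if (n_replicates < 1) stop_("n_replicates must be >= 1")
  if (x_ratio <= 0) stop_("x_ratio must be > 0")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop_("conditions must be a named list")
  }
  genes <- annotation$genes[, c("gene_id", "chrom", "exonic_bp")]
  x_chrom <- annotation$karyotype$chrom[annotation$karyotype$is_x]
  on_x <- genes$chrom == x_chrom
  ng <- nrow(genes)
  libs <- rep_len(as.numeric(library_size), n_replicates)
  if (any(libs <= 0)) stop_("library sizes must be > 0")

  with_seed(seed, {
    baseline <- exp(stats::rnorm(ng, baseline_meanlog, baseline_sdlog))
    baseline[on_x] <- baseline[on_x] * x_ratio

    effects <- matrix(0, ng, length(conditions),
                      dimnames = list(genes$gene_id, names(conditions)))
    for (cn in names(conditions)) {
      spec <- conditions[[cn]]
      if (length(spec) == 0L) next
      if (!is.null(spec$x_log2)) {
        effects[on_x, cn] <- stats::rnorm(sum(on_x), spec$x_log2$median,
                                          spec$x_log2$sd %||% 0)
      }
      if (!is.null(spec$autosome_log2)) {
        effects[!on_x, cn] <- stats::rnorm(sum(!on_x),
                                           spec$autosome_log2$median,
                                           spec$autosome_log2$sd %||% 0)
      }
    }
    quadrant_truth <- NULL
    if (!is.null(joint_x)) {
      jc <- joint_x$conditions
      if (length(jc) != 2L || !all(jc %in% names(conditions))) {
        stop_("joint_x$conditions must name two of the conditions")
      }
      qp <- joint_x$quadrant_probs
      needed <- c("up_up", "up_down", "down_up", "down_down")
      if (!all(needed %in% names(qp)) || sum(qp) > 1) {
        stop_("joint_x$quadrant_probs needs the four quadrant entries, summing to <= 1")
      }
      mag <- joint_x$magnitude %||% c(0.4, 1.2)
      null_sd <- joint_x$null_sd %||% 0.02
      nx <- sum(on_x)
      cat_lev <- c(needed, "null")
      category <- sample(cat_lev, nx, replace = TRUE,
                         prob = c(qp[needed], 1 - sum(qp[needed])))
      sgn <- list(up_up = c(1, 1), up_down = c(1, -1),
                  down_up = c(-1, 1), down_down = c(-1, -1))
      ea <- stats::rnorm(nx, 0, null_sd)
      eb <- stats::rnorm(nx, 0, null_sd)
      for (q in needed) {
        idx <- which(category == q)
        if (length(idx) == 0L) next
        ea[idx] <- sgn[[q]][1L] * stats::runif(length(idx), mag[1L], mag[2L])
        eb[idx] <- sgn[[q]][2L] * stats::runif(length(idx), mag[1L], mag[2L])
      }
      effects[on_x, jc[1L]] <- ea
      effects[on_x, jc[2L]] <- eb
      quadrant_truth <- data.frame(gene_id = genes$gene_id[on_x],
                                   category = category,
                                   stringsAsFactors = FALSE)
    }

    counts <- lapply(names(conditions), function(cn) {
      mu_g <- baseline * 2^effects[, cn] * genes$exonic_bp / 1e3
      m <- matrix(0L, ng, n_replicates,
                  dimnames = list(genes$gene_id,
                                  paste0(cn, "_rep", seq_len(n_replicates))))
      for (r in seq_len(n_replicates)) {
        mu <- mu_g * libs[r] / 1e6
        m[, r] <- if (dispersion > 0) {
          stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
        } else {
          stats::rpois(ng, mu)
        }
      }
      m
    })
    names(counts) <- names(conditions)

    truth <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        baseline = baseline, stringsAsFactors = FALSE)
    for (cn in names(conditions)) truth[[paste0("log2_", cn)]] <- effects[, cn]

    list(counts = counts, genes = genes, library_sizes = libs,
         truth = truth, quadrant_truth = quadrant_truth,
         params = list(x_ratio = x_ratio,
                       baseline_meanlog = baseline_meanlog,
                       baseline_sdlog = baseline_sdlog,
                       dispersion = dispersion,
                       n_replicates = n_replicates, seed = seed))
  })
}
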