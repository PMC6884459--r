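#' Configuration for the staged-embryo expression simulator
#'
#' Bundles every knob of the synthetic data generator.  Defaults describe a
#' study-sized but tractable experiment: 2000 genes over twelve 2-hour
#' embryonic bins, three replicates per condition, about a fifth of the
#' annotation never expressed in embryos, moderate biological noise and a
#' negative-binomial count layer.
#'
#' @param n_genes number of annotated genes (> 0).
#' @param n_bins number of reference time bins (default 12).
#' @param bin_width bin width in hours (default 2; bins tile `[0, n_bins *
#'   bin_width)`).
#' @param n_replicates replicates per condition (> 0).
#' @param frac_silent fraction of genes silent across the whole reference.
#' @param frac_direct_up,frac_direct_down fractions of genes given a true
#'   direct expression change (up / down) in the mutant, independent of any
#'   delay. The three fractions must sum to at most 1.
#' @param direct_effect_log2fc magnitude (log2) of the direct effect (> 0).
#' @param delay_hours rigid developmental delay of the mutant in hours
#'   (>= 0); the mutant is sampled from the reference window shifted
#'   earlier by this amount.
#' @param biological_cv coefficient of variation of the mean-preserving
#'   log-normal biological noise on expected expression (>= 0).
#' @param nb_dispersion negative-binomial dispersion of the count layer
#'   (> 0; variance `mu + dispersion * mu^2`).
#' @param library_size sequenced fragments per replicate (> 0).
#' @param unit output unit of the sample matrices, `"FPKM"` or `"count"`
#'   (FPKM assumes a uniform 1 kb gene length, so FPKM = count * 1e6 /
#'   library_size).
#' @param seed integer seed driving all stochastic draws.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L, n_bins = 12L, bin_width = 2,
                              n_replicates = 3L, frac_silent = 0.19,
                              frac_direct_up = 0, frac_direct_down = 0,
                              direct_effect_log2fc = 2, delay_hours = 0,
                              biological_cv = 0.1, nb_dispersion = 0.01,
                              library_size = 2e7, unit = c("FPKM", "count"),
                              seed = 1L) {
  unit <- match.arg(unit)
  cfg <- list(n_genes = as.integer(n_genes), n_bins = as.integer(n_bins),
              bin_width = bin_width, n_replicates = as.integer(n_replicates),
              frac_silent = frac_silent, frac_direct_up = frac_direct_up,
              frac_direct_down = frac_direct_down,
              direct_effect_log2fc = direct_effect_log2fc,
              delay_hours = delay_hours, biological_cv = biological_cv,
              nb_dispersion = nb_dispersion, library_size = library_size,
              unit = unit, seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_bins < 1L || cfg$n_replicates < 1L ||
      cfg$bin_width <= 0)
    stop_devdelay("n_genes, n_bins, n_replicates and bin_width must be positive",
                  class = "devdelay_value_error")
  fr <- c(cfg$frac_silent, cfg$frac_direct_up, cfg$frac_direct_down)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop_devdelay("frac_silent + frac_direct_up + frac_direct_down must lie in [0, 1]",
                  class = "devdelay_value_error")
  if (cfg$delay_hours < 0 || cfg$biological_cv < 0 || cfg$nb_dispersion <= 0 ||
      cfg$library_size <= 0 || cfg$direct_effect_log2fc <= 0)
    stop_devdelay("invalid noise/effect parameter in simulation_config",
                  class = "devdelay_value_error")
  class(cfg) <- "simulation_config"
  cfg
}

# noiseless log-scale trajectory value of one gene at times t (hours)
trajectory_value <- function(shape, amplitude, tau, peak, sigma, t) {
  base <- switch(shape,
    silent = rep(0, length(t)),
    flat = rep(1, length(t)),
    early_declining = exp(-t / tau),
    late_rising = exp((t - 24) / tau),
    peaked = exp(-(t - peak)^2 / (2 * sigma^2)),
    stop_devdelay("unknown shape class '%s'", shape)
  )
  amplitude * base
}

#' Expected (noiseless) expression over a developmental window
#'
#' Averages each gene's noiseless trajectory over the half-open hour
#' interval `[window[1], window[2])` by fine-grid integration.  This is the
#' expected value around which the sampler adds biological and counting
#' noise; it is exposed so that downstream behaviour can be verified
#' against the trajectory formulas directly.
#'
#' @param truth a `synthetic_truth` object from [generate_reference()].
#' @param window numeric length-2 vector of hours, `start < end`.
#' @return named numeric vector, one expected value per gene.
#' @export
expected_window_expression <- function(truth, window) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(window) != 2L || window[2] <= window[1])
    stop_devdelay("window must be an increasing hour interval",
                  class = "devdelay_value_error")
  tg <- seq(window[1], window[2], by = 0.05)
  tg <- tg[tg < window[2] - 1e-12]  # half-open
  pg <- truth$genes
  out <- vapply(seq_len(nrow(pg)), function(i)
    mean(trajectory_value(pg$shape[i], pg$amplitude[i], pg$tau[i],
                          pg$peak[i], pg$sigma[i], tg)), 1)
  names(out) <- pg$gene_id
  out
}

#' Generate a developmental reference time-course with known truth
#'
#' Builds a wild-type embryonic reference: each non-silent gene receives a
#' smooth noiseless trajectory from one of three shape classes —
#' early-declining (exponential decay), late-rising (saturating ramp
#' towards the end of embryogenesis) or peaked (log-scale Gaussian bump
#' with random peak time) — scaled by a log-normal amplitude. Silent genes
#' are all-zero rows.  Genes destined for a direct effect get a flat
#' (developmentally unmodulated) trajectory, so their mutant change carries
#' no early/late signature and is separable from a delay.  Bin values are
#' trajectory means over each bin.  Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `reference` (a [time_course()]) and `truth`
#'   (class `synthetic_truth`: per-gene shape parameters, the silent /
#'   direct-up / direct-down gene sets — pairwise disjoint — and the
#'   injected `delay_hours`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("gene%05d", seq_len(n))

  n_sil <- round(config$frac_silent * n)
  n_up <- round(config$frac_direct_up * n)
  n_dn <- round(config$frac_direct_down * n)
  perm <- sample.int(n)
  silent <- ids[perm[seq_len(n_sil)]]
  direct_up <- ids[perm[n_sil + seq_len(n_up)]]
  direct_down <- ids[perm[n_sil + n_up + seq_len(n_dn)]]

  shape <- rep("silent", n)
  live <- !(ids %in% silent)
  shape[live] <- sample(c("early_declining", "late_rising", "peaked"),
                        sum(live), replace = TRUE)
  # direct targets ride developmentally flat trajectories, so their
  # expression changes carry no early/late signature and the window rule
  # can separate them from delay effects
  shape[ids %in% c(direct_up, direct_down)] <- "flat"
  pg <- data.frame(
    gene_id = ids, shape = shape,
    amplitude = ifelse(live, stats::rlnorm(n, meanlog = log(30), sdlog = 1), 0),
    tau = stats::runif(n, 3, 8),
    peak = stats::runif(n, 2, 22),
    sigma = stats::runif(n, 3, 6),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(genes = pg, silent_genes = silent, direct_up_genes = direct_up,
         direct_down_genes = direct_down, delay_hours = config$delay_hours,
         config = config),
    class = "synthetic_truth"
  )

  starts <- (seq_len(config$n_bins) - 1L) * config$bin_width
  ends <- starts + config$bin_width
  vals <- vapply(seq_len(config$n_bins), function(b)
    expected_window_expression(truth, c(starts[b], ends[b])),
    numeric(n))
  list(reference = time_course(vals, gene_ids = ids,
                               bin_starts = starts, bin_ends = ends),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d genes (%d silent, %d direct-up, %d direct-down), delay %.1f h\n",
    nrow(x$genes), length(x$silent_genes), length(x$direct_up_genes),
    length(x$direct_down_genes), x$delay_hours))
  invisible(x)
}

#' Draw paired control and delayed-mutant embryo samples
#'
#' Control replicates are sampled around each gene's expected expression
#' over `window` (defaults to 6-12 h embryos); mutant replicates use the
#' window shifted *earlier* by `config$delay_hours` (a rigid developmental
#' delay), after which direct-effect genes are multiplied by
#' `2^(+/- direct_effect_log2fc)`.  Expected values are perturbed by
#' mean-preserving log-normal biological noise (CV = `biological_cv`) and
#' realized as negative-binomial counts at the configured dispersion and
#' library size; FPKM output rescales counts assuming a uniform 1 kb gene
#' length.  Deterministic given `config$seed`.
#'
#' @param reference the [time_course()] from [generate_reference()] (used
#'   for coverage checks and gene order).
#' @param truth the matching `synthetic_truth`.
#' @param config the [simulation_config()].
#' @param window sampling window in hours (length 2, must lie within the
#'   reference coverage).
#' @return A list with `control` and `mutant` [expression_matrix()] objects
#'   and the `truth` passed through.
#' @export
generate_embryo_samples <- function(reference, truth, config,
                                    window = c(6, 12)) {
  stopifnot(inherits(reference, "time_course"),
            inherits(truth, "synthetic_truth"),
            inherits(config, "simulation_config"))
  lo <- reference$bins$start[1L]
  hi <- reference$bins$end[nrow(reference$bins)]
  if (length(window) != 2L || window[2] <= window[1] ||
      window[1] < lo - 1e-9 || window[2] > hi + 1e-9)
    stop_devdelay("window must be an increasing interval covered by the reference bins",
                  class = "devdelay_value_error")
  if (window[1] - config$delay_hours < lo - 1e-9)
    stop_devdelay("delay of %.1f h: window would precede time %.0f",
                  config$delay_hours, lo, class = "devdelay_value_error")

  e_ctl <- expected_window_expression(truth, window)
  e_mut <- expected_window_expression(truth, window - config$delay_hours)
  e_mut[truth$genes$gene_id %in% truth$direct_up_genes] <-
    e_mut[truth$genes$gene_id %in% truth$direct_up_genes] *
    2^config$direct_effect_log2fc
  e_mut[truth$genes$gene_id %in% truth$direct_down_genes] <-
    e_mut[truth$genes$gene_id %in% truth$direct_down_genes] *
    2^(-config$direct_effect_log2fc)

  set.seed(config$seed + 1L)
  draw <- function(expected, label) {
    n <- length(expected); reps <- config$n_replicates
    mu <- matrix(rep(expected, reps), n, reps)
    if (config$biological_cv > 0) {
      s2 <- log(1 + config$biological_cv^2)
      mu <- mu * matrix(stats::rlnorm(n * reps, -s2 / 2, sqrt(s2)), n, reps)
    }
    counts <- matrix(stats::rnbinom(n * reps,
                                    mu = mu * config$library_size / 1e6,
                                    size = 1 / config$nb_dispersion), n, reps)
    vals <- if (config$unit == "FPKM")
      counts * 1e6 / config$library_size else counts
    expression_matrix(vals, gene_ids = names(expected), unit = config$unit,
                      condition_label = label)
  }
  control <- draw(e_ctl, "control")
  mutant <- draw(e_mut, "mutant")
  list(control = control, mutant = mutant, truth = truth)
}

#' One-call synthetic embryo experiment
#'
#' Runs [generate_reference()] then [generate_embryo_samples()] under one
#' seed.
#'
#' @inheritParams generate_embryo_samples
#' @return list with `reference`, `truth`, `control`, `mutant`.
#' @examples
#' sim <- simulate_embryo_experiment(simulation_config(n_genes = 100, seed = 7))
#' sim$reference
#' @export
simulate_embryo_experiment <- function(config = simulation_config(),
                                       window = c(6, 12)) {
  ref <- generate_reference(config)
  smp <- generate_embryo_samples(ref$reference, ref$truth, config, window)
  list(reference = ref$reference, truth = ref$truth,
       control = smp$control, mutant = smp$mutant)
}

#' Write the generator's ground truth as a TSV
#'
#' One row per gene: shape class, trajectory parameters, and membership in
#' the silent / direct-effect sets; the injected delay is carried in a
#' `delay_hours` column (constant).
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pg <- truth$genes
  pg$is_silent <- pg$gene_id %in% truth$silent_genes
  pg$is_direct_up <- pg$gene_id %in% truth$direct_up_genes
  pg$is_direct_down <- pg$gene_id %in% truth$direct_down_genes
  pg$delay_hours <- truth$delay_hours
  utils::write.table(pg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
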