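#' Tally dysregulation classes from counts or a DE table
#'
#' `class_tally()` computes the derived percentages from raw counts;
#' `tally_expression_classes()` first counts the statuses and directions in
#' a DE result table.  Percentages are rounded half-up to one decimal, the
#' convention used when reporting fractions of genes.
#'
#' @param n_annotated annotated transcriptional units in the genome
#'   (>= `n_detected`).
#' @param n_detected genes detected on the RNA level.
#' @param n_tested genes that could be statistically tested.
#' @param n_up,n_down significantly up- / down-regulated genes; their sum
#'   is the number of significant genes.
#' @return A list of class `class_tally` with the six counts,
#'   `n_significant`, and `pct_significant_of_tested`,
#'   `pct_significant_of_annotated`, `pct_up_of_significant`,
#'   `pct_down_of_significant` (one decimal). `empty` flags a tally with no
#'   significant genes, in which case all four percentages are 0.
#' @examples
#' class_tally(n_annotated = 17661, n_detected = 13518, n_tested = 8471,
#'             n_up = 1397, n_down = 740)
#' @export
class_tally <- function(n_annotated, n_detected, n_tested, n_up, n_down) {
  counts <- c(n_annotated, n_detected, n_tested, n_up, n_down)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_devdelay("all counts must be non-negative integers",
                  class = "devdelay_value_error")
  n_significant <- n_up + n_down
  if (n_significant > n_tested || n_tested > n_detected ||
      n_detected > n_annotated)
    stop_devdelay("counts must nest: significant <= tested <= detected <= annotated",
                  class = "devdelay_value_error")
  empty <- n_significant == 0
  pct <- function(num, den) if (den == 0) 0 else round_half_up(100 * num / den, 1)
  structure(
    list(n_annotated = n_annotated, n_detected = n_detected,
         n_tested = n_tested, n_significant = n_significant,
         n_up = n_up, n_down = n_down,
         pct_significant_of_tested = if (empty) 0 else pct(n_significant, n_tested),
         pct_significant_of_annotated = if (empty) 0 else pct(n_significant, n_annotated),
         pct_up_of_significant = if (empty) 0 else pct(n_up, n_significant),
         pct_down_of_significant = if (empty) 0 else pct(n_down, n_significant),
         empty = empty),
    class = "class_tally"
  )
}

#' @rdname class_tally
#' @param de a `de_result` data frame (see [differential_expression()]).
#' @export
tally_expression_classes <- function(de, n_annotated) {
  stopifnot(inherits(de, "data.frame"))
  if (nrow(de) > n_annotated)
    stop_devdelay("DE table has %d records but n_annotated is only %d",
                  nrow(de), n_annotated, class = "devdelay_value_error")
  class_tally(
    n_annotated = n_annotated,
    n_detected = sum(de$status != "not_detected"),
    n_tested = sum(de$status == "tested"),
    n_up = sum(de$direction == "up"),
    n_down = sum(de$direction == "down")
  )
}

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("annotated %d | detected %d | tested %d | significant %d (up %d, down %d)\n",
              x$n_annotated, x$n_detected, x$n_tested, x$n_significant,
              x$n_up, x$n_down))
  cat(sprintf("significant: %.1f%% of tested, %.1f%% of annotated; up %.1f%% / down %.1f%% of significant\n",
              x$pct_significant_of_tested, x$pct_significant_of_annotated,
              x$pct_up_of_significant, x$pct_down_of_significant))
  invisible(x)
}

#' Check for derepression of reference-silent genes
#'
#' A gene silent across the entire wild-type reference (zero in every bin)
#' should never appear up-regulated in the mutant unless it has genuinely
#' been derepressed.  This intersects the up-regulated set with the
#' reference silent set; genes without a reference row cannot be assessed
#' and are reported separately.
#'
#' @param de a `de_result` data frame.
#' @param reference a [time_course()].
#' @return list with `n_silent_upregulated`, `offending_gene_ids`, and
#'   `no_reference_gene_ids` (up-regulated genes absent from the
#'   reference).
#' @export
derepression_check <- function(de, reference) {
  stopifnot(inherits(de, "data.frame"), inherits(reference, "time_course"))
  up <- de$gene_id[de$direction == "up"]
  no_ref <- setdiff(up, reference$gene_ids)
  offending <- intersect(setdiff(up, no_ref), reference$silent_set)
  list(n_silent_upregulated = length(offending),
       offending_gene_ids = offending,
       no_reference_gene_ids = no_ref)
}

#' Count significant genes with very low control expression
#'
#' Flags significant genes whose control-condition mean lies below an
#' expression floor (default FPKM < 3): apparent dysregulation of such
#' genes rests on little signal.
#'
#' @param de a `de_result` data frame.
#' @param fpkm_threshold expression floor (>= 0, default 3).
#' @return list with `count`, `n_significant` and `pct_of_significant`
#'   (rounded half-up to two decimals).
#' @export
low_expression_dysregulated <- function(de, fpkm_threshold = 3) {
  stopifnot(inherits(de, "data.frame"))
  if (fpkm_threshold < 0)
    stop_devdelay("fpkm_threshold must be >= 0", class = "devdelay_value_error")
  sig <- de$direction %in% c("up", "down")
  count <- sum(sig & de$mean_control < fpkm_threshold)
  list(count = count, n_significant = sum(sig),
       pct_of_significant = if (sum(sig) == 0) 0
       else round_half_up(100 * count / sum(sig), 2))
}

#' Median developmental profile of a gene set
#'
#' Per-bin median reference expression across the member genes, plus the
#' bins of maximal and minimal median — the summary used to show that an
#' up-regulated set behaves like an early-embryo program (or a
#' down-regulated one like a late program).
#'
#' @param gene_set non-empty character vector of gene ids, all present in
#'   the reference.
#' @param reference a [time_course()].
#' @return A list of class `profile_summary`: `bins`, `median_expression`
#'   (one per bin), `n_genes`, `max_bin`, `min_bin` (bin labels).
#' @export
profile_summary <- function(gene_set, reference) {
  stopifnot(inherits(reference, "time_course"))
  gene_set <- as.character(gene_set)
  if (length(gene_set) == 0L)
    stop_devdelay("gene_set must be non-empty", class = "devdelay_value_error")
  missing <- setdiff(gene_set, reference$gene_ids)
  if (length(missing))
    stop_devdelay("gene '%s' is absent from the reference", missing[1L],
                  class = "devdelay_value_error")
  med <- apply(reference$values[gene_set, , drop = FALSE], 2, stats::median)
  structure(
    list(bins = reference$bins, median_expression = unname(med),
         n_genes = length(gene_set),
         max_bin = reference$bins$label[which.max(med)],
         min_bin = reference$bins$label[which.min(med)]),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf("profile_summary over %d genes; highest median in %s h, lowest in %s h\n",
              x$n_genes, x$max_bin, x$min_bin))
  print(stats::setNames(round(x$median_expression, 3), x$bins$label))
  invisible(x)
}

#' @export
plot.profile_summary <- function(x, ylab = "median expression",
                                 xlab = "embryo age (h)", type = "b", ...) {
  mid <- (x$bins$start + x$bins$end) / 2
  plot(mid, x$median_expression, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

window_bin_index <- function(reference, window) {
  b <- reference$bins
  if (length(window) != 2L || window[2] <= window[1])
    stop_devdelay("window must be an increasing hour interval",
                  class = "devdelay_value_error")
  if (!any(abs(b$start - window[1]) < 1e-9) ||
      !any(abs(b$end - window[2]) < 1e-9))
    stop_devdelay("window [%s, %s) is not aligned to reference bin boundaries",
                  format(window[1]), format(window[2]),
                  class = "devdelay_value_error")
  which(b$start >= window[1] - 1e-9 & b$end <= window[2] + 1e-9)
}

#' Classify dysregulated genes as delay-explainable or not
#'
#' Applies the early/late window rule: an up-regulated gene is explainable
#' by a developmental delay only if its wild-type reference expression is
#' strictly higher in the early window (default 0-6 h) than in the late
#' window (default 6-12 h); a down-regulated gene only if it is strictly
#' lower early than late.  Ties count as NOT explained — a gene with equal
#' early and late levels gains nothing from sampling the trajectory
#' earlier.  Windows must tile exactly onto reference bin boundaries; bin
#' values inside a window are combined by `aggregate` (mean by default).
#'
#' Genes with `direction == "none"` are ignored; dysregulated genes absent
#' from the reference are excluded from classification and reported in the
#' `no_reference_gene_ids` attribute.
#'
#' @param de a `de_result` data frame.
#' @param reference a [time_course()].
#' @param early_window,late_window length-2 hour intervals aligned to bins.
#' @param aggregate `"mean"` or `"max"` over the bins of a window.
#' @return A data frame of class `delay_classification` with one row per
#'   classified gene: `gene_id`, `direction`, `window_early_mean`,
#'   `window_late_mean`, `explained_by_delay`; attributes
#'   `n_up_unexplained`, `n_down_unexplained`, `no_reference_gene_ids`.
#' @examples
#' sim <- simulate_embryo_experiment(
#'   simulation_config(n_genes = 300, delay_hours = 2, seed = 3))
#' de <- differential_expression(sim$control, sim$mutant)
#' cl <- classify_delay_explainability(de, sim$reference)
#' summary(cl)
#' @export
classify_delay_explainability <- function(de, reference,
                                          early_window = c(0, 6),
                                          late_window = c(6, 12),
                                          aggregate = c("mean", "max")) {
  stopifnot(inherits(de, "data.frame"), inherits(reference, "time_course"))
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") rowMeans else
    function(m) apply(m, 1, max)
  early_idx <- window_bin_index(reference, early_window)
  late_idx <- window_bin_index(reference, late_window)

  dys <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  no_ref <- setdiff(dys$gene_id, reference$gene_ids)
  dys <- dys[!(dys$gene_id %in% no_ref), , drop = FALSE]

  early <- agg_fun(reference$values[dys$gene_id, early_idx, drop = FALSE])
  late <- agg_fun(reference$values[dys$gene_id, late_idx, drop = FALSE])
  explained <- ifelse(dys$direction == "up", early > late, early < late)

  out <- data.frame(gene_id = dys$gene_id, direction = dys$direction,
                    window_early_mean = unname(early),
                    window_late_mean = unname(late),
                    explained_by_delay = unname(explained),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_up_unexplained") <- sum(out$direction == "up" & !out$explained_by_delay)
  attr(out, "n_down_unexplained") <- sum(out$direction == "down" & !out$explained_by_delay)
  attr(out, "no_reference_gene_ids") <- no_ref
  class(out) <- c("delay_classification", "data.frame")
  out
}

#' @export
summary.delay_classification <- function(object, ...) {
  up <- sum(object$direction == "up")
  dn <- sum(object$direction == "down")
  cat(sprintf("delay classification of %d dysregulated genes (%d up, %d down)\n",
              nrow(object), up, dn))
  cat(sprintf("not explainable by delay: %d of %d up, %d of %d down\n",
              attr(object, "n_up_unexplained"), up,
              attr(object, "n_down_unexplained"), dn))
  nr <- attr(object, "no_reference_gene_ids")
  if (length(nr))
    cat(sprintf("%d dysregulated genes had no reference row and were excluded\n",
                length(nr)))
  invisible(object)
}

#' Assign a developmental stage to a sample by rank correlation
#'
#' Spearman-correlates a sample's per-gene expression vector with every
#' reference bin over the shared genes and reports the best-matching bin
#' (earliest bin on ties).  A delayed mutant is expected to match an
#' earlier bin than its chronological-age control.
#'
#' @param sample_means named numeric vector of per-gene expression (e.g.
#'   replicate means); at least 10 names must be shared with the
#'   reference.
#' @param reference a [time_course()] with at least 2 bins.
#' @return list with `best_bin` (index), `best_bin_label`, and
#'   `correlation_profile` (named per-bin Spearman rho).
#' @export
stage_assignment <- function(sample_means, reference) {
  stopifnot(inherits(reference, "time_course"))
  if (nrow(reference$bins) < 2L)
    stop_devdelay("reference needs at least 2 bins",
                  class = "devdelay_value_error")
  shared <- intersect(names(sample_means), reference$gene_ids)
  if (length(shared) < 10L)
    stop_devdelay("only %d genes shared with the reference (need >= 10)",
                  length(shared), class = "devdelay_value_error")
  s <- sample_means[shared]
  if (stats::sd(s) == 0)
    stop_devdelay("sample vector is constant over shared genes; correlation undefined (degenerate)",
                  class = "devdelay_degenerate_error")
  rho <- suppressWarnings(
    stats::cor(s, reference$values[shared, , drop = FALSE],
               method = "spearman")[1L, ])
  if (anyNA(rho))
    stop_devdelay("correlation undefined for a constant reference bin (degenerate)",
                  class = "devdelay_degenerate_error")
  best <- which.max(rho)  # which.max returns the earliest maximum
  list(best_bin = unname(best),
       best_bin_label = reference$bins$label[best],
       correlation_profile = stats::setNames(as.numeric(rho),
                                             reference$bins$label))
}
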