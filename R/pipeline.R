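#' Configuration for an end-to-end delay-analysis run
#'
#' Collects the input tables and every analysis threshold. Thresholds
#' default to the conventional values of this analysis: FDR
#' `alpha = 0.05`, testability floor 1 FPKM, low-expression floor
#' FPKM < 3, and the 0-6 h / 6-12 h windows of the delay rule.
#'
#' @param control_path,mutant_path expression-table TSVs (see
#'   [read_expression_table()]).
#' @param reference_path developmental reference TSV (see
#'   [read_time_course()]).
#' @param annotation_path optional gene->term TSV
#'   (`gene_id`, `term_id`, `term_name`) for enrichment.
#' @param term_edges_path optional parent->child term-edge TSV
#'   (`parent_id`, `child_id`).
#' @param unit unit of the expression tables.
#' @param alpha FDR threshold in (0, 1).
#' @param min_tested_mean testability floor on condition means.
#' @param fpkm_threshold low-expression floor for
#'   [low_expression_dysregulated()].
#' @param early_window,late_window hour windows of the delay rule, aligned
#'   to reference bins.
#' @param aggregate window aggregation, `"mean"` or `"max"`.
#' @param n_annotated annotated transcriptional units; defaults to the
#'   number of genes in the expression tables.
#' @param out_dir optional output directory for the report artifacts.
#' @param seed optional integer recorded in the run metadata.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(control_path, mutant_path, reference_path,
                            annotation_path = NULL, term_edges_path = NULL,
                            unit = c("FPKM", "count"), alpha = 0.05,
                            min_tested_mean = 1, fpkm_threshold = 3,
                            early_window = c(0, 6), late_window = c(6, 12),
                            aggregate = "mean", n_annotated = NULL,
                            out_dir = NULL, seed = NULL) {
  unit <- match.arg(unit)
  if (alpha <= 0 || alpha >= 1)
    stop_devdelay("alpha must be in (0, 1)", class = "devdelay_value_error")
  structure(
    list(control_path = control_path, mutant_path = mutant_path,
         reference_path = reference_path, annotation_path = annotation_path,
         term_edges_path = term_edges_path, unit = unit, alpha = alpha,
         min_tested_mean = min_tested_mean, fpkm_threshold = fpkm_threshold,
         early_window = early_window, late_window = late_window,
         aggregate = aggregate, n_annotated = n_annotated,
         out_dir = out_dir, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full delay analysis end to end
#'
#' Reads the tables, runs [differential_expression()], tallies the
#' dysregulation classes, runs the derepression check and the
#' low-expression filter, summarizes the developmental profiles of the up-
#' and down-regulated sets, classifies delay-explainability, stage-assigns
#' both conditions, and (when an annotation is supplied) tests the
#' delay-unexplained up and down sets for term overrepresentation.
#'
#' When `config$out_dir` is set, the stage outputs are written there:
#' `de.tsv`, `tally.json`, `delay_classification.tsv`,
#' `profile_summary.tsv`, `enrichment.tsv` and `run_metadata.json`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `devdelay_report`: list with `de`, `tally`,
#'   `derepression`, `low_expression`, `profiles` (up/down
#'   [profile_summary()]), `delay` (the [classify_delay_explainability()]
#'   result), `stages` (control/mutant [stage_assignment()]), `enrichment`
#'   (list with `up`, `down`, or `NULL`), and `config`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_embryo_experiment(
#'   simulation_config(n_genes = 300, delay_hours = 2, seed = 5))
#' write_expression_table(sim$control, file.path(dir, "control.tsv"))
#' write_expression_table(sim$mutant, file.path(dir, "mutant.tsv"))
#' write_time_course(sim$reference, file.path(dir, "reference.tsv"))
#' rep <- run_pipeline(pipeline_config(
#'   file.path(dir, "control.tsv"), file.path(dir, "mutant.tsv"),
#'   file.path(dir, "reference.tsv")))
#' rep
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_devdelay("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  control <- stage("read_control",
                   read_expression_table(config$control_path, config$unit, "control"))
  mutant <- stage("read_mutant",
                  read_expression_table(config$mutant_path, config$unit, "mutant"))
  reference <- stage("read_reference", read_time_course(config$reference_path))

  de <- stage("differential_expression",
              differential_expression(control, mutant, alpha = config$alpha,
                                      min_tested_mean = config$min_tested_mean))
  n_ann <- config$n_annotated %||% nrow(de)
  tally <- stage("tally", tally_expression_classes(de, n_ann))
  derep <- stage("derepression_check", derepression_check(de, reference))
  lowx <- stage("low_expression",
                low_expression_dysregulated(de, config$fpkm_threshold))

  in_ref <- function(ids) intersect(ids, reference$gene_ids)
  up_ids <- in_ref(de$gene_id[de$direction == "up"])
  down_ids <- in_ref(de$gene_id[de$direction == "down"])
  profiles <- list(
    up = if (length(up_ids)) stage("profile_up", profile_summary(up_ids, reference)),
    down = if (length(down_ids)) stage("profile_down", profile_summary(down_ids, reference))
  )
  delay <- stage("delay_classification",
                 classify_delay_explainability(de, reference,
                                               early_window = config$early_window,
                                               late_window = config$late_window,
                                               aggregate = config$aggregate))
  stages <- stage("stage_assignment", list(
    control = stage_assignment(stats::setNames(de$mean_control, de$gene_id), reference),
    mutant = stage_assignment(stats::setNames(de$mean_mutant, de$gene_id), reference)
  ))

  enrichment <- NULL
  if (!is.null(config$annotation_path)) {
    ann <- stage("read_annotation",
                 utils::read.delim(config$annotation_path, stringsAsFactors = FALSE))
    edges <- if (!is.null(config$term_edges_path))
      stage("read_term_edges",
            utils::read.delim(config$term_edges_path, stringsAsFactors = FALSE))
    background <- unique(ann$gene_id)
    enrich_set <- function(ids) {
      ids <- intersect(ids, background)
      if (length(ids) == 0L) return(NULL)
      most_specific_terms(
        fisher_overrepresentation(ids, background, ann),
        term_edges = edges, alpha = config$alpha)
    }
    unexp <- delay$gene_id[!delay$explained_by_delay]
    enrichment <- stage("enrichment", list(
      up = enrich_set(intersect(unexp, up_ids)),
      down = enrich_set(intersect(unexp, down_ids))
    ))
  }

  report <- structure(
    list(de = de, tally = tally, derepression = derep,
         low_expression = lowx, profiles = profiles, delay = delay,
         stages = stages, enrichment = enrichment, config = config),
    class = "devdelay_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_de_table(report$de, file.path(out_dir, "de.tsv"))
  jsonlite::write_json(unclass(report$tally),
                       file.path(out_dir, "tally.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(report$delay),
                     file.path(out_dir, "delay_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- do.call(rbind, lapply(names(report$profiles), function(dirn) {
    p <- report$profiles[[dirn]]
    if (is.null(p)) return(NULL)
    data.frame(set = dirn, bin = p$bins$label,
               median_expression = p$median_expression,
               n_genes = p$n_genes, stringsAsFactors = FALSE)
  }))
  if (!is.null(prof))
    utils::write.table(prof, file.path(out_dir, "profile_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- do.call(rbind, lapply(names(report$enrichment), function(dirn) {
    e <- report$enrichment[[dirn]]
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    cbind(set = dirn, as.data.frame(e))
  }))
  if (!is.null(enr))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    config = lapply(unclass(report$config), function(x) x %||% NA),
    package_version = as.character(utils::packageVersion("devdelay")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.devdelay_report <- function(x, ...) {
  cat("devdelay pipeline report\n")
  print(x$tally)
  cat(sprintf("reference-silent genes up-regulated: %d\n",
              x$derepression$n_silent_upregulated))
  cat(sprintf("significant genes below FPKM %s in control: %d (%.2f%%)\n",
              format(x$config$fpkm_threshold), x$low_expression$count,
              x$low_expression$pct_of_significant))
  summary(x$delay)
  cat(sprintf("stage assignment: control ~ %s h, mutant ~ %s h\n",
              x$stages$control$best_bin_label, x$stages$mutant$best_bin_label))
  if (!is.null(x$enrichment)) {
    n_up <- if (is.null(x$enrichment$up)) 0 else nrow(x$enrichment$up)
    n_dn <- if (is.null(x$enrichment$down)) 0 else nrow(x$enrichment$down)
    cat(sprintf("most-specific enriched terms: %d (up-unexplained), %d (down-unexplained)\n",
                n_up, n_dn))
  }
  invisible(x)
}

#' @export
summary.devdelay_report <- function(object, ...) print(object, ...)
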