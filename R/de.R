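#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment controlling the false discovery rate, delegating
#' to [stats::p.adjust()]. Output order follows input order; each q-value
#' lies in `[p, 1]` and thresholding `q < alpha` controls the expected
#' false-discovery proportion at `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_devdelay("p-values must all lie in [0, 1]",
                  class = "devdelay_value_error")
  stats::p.adjust(p, method = "BH")
}

#' Simplified per-gene differential expression between two conditions
#'
#' A deliberately simple, calibrated stand-in for a full RNA-seq DE engine:
#' the downstream delay analysis consumes only per-gene status, direction,
#' condition means and q-values, so any well-calibrated per-gene test
#' suffices.  Per gene:
#'
#' * `not_detected` — all replicate values are 0 in both conditions;
#' * `detected_untested` — detected, but a condition mean is below
#'   `min_tested_mean` or the within-group variance is degenerate (both
#'   groups constant on the log scale);
#' * `tested` — Welch's t on `log2(x + 1)` replicate values; q-values are
#'   BH-adjusted across tested genes and `direction` is `up`/`down` at
#'   `q < alpha` by the sign of the mean difference, `none` otherwise.
#'
#' @param control,mutant [expression_matrix()] objects over the same genes
#'   in the same order, each with at least 2 replicates.
#' @param alpha FDR threshold for calling a direction (default 0.05).
#' @param min_tested_mean minimal condition mean (in the matrix unit)
#'   required for testing (default 1).
#' @return A data frame of class `de_result` with one row per gene:
#'   `gene_id`, `status`, `mean_control`, `mean_mutant`,
#'   `log2_fold_change`, `p_value`, `q_value`, `direction`.
#'   `log2_fold_change`, `p_value` and `q_value` are `NA` for untested
#'   genes. The `alpha` used is stored as an attribute.
#' @examples
#' set.seed(1)
#' ctl <- expression_matrix(matrix(rpois(30, 20), 10, 3),
#'                          paste0("g", 1:10), "count", "control")
#' mut <- expression_matrix(matrix(rpois(30, 20), 10, 3),
#'                          paste0("g", 1:10), "count", "mutant")
#' differential_expression(ctl, mut)
#' @export
differential_expression <- function(control, mutant, alpha = 0.05,
                                    min_tested_mean = 1) {
  stopifnot(inherits(control, "expression_matrix"),
            inherits(mutant, "expression_matrix"))
  if (!identical(control$gene_ids, mutant$gene_ids))
    stop_devdelay("control and mutant matrices must share the same genes in the same order",
                  class = "devdelay_value_error")
  if (ncol(control$values) < 2L || ncol(mutant$values) < 2L)
    stop_devdelay("need at least 2 replicates per condition for testing",
                  class = "devdelay_value_error")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_devdelay("alpha must be in (0, 1)", class = "devdelay_value_error")

  cv <- control$values; mv <- mutant$values
  mean_c <- rowMeans(cv); mean_m <- rowMeans(mv)

  lc <- log2(cv + 1); lm_ <- log2(mv + 1)
  n1 <- ncol(lc); n2 <- ncol(lm_)
  m1 <- rowMeans(lc); m2 <- rowMeans(lm_)
  v1 <- rowSums((lc - m1)^2) / (n1 - 1)
  v2 <- rowSums((lm_ - m2)^2) / (n2 - 1)

  status <- ifelse(mean_c == 0 & mean_m == 0, "not_detected", "tested")
  testable <- status == "tested" &
    mean_c >= min_tested_mean & mean_m >= min_tested_mean &
    (v1 + v2) > 0
  status[status == "tested" & !testable] <- "detected_untested"

  p <- q <- lfc <- rep(NA_real_, length(mean_c))
  if (any(testable)) {
    se2 <- v1[testable] / n1 + v2[testable] / n2
    tstat <- (m2[testable] - m1[testable]) / sqrt(se2)
    df <- se2^2 / ((v1[testable] / n1)^2 / (n1 - 1) +
                     (v2[testable] / n2)^2 / (n2 - 1))
    p[testable] <- 2 * stats::pt(-abs(tstat), df)
    q[testable] <- bh_adjust(p[testable])
    lfc[testable] <- m2[testable] - m1[testable]  # log2(x+1) scale
  }
  direction <- rep("none", length(mean_c))
  sig <- testable & !is.na(q) & q < alpha
  direction[sig & mean_m > mean_c] <- "up"
  direction[sig & mean_m < mean_c] <- "down"

  out <- data.frame(
    gene_id = control$gene_ids, status = status,
    mean_control = mean_c, mean_mutant = mean_m,
    log2_fold_change = lfc, p_value = p, q_value = q,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_tested_mean") <- min_tested_mean
  class(out) <- c("de_result", "data.frame")
  out
}

#' Read / write a differential-expression result table
#'
#' TSV with columns `gene_id`, `status`, `mean_control`, `mean_mutant`,
#' `log2_fold_change` (`log2fc` accepted on read), `p_value` (`p`),
#' `q_value` (`q`), `direction`. `NA` marks untested fields.
#'
#' @param de a `de_result` data frame.
#' @param path file path.
#' @return `read_de_table` returns a `de_result`; `write_de_table` returns
#'   `path` invisibly.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "data.frame"))
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  ren <- c(log2fc = "log2_fold_change", p = "p_value", q = "q_value")
  for (nm in names(ren)) names(de)[names(de) == nm] <- ren[[nm]]
  needed <- c("gene_id", "status", "mean_control", "mean_mutant", "direction")
  miss <- setdiff(needed, names(de))
  if (length(miss))
    stop_devdelay("DE table %s lacks column(s): %s", path,
                  paste(miss, collapse = ", "), class = "devdelay_format_error")
  class(de) <- c("de_result", "data.frame")
  de
}
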