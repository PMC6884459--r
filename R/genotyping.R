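#' Summarize a coding-region deletion and its diagnostic PCR amplicon
#'
#' Small genotyping arithmetic for a deletion allele screened by PCR: the
#' percentage of the coding region removed, and the amplicon length expected
#' from the deletion chromosome given the wild-type amplicon length.
#'
#' @param codons_removed integer >= 0, codons deleted from the coding region.
#' @param codons_total integer > 0, codons in the full coding region.
#' @param wt_amplicon_bp integer > 0, diagnostic amplicon length on the
#'   wild-type template.
#' @param deletion_bp integer >= 0, genomic length of the deletion; must not
#'   exceed `wt_amplicon_bp`.
#' @return A list of class `deletion_summary` with fields `codons_removed`,
#'   `codons_total`, `coding_loss_pct` (integer percent, rounded),
#'   `wt_amplicon_bp`, `deletion_bp`, `expected_mutant_amplicon_bp`.
#' @examples
#' describe_deletion(326, 405, 2007, 1409)  # 80% coding loss, 598 bp amplicon
#' @export
describe_deletion <- function(codons_removed, codons_total,
                              wt_amplicon_bp, deletion_bp) {
  check_count <- function(x, name, min) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
      stop_devdelay("%s must be a single integer >= %d", name, min,
                    class = "devdelay_value_error")
    as.integer(x)
  }
  codons_removed <- check_count(codons_removed, "codons_removed", 0L)
  codons_total <- check_count(codons_total, "codons_total", 1L)
  wt_amplicon_bp <- check_count(wt_amplicon_bp, "wt_amplicon_bp", 1L)
  deletion_bp <- check_count(deletion_bp, "deletion_bp", 0L)
  if (codons_removed > codons_total)
    stop_devdelay("codons_removed exceeds codons_total",
                  class = "devdelay_value_error")
  if (deletion_bp > wt_amplicon_bp)
    stop_devdelay("deletion_bp (%d) exceeds wt_amplicon_bp (%d)",
                  deletion_bp, wt_amplicon_bp, class = "devdelay_value_error")
  structure(
    list(codons_removed = codons_removed,
         codons_total = codons_total,
         coding_loss_pct = as.integer(round_half_up(100 * codons_removed / codons_total)),
         wt_amplicon_bp = wt_amplicon_bp,
         deletion_bp = deletion_bp,
         expected_mutant_amplicon_bp = wt_amplicon_bp - deletion_bp),
    class = "deletion_summary"
  )
}

#' @export
print.deletion_summary <- function(x, ...) {
  cat(sprintf(
    "deletion: %d/%d codons removed (%d%% of the coding region)\n",
    x$codons_removed, x$codons_total, x$coding_loss_pct))
  cat(sprintf(
    "amplicon: %d bp wild-type - %d bp deletion = %d bp expected on the mutant template\n",
    x$wt_amplicon_bp, x$deletion_bp, x$expected_mutant_amplicon_bp))
  invisible(x)
}
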