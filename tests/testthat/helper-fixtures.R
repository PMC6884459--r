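# small programmatic fixtures shared across test files

make_expr <- function(values, ids = paste0("g", seq_len(nrow(values))),
                      unit = "FPKM", label = "") {
  expression_matrix(values, gene_ids = ids, unit = unit,
                    condition_label = label)
}

# a 4-gene, 3-bin reference with one silent gene
tiny_reference <- function() {
  time_course(
    rbind(c(10, 4, 1), c(1, 4, 10), c(0, 0, 0), c(5, 5, 5)),
    gene_ids = c("early", "late", "quiet", "flatg"),
    bin_starts = c(0, 2, 4), bin_ends = c(2, 4, 6)
  )
}

# a 12-bin [0,24) reference over explicit rows
reference_12 <- function(values, ids = paste0("g", seq_len(nrow(values)))) {
  time_course(values, gene_ids = ids,
              bin_starts = seq(0, 22, 2), bin_ends = seq(2, 24, 2))
}

# hand-built DE records
de_records <- function(gene_id, direction = "none", status = "tested",
                       mean_control = 10, mean_mutant = 10) {
  df <- data.frame(gene_id = gene_id, status = status,
                   mean_control = mean_control, mean_mutant = mean_mutant,
                   log2_fold_change = NA_real_, p_value = NA_real_,
                   q_value = NA_real_, direction = direction,
                   stringsAsFactors = FALSE)
  class(df) <- c("de_result", "data.frame")
  df
}

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
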