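# small on-disk fixtures built in code

write_ct_fixture <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

write_design_fixture <- function(sample_id, group) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup",
               paste(sample_id, group, sep = "\t")), path)
  path
}

## expression table straight from a positive quantity matrix
expr_from_q <- function(q, groups = rep("g1", nrow(q))) {
  structure(list(q = q, design = group_design(rownames(q), groups)),
            class = "expression_table")
}
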