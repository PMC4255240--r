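# small in-code fixtures shared across tests

toy_counts_table <- function() {
  connectivity_table(data.frame(
    target = c("V1", "V1", "V2"),
    source = c("V2", "V4", "V4"),
    supra = c(40L, 10L, 30L),
    infra = c(60L, 90L, 10L),
    distance_mm = c(9.3, 14.8, 9.4)))
}

# write a delimited connectivity file and return its path
write_toy_file <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
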