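# hand-built tiny objects for arithmetic-level tests

tiny_compendium <- function(n = 2L, vaf = 0.4, tissue = "FF") {
  sites <- data.frame(chrom = rep("chr1", n), pos = seq(100L, by = 100L,
                                                        length.out = n),
                      ref = rep("A", n), alt = rep("T", n),
                      tumor_vaf = rep_len(vaf, n))
  new_compendium("TP", sites, tissue)
}

evidence_for <- function(compendium, depth, alt_count) {
  data.table::data.table(chrom = compendium$sites$chrom,
                         pos = compendium$sites$pos,
                         ref = compendium$sites$ref,
                         alt = compendium$sites$alt,
                         depth = as.integer(depth),
                         alt_count = as.integer(alt_count))
}

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
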