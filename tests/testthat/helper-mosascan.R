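# shared fixtures for the test suite; everything is built in code

fixture_records <- function() {
  suppressMessages(load_cohort_fixture())
}

fixture_report <- function() {
  suppressMessages(summarize_cohort(fixture_records()))
}

# write a small hand-rolled VCF for reader tests
write_mini_vcf <- function(body_lines, samples = c("S1"),
                           formats = c("GT", "AD", "DP")) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

write_mini_ped <- function(rows) {
  path <- tempfile(fileext = ".ped")
  writeLines(rows, path)
  path
}

# classify a printed AAF percentage exactly (one decimal place -> /1000)
classify_percent <- function(aaf_percent, sex, chrom_class,
                             policy = threshold_policy()) {
  classify_observation(round(aaf_percent * 10), 1000, sex = sex,
                       chrom_class = chrom_class, policy = policy)
}
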