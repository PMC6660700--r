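test_that("bundled fixture loads with the documented shape", {
  rec <- fixture_records()
  expect_s3_class(rec, "cohort_records")
  expect_identical(nrow(rec), 120L)
  expect_identical(sum(rec$carrier == "proband"), 80L)
  expect_identical(sum(rec$table == "parental"), 40L)
  # record ordering is preserved: first and last rows as printed
  expect_identical(rec$record_id[1], "1F")
  expect_identical(rec$record_id[120], "120F-Fa")

  r1 <- rec[rec$record_id == "1F", ]
  expect_identical(r1$gene, "ARID1A")
  expect_identical(r1$classification, "pathogenic")
  expect_equal(r1$aaf_percent, 17.5)

  pgm <- rec[rec$record_id == "81M-PGM", ]
  expect_true(is.na(pgm$aaf_percent))
  expect_identical(pgm$aaf_method, "unavailable")
  expect_identical(pgm$carrier, "grandmother")

  placeholder <- rec[rec$record_id == "106-PLACEHOLDER", ]
  expect_identical(placeholder$aaf_method, "unavailable")
  expect_true(is.na(placeholder$aaf_percent))
})

test_that("fixture validation rejects malformed input", {
  rec <- read.delim(mosascan_fixture_path(), colClasses = "character")

  dup <- rec
  dup$record_id[2] <- dup$record_id[1]
  p <- tempfile(fileext = ".tsv")
  write.table(dup, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort_fixture(p), "duplicate record_id")

  lines <- readLines(mosascan_fixture_path())
  lines[5] <- paste(lines[5], "extra", sep = "\t")
  p2 <- tempfile(fileext = ".tsv")
  writeLines(lines, p2)
  expect_error(load_cohort_fixture(p2), "malformed cohort row.*5")

  bad <- rec
  bad$classification[3] <- "benign"
  p3 <- tempfile(fileext = ".tsv")
  write.table(bad, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort_fixture(p3), "invalid classification.*benign")

  bad2 <- rec
  bad2$aaf_percent[1] <- "101"
  p4 <- tempfile(fileext = ".tsv")
  write.table(bad2, p4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort_fixture(p4), "out of \\(0, 100\\]")
})

test_that("consequence classification follows the protein-first precedence", {
  cases <- list(
    list("c.1447C>T", "p.R483*", "nonsense"),
    list("c.67+2T>G", NA, "splice"),
    list("c.810+1G>T", NA, "splice"),
    list("c.400-3C>T", NA, "splice"),
    list("c.1359_1361delAGA", "p.E453del", "inframe_indel"),
    list("c.573_575del", "p.I191del", "inframe_indel"),
    list("c.2914delG", "p.D972fs", "frameshift"),
    list("c.865_867delinsAA", "p.Y289fs", "frameshift"),  # delins + fs
    list("c.1077dupT", "p.L362fs", "frameshift"),
    list("c.419G>A", "p.R140Q", "missense"),
    # cDNA-only del/dup resolved by span divisible by three
    list("c.100_102del", NA, "inframe_indel"),
    list("c.100_103del", NA, "frameshift"),
    list("c.100delA", NA, "frameshift")
  )
  for (cs in cases) {
    expect_identical(classify_consequence(cs[[1]], cs[[2]]), cs[[3]],
                     label = paste(cs[[1]], cs[[2]]))
  }
})

test_that("unparseable notation yields class other with a warning, not an error", {
  expect_warning(out <- classify_consequence("not-hgvs", NA), "unparseable")
  expect_identical(out, "other")
  expect_warning(out2 <- classify_consequence("c.55A>G", "p.garbage!!"),
                 "unparseable")
  expect_identical(out2, "other")
})

test_that("fixture-wide consequence spectrum matches the published counts", {
  rec <- fixture_records()
  csq <- classify_consequence(rec$cdna_hgvs, rec$protein_hgvs)
  tab <- table(csq)
  expect_equal(unname(tab["missense"]), 81)
  expect_equal(unname(tab["nonsense"]), 17)
  expect_equal(sum(tab[c("frameshift", "inframe_indel")]), 16)
  expect_equal(unname(tab["splice"]), 6)
  expect_false("other" %in% names(tab))
  # totality: classification never raises on fixture rows
  expect_no_warning(classify_consequence(rec$cdna_hgvs, rec$protein_hgvs))
})

test_that("substitution detection matches definition and fixture count", {
  expect_true(is_substitution("c.419G>A"))
  expect_true(is_substitution("c.291+2T>G"))   # splice-site substitution
  expect_false(is_substitution("c.2083_2084delCA"))
  expect_false(is_substitution("c.1077dupT"))
  expect_warning(expect_false(is_substitution("rubbish")), "unparseable")

  rec <- fixture_records()
  sub <- is_substitution(rec$cdna_hgvs)
  expect_identical(sum(sub), 104L)
  # substitutions = missense + nonsense + splice on this cohort
  csq <- classify_consequence(rec$cdna_hgvs, rec$protein_hgvs)
  expect_identical(sum(csq %in% c("missense", "nonsense", "splice")), 104L)
})

test_that("CpG site detection covers both strands and validates bases", {
  expect_true(is_cpg_site("C", "A", "G", "T"))
  expect_false(is_cpg_site("A", "C", "G", "T"))
  expect_true(is_cpg_site("G", "C", "A", "A"))   # reverse-strand CpG
  expect_false(is_cpg_site("C", "G", "A", "T"))
  expect_error(is_cpg_site("X", "A", "G"), "invalid reference")
})

test_that("proband sex parses from the record id suffix", {
  expect_identical(proband_sex_from_id(c("1F", "6M", "12U", "84U-Mo")),
                   c("female", "male", "unknown", "unknown"))
  rec <- fixture_records()
  pro <- rec[rec$table == "proband", ]
  expect_identical(proband_sex_from_id(pro$record_id), pro$carrier_sex)
})
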