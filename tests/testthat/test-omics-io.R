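# Domain types and readers/writers for the tabular inputs.

test_that("omics_matrix enforces range invariants per kind", {
  m <- matrix(c(100, 0, NA, 50), 2, 2,
              dimnames = list(c("e1", "e2"), c("s1", "s2")))
  psi <- omics_matrix(m, "psi")
  expect_s3_class(psi, "omics_matrix")
  expect_identical(omics_kind(psi), "psi")
  expect_equal(sum(is.na(omics_values(psi))), 1)

  bad_beta <- matrix(c(0.2, 1.2), 1, 2,
                     dimnames = list("g", c("a", "b")))
  expect_error(omics_matrix(bad_beta, "methylation"), "beta out of range")
  neg <- matrix(-1, 1, 1, dimnames = list("g", "s"))
  expect_error(omics_matrix(neg, "expression"), "out of range")
  with_na <- matrix(c(1, NA), 1, 2, dimnames = list("g", c("a", "b")))
  expect_error(omics_matrix(with_na, "expression"), "missing")
  psi_oob <- matrix(101, 1, 1, dimnames = list("e", "s"))
  expect_error(omics_matrix(psi_oob, "psi"), "out of range")
})

test_that("duplicate feature or sample ids are rejected", {
  m <- matrix(1, 2, 2, dimnames = list(c("g", "g"), c("a", "b")))
  expect_error(omics_matrix(m, "expression"), "duplicate feature")
  m2 <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("a", "a")))
  expect_error(omics_matrix(m2, "expression"), "duplicate sample")
})

test_that("read_omics_matrix parses TSVs and flags bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3\ts4",
               "g1\t1.5\t2\t0\t7",
               "g2\t3\t4\t5\t6",
               "g3\t0\t0\t1\t2"), f)
  x <- read_omics_matrix(f, "expression")
  expect_equal(nrow(x), 3)
  expect_equal(length(sample_ids(x)), 4)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "g1\tabc"), f2)
  expect_error(read_omics_matrix(f2, "expression"), "non-numeric")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "g1\t1.2"), f3)
  expect_error(read_omics_matrix(f3, "methylation"), "beta out of range")
})

test_that("write/read round-trips values bit-identically, NA preserved", {
  set.seed(11)
  m <- matrix(runif(20, 0, 100), 4, 5,
              dimnames = list(paste0("e", 1:4), paste0("s", 1:5)))
  m[2, 3] <- NA
  x <- omics_matrix(m, "psi")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(x, f, comments = "round-trip fixture")
  y <- read_omics_matrix(f, "psi")
  expect_identical(omics_values(y), omics_values(x))
  expect_true(grepl("^# ", readLines(f, n = 1)))
})

test_that("sample table reader validates and case-normalizes conditions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttissue\tcondition",
               "a\tlung\tTumor", "b\tlung\ttumor",
               "c\tlung\tNORMAL", "d\tlung\tnormal"), f)
  s <- read_sample_table(f)
  expect_equal(table(s$condition)[["tumor"]], 2)
  expect_equal(table(s$condition)[["normal"]], 2)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttissue\tcondition", "a\tlung\tmetastatic"), f2)
  expect_error(read_sample_table(f2), "allowed labels: tumor, normal")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttissue\tcondition",
               "a\tlung\ttumor", "a\tlung\tnormal"), f3)
  expect_error(read_sample_table(f3), "duplicate sample_id")
})

test_that("annotation and target map readers validate their contracts", {
  fa <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tgene_id\tlength_nt",
               "e1\tg1\t12", "e2\tg1\t140", "e3\tg2\t3"), fa)
  ann <- read_exon_annotation(fa)
  expect_identical(ann$length_nt, c(12L, 140L, 3L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tgene_id\tlength_nt", "e1\tg1\t0"), bad)
  expect_error(read_exon_annotation(bad), "positive integer")

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sf_id\texon_id", "SF1\te1", "SF1\te9"), ft)
  expect_error(read_target_map(ft, annotation = ann), "absent from annotation")
  writeLines(c("sf_id\texon_id", "SF1\te1", "SF1\te2"), ft)
  tm <- read_target_map(ft, annotation = ann)
  expect_equal(nrow(tm), 2)
})

vast_fixture <- function() {
  f <- withr::local_tempfile(fileext = ".tab", .local_envir = parent.frame())
  writeLines(c(
    paste("GENE", "EVENT", "LENGTH", "sampleA", "sampleA-Q",
          "sampleB", "sampleB-Q", "sampleC", "sampleC-Q", sep = "\t"),
    paste("TEAD2", "EX001", "12", "88", "N,N,N", "90", "OK,OK",
          "85", "SOK,OK", sep = "\t"),
    paste("SPTAN1", "EX002", "140", "10", "LOW,OK", "12", "VLOW,OK",
          "14", "OK,OK", sep = "\t")), f)
  f
}

test_that("vast-tools reader masks low-quality PSI cells", {
  f <- vast_fixture()
  res <- read_vast_inclusion_table(f, min_quality = "VLOW")
  vals <- omics_values(res$psi)
  # exactly the one grade-N cell is dropped at the VLOW cutoff
  expect_equal(sum(is.na(vals)), 1)
  expect_true(is.na(vals["EX001", "sampleA"]))
  expect_identical(res$annotation$length_nt, c(12L, 140L))

  # most permissive grade keeps everything: equals the raw PSI columns
  res_all <- read_vast_inclusion_table(f, min_quality = "N")
  expect_equal(sum(is.na(omics_values(res_all$psi))), 0)
  expect_equal(unname(omics_values(res_all$psi)["EX001", ]), c(88, 90, 85))

  # a stricter cutoff is monotone: more cells masked
  res_ok <- read_vast_inclusion_table(f, min_quality = "OK")
  expect_gte(sum(is.na(omics_values(res_ok$psi))), 3)
})

test_that("vast-tools reader rejects malformed tables", {
  f <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("GENE\tEVENT\tLENGTH\tsampleA",
               "g\te\t10\t50"), f)
  expect_error(read_vast_inclusion_table(f), "-Q")

  f2 <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("GENE\tEVENT\tLENGTH\tsampleA\tsampleA-Q",
               "g\te\t10\t50\tWEIRD,OK"), f2)
  expect_error(read_vast_inclusion_table(f2), "unknown quality grade")
})
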