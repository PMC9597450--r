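test_that("write then read is the identity on a band matrix", {
  bm <- generate_band_matrix(list(
    assay_spec("A", 6, n_monomorphic = 3, n_unique_pos = 2,
               n_unique_neg = 1, n_other_polymorphic = 8),
    assay_spec("B", 6, n_monomorphic = 1, n_other_polymorphic = 4)
  ), seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_band_matrix(bm, path)
  back <- read_band_matrix(path)
  expect_identical(back$genotypes, bm$genotypes)
  expect_equal(n_bands(back), n_bands(bm))
  # writer sorts by assay then descending size: compare in that order
  o <- order(bm$bands$assay_id, -bm$bands$fragment_size, bm$bands$band_id)
  expect_equal(back$bands$fragment_size, bm$bands$fragment_size[o])
  expect_identical(unname(back$presence), unname(bm$presence[o, ]))
})

test_that("reader validates cells, duplicates and empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("assay_id,band_id,fragment_size,G1,G2",
               "P1,500,500,1,2"), path)
  expect_error(read_band_matrix(path), "malformed cell.*G2")

  writeLines(c("assay_id,band_id,fragment_size,G1,G2",
               "P1,500,500,1,0",
               "P1,500,510,0,1"), path)
  expect_error(read_band_matrix(path), "duplicate band")

  writeLines(character(0), path)
  expect_error(read_band_matrix(path), "empty")
})

test_that("comma and tab dialects are both accepted, roster order kept", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("assay_id,band_id,fragment_size,Gb,Ga",
               "P1,500,500,1,0",
               "P1,300,300,0,1"), path)
  bm <- read_band_matrix(path)
  expect_identical(bm$genotypes, c("Gb", "Ga"))
  expect_equal(unname(bm$presence[, "Gb"]), c(1L, 0L))
})

test_that("band classification matches the exhaustive truth-table oracle", {
  for (n in 2:8) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), n)))
    got <- apply(patterns, 1L, classify_band)
    want <- apply(patterns, 1L, ref_classify)
    expect_identical(got, want, info = paste("n =", n))
  }
  expect_error(classify_band(1), "at least two genotypes")
})

test_that("assay summaries obey the MB + PB = TAB accounting", {
  bm <- small_band_matrix()
  s1 <- summarize_assay(bm, "P1")
  expect_equal(s1$n_monomorphic, 1)
  expect_equal(s1$n_unique_pos, 1)
  expect_equal(s1$n_unique_neg, 1)
  expect_equal(s1$n_polymorphic, 3)
  expect_equal(s1$n_total, 4)
  expect_equal(c(s1$fs_min, s1$fs_max), c(300, 900))
  expect_error(summarize_assay(bm, "nope"), "unknown assay_id")

  # shapes seen in the study's primer tables: MB=5/PB=1 and an all-unique-rich
  # 19-band assay with no monomorphic bands
  shaped <- generate_band_matrix(list(
    assay_spec("issr4", 6, n_monomorphic = 5, n_other_polymorphic = 1),
    assay_spec("issr2", 6, n_unique_pos = 9, n_other_polymorphic = 10)
  ), seed = 2)
  s <- summarize_assays(shaped)
  expect_equal(unlist(s[1, c("n_monomorphic", "n_unique", "n_polymorphic",
                             "n_total")], use.names = FALSE), c(5, 0, 1, 6))
  expect_equal(unlist(s[2, c("n_monomorphic", "n_unique", "n_polymorphic",
                             "n_total")], use.names = FALSE), c(0, 9, 19, 19))
  expect_true(all(s$n_monomorphic + s$n_polymorphic == s$n_total))
  expect_true(all(s$n_unique <= s$n_polymorphic))
})

test_that("all-monomorphic assay degenerates to PB = UB = 0", {
  bm <- generate_band_matrix(assay_spec("M", 6, n_monomorphic = 4), seed = 1)
  s <- summarize_assay(bm, "M")
  expect_equal(s$n_polymorphic, 0)
  expect_equal(s$n_unique, 0)
  expect_equal(s$n_total, s$n_monomorphic)
})

test_that("bands amplified in no genotype are excluded from TAB", {
  bm <- band_matrix(paste0("G", 1:4),
                    data.frame(assay_id = "P", band_id = c("a", "b"),
                               fragment_size = c(500, 400)),
                    rbind(c(1, 1, 0, 0), c(0, 0, 0, 0)))
  s <- summarize_assay(bm, "P")
  expect_equal(s$n_total, 1)
  expect_equal(band_classes(bm)[2], "absent")
})

test_that("unique-band catalogue equals a brute-force per-band scan", {
  set.seed(42)
  pres <- matrix(rbinom(6 * 50, 1, 0.55), nrow = 50)
  bm <- band_matrix(paste0("G", 1:6),
                    data.frame(assay_id = "R", band_id = as.character(1:50),
                               fragment_size = 100 + 1:50),
                    pres)
  cat <- unique_band_catalogue(bm)
  for (g in seq_len(6)) {
    npos <- sum(apply(pres, 1, function(r) sum(r) == 1 && r[g] == 1))
    nneg <- sum(apply(pres, 1, function(r) sum(r) == 5 && r[g] == 0))
    expect_equal(cat$n_pos[g], npos)
    expect_equal(cat$n_neg[g], nneg)
  }
  cls <- band_classes(bm)
  expect_equal(sum(cat$n_specific),
               sum(cls %in% c("unique_pos", "unique_neg")))
})

test_that("all-monomorphic matrix yields an empty catalogue", {
  bm <- generate_band_matrix(assay_spec("M", 5, n_monomorphic = 7), seed = 1)
  cat <- unique_band_catalogue(bm)
  expect_true(all(cat$n_specific == 0))
})

test_that("constructor rejects inconsistent input", {
  expect_error(band_matrix(character(0),
                           data.frame(assay_id = "a", band_id = "b",
                                      fragment_size = 1),
                           matrix(1, 1, 0)),
               "at least one genotype")
  expect_error(band_matrix(c("G1", "G2"),
                           data.frame(assay_id = "a", band_id = "b",
                                      fragment_size = -5),
                           matrix(c(1, 0), 1)),
               "positive")
})
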