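test_that("per-chromosome descriptors are exact", {
  k <- karyotype_set("g", short_arm = c(5, 0, 2), long_arm = c(5, 4, 6))
  d <- chromosome_descriptors(k)
  expect_equal(d$CL, c(10, 4, 8))
  expect_equal(d$arm_ratio, c(1, Inf, 3))
  expect_equal(d$ci, c(0.5, 0, 0.25))
  expect_equal(d$m_value, c(0, 1, 0.5))
  expect_error(karyotype_set("g", 0, 0), "degenerate")
})

test_that("arms are normalized so the long arm is the longer one", {
  k <- karyotype_set("g", short_arm = c(7, 1), long_arm = c(3, 2))
  expect_equal(k$chromosomes$short_arm, c(3, 1))
  expect_equal(k$chromosomes$long_arm, c(7, 2))
})

test_that("arm-ratio classification follows the Levan-style bands", {
  k <- karyotype_set("g", short_arm = c(1, 1, 1, 1, 0),
                     long_arm = c(1, 2, 5, 8, 3))
  expect_equal(classify_chromosomes(k),
               c("nm", "nsm (-)", "nst", "nt", "nt"))
  # configurable thresholds
  loose <- c(nm = 2.5, `nsm (-)` = 5, nst = 9)
  expect_equal(classify_chromosomes(k, loose),
               c("nm", "nm", "nst", "nst", "nt"))
})

test_that("karyotype formula tallies diploid class counts in fixed order", {
  all_m <- karyotype_set("g", rep(2, 13), rep(2.5, 13))
  expect_equal(karyotype_formula(all_m), "26 nm")

  mixed <- karyotype_set("g",
                         short_arm = c(1, rep(1, 6), rep(2, 6)),
                         long_arm = c(2, rep(4, 6), rep(2.5, 6)))
  expect_equal(karyotype_formula(mixed), "2 nsm (-)+12 nst+12 nm")

  set.seed(31)
  rk <- random_karyotype(13)
  cls <- classify_chromosomes(rk)
  counts <- 2 * table(factor(cls, levels = c("nsm (-)", "nst", "nm", "nt")))
  want <- paste(paste(counts[counts > 0], names(counts[counts > 0])),
                collapse = "+")
  expect_equal(karyotype_formula(rk), want)
  expect_equal(sum(counts), rk$n_diploid)
})

test_that("a uniform metacentric complement is perfectly symmetric", {
  k <- karyotype_set("g", rep(3, 13), rep(3, 13))
  s <- karyotype_summary(k)
  expect_equal(s$TF_percent, 50)
  expect_equal(s$AsK_percent, 50)
  expect_equal(s$S_percent, 100)
  expect_equal(c(s$A, s$MCA, s$CVcl, s$CVci, s$A1, s$A2), rep(0, 6))
  expect_equal(s$CI, 0.5)
  expect_equal(s$stebbins, "1A")
})

test_that("summary indices equal an independent formula-by-formula oracle", {
  set.seed(77)
  for (i in 1:10) {
    rk <- random_karyotype(13)
    s <- karyotype_summary(rk)
    ref <- ref_karyotype_indices(rk$chromosomes$short_arm,
                                 rk$chromosomes$long_arm)
    for (nm in names(ref)) {
      expect_equal(s[[nm]], ref[[nm]], tolerance = 1e-12, info = nm)
    }
  }
})

test_that("pooled short-arm fraction fixes TF% and its complement AsK%", {
  k <- generate_karyotype(13, 108.47, tf_percent = 41.50, seed = 1)
  s <- karyotype_summary(k)
  expect_equal(s$TF_percent, 41.50, tolerance = 1e-9)
  expect_equal(s$AsK_percent, 58.50, tolerance = 1e-9)
})

test_that("summary invariants hold on random karyotypes", {
  set.seed(123)
  for (i in 1:50) {
    rk <- random_karyotype(sample(5:20, 1))
    s <- karyotype_summary(rk)
    expect_equal(s$TF_percent + s$AsK_percent, 100, tolerance = 1e-12)
    expect_equal(s$MCA, 100 * s$A, tolerance = 1e-12)
    expect_equal(s$A2, s$CVcl / 100, tolerance = 1e-12)
    expect_lte(s$TF_percent, 50)
    expect_true(s$A >= 0 && s$A <= 1)
    expect_true(s$A1 >= 0 && s$A1 < 1)
    expect_true(s$CI > 0 && s$CI <= 0.5)
  }
})

test_that("summary indices are scale- and permutation-invariant", {
  set.seed(9)
  rk <- random_karyotype(13)
  s1 <- karyotype_summary(rk)
  scaled <- karyotype_set("g", 3.7 * rk$chromosomes$short_arm,
                          3.7 * rk$chromosomes$long_arm)
  s2 <- karyotype_summary(scaled)
  expect_equal(s2$HCL, 3.7 * s1$HCL)
  inv <- c("TF_percent", "AsK_percent", "S_percent", "CI", "A", "MCA",
           "CVcl", "CVci", "A1", "A2", "stebbins", "formula")
  expect_equal(s2[inv], s1[inv])

  o <- sample(13)
  perm <- karyotype_set("g", rk$chromosomes$short_arm[o],
                        rk$chromosomes$long_arm[o])
  expect_equal(karyotype_summary(perm)[inv], s1[inv])
})

test_that("population-sd convention is available and smaller", {
  set.seed(2)
  rk <- random_karyotype(13)
  s_sam <- karyotype_summary(rk, sd_type = "sample")
  s_pop <- karyotype_summary(rk, sd_type = "population")
  expect_equal(s_pop$CVcl, s_sam$CVcl * sqrt(12 / 13), tolerance = 1e-12)
})

test_that("Stebbins category applies the length-ratio and arm-ratio rules", {
  # R = 1.95 < 2, 4/13 chromosomes with arm ratio > 2 -> "2A"
  lens <- c(rep(1, 9), rep(1.95, 4))
  s <- ifelse(seq_along(lens) <= 9, lens / 2, lens / 4)
  k <- karyotype_set("g", s, lens - s)
  expect_equal(stebbins_category(k), "2A")
  # same split, R = 2.5 -> "2B"
  lens2 <- c(rep(1, 9), rep(2.5, 4))
  s2 <- ifelse(seq_along(lens2) <= 9, lens2 / 2, lens2 / 4)
  expect_equal(stebbins_category(karyotype_set("g", s2, lens2 - s2)), "2B")
  # every chromosome asymmetric, huge length spread -> "4C"
  k4 <- karyotype_set("g", rep(1, 5), c(3, 4, 5, 6, 19))
  expect_equal(stebbins_category(k4), "4C")
})

test_that("ideogram coordinates are cumulative arm offsets", {
  one <- karyotype_set("g", 2, 3)
  t1 <- ideogram_table(one)
  expect_equal(c(t1$centromere, t1$end), c(2, 5))

  two <- karyotype_set("g", c(2, 3), c(3, 5))
  t2 <- ideogram_table(two, order = "by_length")
  expect_equal(t2$index, c(2, 1))  # 8-long chromosome drawn first
  expect_equal(t2$end, c(8, 5))
  t2b <- ideogram_table(two, order = "by_index")
  expect_equal(t2b$index, c(1, 2))

  set.seed(5)
  rk <- random_karyotype(13)
  tt <- ideogram_table(rk)
  expect_equal(tt$end, tt$short_arm + tt$long_arm)
  expect_true(all(diff(tt$end) <= 0))
})

test_that("ideogram SVG export writes a well-formed file", {
  path <- withr::local_tempfile(fileext = ".svg")
  write_ideogram_svg(karyotype_set("g", c(2, 3), c(3, 5)), path)
  svg <- readLines(path)
  expect_match(svg[1], "^<svg ")
  expect_equal(svg[length(svg)], "</svg>")
  expect_equal(sum(grepl("<rect", svg)), 4)  # two arms per chromosome
})
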