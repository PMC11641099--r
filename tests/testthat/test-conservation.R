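# Interval-map lifting and six-way conservation classification.

lm_row <- function(sc, ss, se, tc, ts, te, str = "+") {
  data.frame(src_chrom = sc, src_start = ss, src_end = se, tgt_chrom = tc,
             tgt_start = ts, tgt_end = te, tgt_strand = str,
             stringsAsFactors = FALSE)
}

test_that("lift_site applies identity, offset and strand-flip maps", {
  ident <- lm_row("chr1", 1L, 1000L, "chr1", 1L, 1000L)
  expect_equal(lift_site("chr1", 500L, ident)$pos, 500L)
  off <- lm_row("chr1", 100L, 200L, "chr5", 1100L, 1200L)
  expect_equal(lift_site("chr1", 150L, off),
               list(chrom = "chr5", pos = 1150L, strand = "+"))
  expect_null(lift_site("chr1", 99L, off))
  expect_null(lift_site("chr2", 150L, off))

  # strand flip: compare against a per-base enumerated mapping table
  flip <- lm_row("chr1", 100L, 120L, "chr9", 5000L, 5020L, "-")
  table_map <- setNames(5020L - (0:20), 100L + (0:20))
  set.seed(2)
  for (pos in sample(100:120, 10)) {
    expect_equal(lift_site("chr1", pos, flip)$pos,
                 unname(table_map[as.character(pos)]))
  }
})

test_that("category examples follow the six-way definitions", {
  # map covers only the start site -> the other site fails to lift
  partial <- lm_row("chr1", 10L, 10L, "chrm1", 110L, 110L)
  mouse <- data.frame(chrom = "chrm1", start = 110L, end = 910L, strand = "+",
                      stringsAsFactors = FALSE)
  key <- list(chrom = "chr1", start = 10L, end = 810L, strand = "+")
  expect_equal(classify_conservation(key, partial, mouse)$category, "not-aligned")

  # identity lift + mouse catalogue containing the same BSJ -> homologous
  ident <- lm_row("chr1", 1L, 2000L, "chrm1", 1L, 2000L)
  mouse2 <- data.frame(chrom = "chrm1", start = 10L, end = 810L, strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_conservation(key, ident, mouse2)$category, "homologous")

  # two different mouse circRNAs covering one site each -> both sites utilized
  mouse3 <- data.frame(chrom = "chrm1", start = c(9L, 500L), end = c(300L, 812L),
                       strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_conservation(key, ident, mouse3)$category,
               "both sites utilized")

  # single-site matches and the empty neighbourhood
  mouse5 <- data.frame(chrom = "chrm1", start = 11L, end = 300L, strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_conservation(key, ident, mouse5)$category,
               "5' site utilized")
  mouse6 <- data.frame(chrom = "chrm1", start = 500L, end = 809L, strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_conservation(key, ident, mouse6)$category,
               "3' site utilized")
  mouse7 <- data.frame(chrom = "chrm1", start = 400L, end = 500L, strand = "+",
                       stringsAsFactors = FALSE)
  expect_equal(classify_conservation(key, ident, mouse7)$category,
               "no homologous")

  # on the minus strand the 5' site is the end coordinate
  key_m <- list(chrom = "chr1", start = 10L, end = 810L, strand = "-")
  expect_equal(classify_conservation(key_m, ident, mouse5)$category,
               "3' site utilized")
})

test_that("classification matches the exhaustive brute-force classifier on planted truth", {
  b <- cached_bundle()
  cc <- classify_conservation_all(b$truth, b$liftmap, b$cat_mouse)
  expect_identical(cc$category, b$truth$cons_category)
  set.seed(6)
  idx <- sample(nrow(b$truth), 40)
  for (i in idx) {
    expect_equal(cc$category[i],
                 oracle_conservation(as.list(b$truth[i, c("chrom", "start", "end",
                                                          "strand")]),
                                     b$liftmap, b$cat_mouse))
  }
})

test_that("enlarging the window never demotes a homologous BSJ", {
  b <- cached_bundle()
  sub <- b$truth[1:80, ]
  prev <- classify_conservation_all(sub, b$liftmap, b$cat_mouse, window = 2)
  for (w in c(3, 5, 10)) {
    cur <- classify_conservation_all(sub, b$liftmap, b$cat_mouse, window = w)
    was_hom <- prev$category == "homologous"
    expect_true(all(cur$category[was_hom] == "homologous"))
    prev <- cur
  }
})

test_that("identity lift map with mouse catalogue = human calls gives all homologous", {
  b <- cached_bundle()
  sub <- b$truth[1:60, c("chrom", "start", "end", "strand")]
  ident <- do.call(rbind, lapply(unique(sub$chrom), function(ch) {
    lm_row(ch, 1L, 5000000L, ch, 1L, 5000000L)
  }))
  cc <- classify_conservation_all(sub, ident, sub)
  expect_true(all(cc$category == "homologous"))
})

test_that("conservation summary counts and percentages are exact", {
  calls <- data.frame(category = c("homologous", "no homologous", "not-aligned",
                                   "homologous"), stringsAsFactors = FALSE)
  s <- conservation_summary(calls)
  expect_equal(s$count[s$category == "homologous"], 2L)
  expect_equal(s$percent[s$category == "homologous"], 50)
  expect_lt(abs(sum(s$percent) - 100), 0.011)
  expect_equal(nrow(conservation_summary(calls[0, , drop = FALSE])), 0L)

  b <- cached_bundle()
  cc <- classify_conservation_all(b$truth, b$liftmap, b$cat_mouse)
  s_b <- conservation_summary(cc)
  truth_tab <- table(b$truth$cons_category)
  expect_identical(setNames(s_b$count, s_b$category)[names(truth_tab)],
                   setNames(as.integer(truth_tab), names(truth_tab)))
})
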