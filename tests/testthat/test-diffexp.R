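# Expression filter, normalization, PCA, NB Wald test, BH, set overlaps.

make_cm <- function(counts, libsize = rep(1e7, ncol(counts)),
                    condition = rep(c("control", "RPL"), each = ncol(counts) / 2),
                    project = "P1") {
  counts <- matrix(as.integer(counts), nrow = nrow(counts), ncol = ncol(counts))
  features <- data.frame(chrom = rep("chr1", nrow(counts)),
                         start = seq_len(nrow(counts)) * 10L,
                         end = seq_len(nrow(counts)) * 10L + 5L,
                         strand = rep("+", nrow(counts)),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(counts))),
                        project_id = project, condition = condition,
                        library_size = libsize, stringsAsFactors = FALSE)
  circ_counts(counts, features, samples)
}

test_that("expression filter implements the >=5-in-half-the-samples rule", {
  cm <- make_cm(rbind(c(5, 5, 5, 0, 0, 0), c(4, 4, 4, 4, 4, 4)))
  filt <- filter_expressed(cm)
  expect_equal(nrow(filt$counts), 1L)
  expect_equal(unname(filt$counts[1, ]), c(5L, 5L, 5L, 0L, 0L, 0L))

  # 9 samples: ceil(4.5) = 5 passing samples required — enumerate all cases
  for (npass in 0:9) {
    row <- c(rep(9, npass), rep(0, 9 - npass))
    cm9 <- make_cm(matrix(row, nrow = 1),
                   condition = rep(c("control", "RPL"), c(5, 4)))
    kept <- nrow(filter_expressed(cm9)$counts)
    expect_equal(kept, as.integer(npass >= 5))
  }
  # raising min_count never adds a row (monotonicity)
  set.seed(40)
  cm_r <- make_cm(matrix(rpois(200, 4), nrow = 20))
  prev <- rownames(filter_expressed(cm_r, min_count = 1)$counts)
  for (mc in 2:8) {
    cur <- rownames(filter_expressed(cm_r, min_count = mc)$counts)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # empty matrix passes through
  expect_equal(nrow(filter_expressed(make_cm(matrix(0L, 0, 6)))$counts), 0L)
})

test_that("library-size normalization and baseMean arithmetic", {
  cm <- make_cm(matrix(c(10L, 10L), nrow = 1), libsize = c(1e7, 1e7))
  nn <- normalize_counts(cm)
  expect_equal(unname(nn$normalized[1, 1]), 1e-6)
  expect_equal(unname(nn$size_factors), c(1e7, 1e7))

  cm2 <- make_cm(matrix(c(5L, 0L, 7L), nrow = 1), libsize = rep(1e7, 3),
                 condition = c("control", "control", "RPL"))
  expect_equal(mean(normalize_counts(cm2)$normalized[1, ]), 4.0e-7)

  cm0 <- make_cm(matrix(1L, 1, 2), libsize = c(0, 1e7),
                 condition = c("control", "RPL"))
  expect_error(normalize_counts(cm0), class = "circRPL_value_error")
})

test_that("PCA matches a dense eigen oracle and fixes ordering and sign", {
  set.seed(55)
  counts <- matrix(rpois(6 * 20, 40), nrow = 20)
  cm <- make_cm(counts, condition = rep(c("control", "RPL"), each = 3))
  res <- run_pca(cm, n_components = 2)
  # oracle: eigen-decomposition of the sample covariance of the transform
  X <- t(log2(sweep(counts, 2, cm$samples$library_size, "/") + 1e-7))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(Xc))
  for (j in 1:2) {
    sc_or <- Xc %*% eg$vectors[, j]
    got <- res$scores[[paste0("PC", j)]]
    expect_true(max(abs(got - sc_or)) < 1e-8 || max(abs(got + sc_or)) < 1e-8)
  }
  expect_true(all(diff(res$var_explained) <= 1e-12))
  expect_lte(sum(res$var_explained), 100 + 1e-9)

  # identical samples have identical scores
  cm_dup <- make_cm(cbind(counts[, 1], counts[, 1], counts[, 2], counts[, 3]),
                    condition = c("control", "control", "RPL", "RPL"))
  res2 <- run_pca(cm_dup, n_components = 2)
  expect_equal(res2$scores$PC1[1], res2$scores$PC1[2])
  expect_equal(res2$scores$PC2[1], res2$scores$PC2[2])

  expect_error(run_pca(make_cm(matrix(1L, 3, 2),
                               condition = c("control", "RPL")), 3),
               class = "circRPL_design_error")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "circRPL_value_error")
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("NB Wald test: null identity, label antisymmetry, permutation equivariance", {
  counts <- matrix(rep(c(8L, 12L, 9L, 8L, 12L, 9L), 3), nrow = 3, byrow = TRUE)
  cm <- make_cm(counts)
  de <- nb_wald_de(cm)
  expect_equal(de$log2FoldChange, rep(0, 3), tolerance = 1e-6)
  expect_true(all(de$pvalue > 0.99))

  set.seed(80)
  counts2 <- matrix(rnbinom(10 * 10, mu = 30, size = 5), nrow = 10)
  cond <- rep(c("control", "RPL"), each = 5)
  libs <- runif(10, 5e6, 2e7)
  cm2 <- make_cm(counts2, libsize = libs, condition = cond)
  de2 <- nb_wald_de(cm2)
  # swapping group labels negates every log2FC exactly
  cm_sw <- make_cm(counts2, libsize = libs,
                   condition = ifelse(cond == "RPL", "control", "RPL"))
  de_sw <- nb_wald_de(cm_sw)
  expect_equal(de_sw$log2FoldChange, -de2$log2FoldChange, tolerance = 1e-8)
  expect_equal(de_sw$pvalue, de2$pvalue, tolerance = 1e-8)
  # permuting samples together with labels changes nothing
  perm <- sample(10)
  cm_pm <- make_cm(counts2[, perm], libsize = libs[perm], condition = cond[perm])
  de_pm <- nb_wald_de(cm_pm)
  expect_equal(de_pm$log2FoldChange, de2$log2FoldChange, tolerance = 1e-8)
  expect_equal(de_pm$pvalue, de2$pvalue, tolerance = 1e-8)
})

test_that("NB Wald test handles zero rows, zero groups and bad designs", {
  counts <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 25L, 30L), c(9L, 11L, 10L, 12L))
  cm <- make_cm(counts)
  de <- nb_wald_de(cm)
  expect_equal(de$pvalue[1], 1)
  expect_equal(de$log2FoldChange[1], 0)
  expect_true(de$zero_flag[2])
  expect_true(is.finite(de$log2FoldChange[2]))
  expect_gt(de$log2FoldChange[2], 0)
  expect_true(all(de$padj >= de$pvalue - 1e-12))

  cm_bad <- make_cm(matrix(1L, 2, 3), condition = c("control", "RPL", "RPL"))
  expect_error(nb_wald_de(cm_bad), class = "circRPL_design_error")
  cm_lab <- make_cm(matrix(1L, 2, 4),
                    condition = c("a", "a", "b", "b"))
  expect_error(nb_wald_de(cm_lab), class = "circRPL_design_error")
})

test_that("significance uses strict padj and |lfc| cut-offs", {
  b <- cached_bundle()
  cm1 <- subset_project(b$counts, "PROJ1")
  de <- nb_wald_de(filter_expressed(cm1))
  expect_identical(de$significant,
                   de$padj < 0.05 & abs(de$log2FoldChange) > 0.58)
})

test_that("overlap region counts equal the membership-pattern tally", {
  ov <- cross_tissue_overlap(list(A = c("x", "y", "z"), B = c("u", "v")))
  expect_equal(ov$count[ov$region == "A"], 3L)
  expect_equal(ov$count[ov$region == "B"], 2L)
  expect_equal(ov$count[ov$region == "A&B"], 0L)

  same <- replicate(4, paste0("g", 1:7), simplify = FALSE)
  names(same) <- LETTERS[1:4]
  ov4 <- cross_tissue_overlap(same)
  expect_equal(ov4$count[ov4$region == "A&B&C&D"], 7L)
  expect_equal(sum(ov4$count), 7L)

  # randomized 4-set system against the 2^4 pattern oracle
  set.seed(60)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) sample(paste0("e", 1:40), sample(5:25, 1)))
    names(sets) <- LETTERS[1:4]
    ov_r <- cross_tissue_overlap(sets)
    universe <- unique(unlist(sets))
    pat <- vapply(universe, function(e) {
      paste(names(sets)[vapply(sets, function(s) e %in% s, TRUE)], collapse = "&")
    }, "")
    tab <- table(pat)
    for (r in seq_len(nrow(ov_r))) {
      expected <- if (ov_r$region[r] %in% names(tab))
        as.integer(tab[ov_r$region[r]]) else 0L
      expect_equal(ov_r$count[r], expected)
    }
    expect_equal(sum(ov_r$count), length(universe))
    expect_identical(shared_de(sets),
                     sort(universe[vapply(universe, function(e)
                       sum(vapply(sets, function(s) e %in% s, TRUE)) >= 2, TRUE)]))
  }
})
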