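# Expression filtering, library-size normalization, PCA, and the
# negative-binomial Wald differential-expression test (RPL vs control) with
# Benjamini-Hochberg correction.
#
# Model per circRNA i, sample j:
#   k_ij ~ NB(mu_ij, alpha_i),   mu_ij = s_j * q_i * 2^(beta_i * x_j)
# with s_j the total library size, x_j = 1 for RPL samples, alpha_i the
# dispersion (Var = mu + alpha*mu^2). The two group log-means are fitted by
# maximum likelihood (Newton, library-size offsets), alpha_i by the
# df-corrected Pearson moment equation, and the Wald statistic
# beta_hat / SE(beta_hat) is referred to a t distribution with n - 2 degrees
# of freedom (small-sample calibration; see the methods vignette).

#' Filter to expressed circRNAs
#'
#' Keeps circRNAs with at least `min_count` junction reads in at least
#' `ceil(min_fraction * n_samples)` samples of the project ("at least five
#' supporting reads in half of the samples" at the defaults).
#'
#' @param cm A `circ_counts` object for a single project.
#' @param min_count Minimum junction-read count (default 5).
#' @param min_fraction Minimum fraction of samples that must reach
#'   `min_count` (default 0.5); the sample threshold is
#'   `ceiling(min_fraction * n_samples)`.
#' @return The filtered `circ_counts` (row order preserved).
#' @export
filter_expressed <- function(cm, min_count = 5, min_fraction = 0.5) {
  n <- ncol(cm$counts)
  need <- ceiling(min_fraction * n)
  keep <- rowSums(cm$counts >= min_count) >= need
  circ_counts(cm$counts[keep, , drop = FALSE],
              cm$features[keep, , drop = FALSE], cm$samples)
}

#' Library-size normalization
#'
#' With `mode = "library_size"` (the default) the size factor of sample j is
#' its total library size, so normalized counts are counts per sequenced
#' read (typically 1e-7..1e-5 for circRNA junctions). An alternative
#' `"median_ratios"` mode computes DESeq-style median-of-ratios factors for
#' comparison.
#'
#' @param cm A `circ_counts` object.
#' @param mode `"library_size"` or `"median_ratios"`.
#' @return List: `normalized` (matrix), `size_factors` (named vector).
#' @export
normalize_counts <- function(cm, mode = c("library_size", "median_ratios")) {
  mode <- match.arg(mode)
  if (mode == "library_size") {
    s <- cm$samples$library_size
    if (any(s <= 0)) circ_stop("library size must be > 0", "circRPL_value_error")
  } else {
    logg <- rowMeans(log(cm$counts))
    use <- is.finite(logg)
    if (!any(use)) circ_stop("median-of-ratios: no feature with all-positive counts",
                             "circRPL_value_error")
    s <- apply(cm$counts[use, , drop = FALSE], 2, function(col) {
      exp(stats::median(log(col) - logg[use]))
    })
  }
  names(s) <- cm$samples$sample_id
  list(normalized = sweep(cm$counts, 2, s, "/"), size_factors = s)
}

# ---- NB Wald internals ----

# MLE of c in mu_j = s_j * exp(c) for fixed dispersion alpha (Newton).
# An all-zero group gets a 0.5 pseudo-count on the group total so the
# log-mean stays finite.
fit_group_logmean <- function(k, s, alpha) {
  if (sum(k) == 0) return(list(c = log(0.5 / sum(s)), pseudo = TRUE))
  c0 <- log(sum(k) / sum(s))
  for (it in 1:100) {
    mu <- s * exp(c0)
    g <- sum((k - mu) / (1 + alpha * mu))
    h <- -sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
    step <- g / h
    if (!is.finite(step)) break
    c0 <- c0 - step
    if (abs(step) < 1e-10) break
  }
  list(c = c0, pseudo = FALSE)
}

# Pearson moment-equation dispersion with df correction:
# solve sum (k-mu)^2 / (mu (1 + a mu)) = n - p  for a >= 0.
pearson_dispersion <- function(k, mu, df, floor = 1e-8) {
  mu <- pmax(mu, 1e-12)
  f <- function(a) sum((k - mu)^2 / (mu * (1 + a * mu))) - df
  if (df <= 0 || f(0) <= 0) return(floor)
  hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
  if (f(hi) > 0) return(hi)
  max(stats::uniroot(f, c(0, hi), tol = 1e-10)$root, floor)
}

#' Negative-binomial Wald differential expression
#'
#' Tests each circRNA for differential expression between RPL and control
#' samples under an NB model with library-size offsets (see the file-level
#' model note). Rows with all-zero counts are reported with p = 1, not
#' dropped; a group with all-zero counts gets a 0.5 pseudo-count on its
#' total so the log2 fold-change stays finite (flagged in `zero_flag`).
#' P-values are BH-adjusted over all tested circRNAs; a circRNA is
#' `significant` iff `padj < alpha_fdr` and `|log2FoldChange| > lfc_cut`
#' (strict inequalities).
#'
#' @param cm A filtered single-project `circ_counts` object.
#' @param condition Factor/character of conditions aligned to samples;
#'   defaults to the sample sheet's `condition` column. Must contain exactly
#'   `control` and `RPL`, each with >= 2 samples.
#' @param alpha_fdr Adjusted-p cut-off (default 0.05).
#' @param lfc_cut Absolute log2 fold-change cut-off (default 0.58).
#' @param disp_floor Lower bound on the dispersion estimate.
#' @return A `circ_de` data frame: `name, baseMean, log2FoldChange, lfcSE,
#'   stat, pvalue, padj, significant, zero_flag` (one row per circRNA, input
#'   order). `baseMean` is the mean of library-size-normalized counts.
#' @export
nb_wald_de <- function(cm, condition = cm$samples$condition,
                       alpha_fdr = 0.05, lfc_cut = 0.58, disp_floor = 1e-8) {
  condition <- as.character(condition)
  if (!setequal(unique(condition), c("control", "RPL"))) {
    circ_stop("condition must contain exactly 'control' and 'RPL'",
              "circRPL_design_error")
  }
  if (min(table(condition)) < 2) {
    circ_stop("each condition needs >= 2 samples", "circRPL_design_error")
  }
  counts <- cm$counts
  if (any(counts != round(counts))) {
    circ_stop("counts must be integers", "circRPL_value_error")
  }
  s <- cm$samples$library_size
  x <- as.integer(condition == "RPL")
  n <- length(x)
  nfeat <- nrow(counts)
  norm <- sweep(counts, 2, s, "/")
  baseMean <- rowMeans(norm)

  lfc <- se <- stat <- pval <- numeric(nfeat)
  zero_flag <- logical(nfeat)
  i0 <- x == 0; i1 <- x == 1
  s0 <- s[i0]; s1 <- s[i1]
  for (i in seq_len(nfeat)) {
    k <- as.numeric(counts[i, ])
    if (all(k == 0)) {
      lfc[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; pval[i] <- 1
      zero_flag[i] <- TRUE
      next
    }
    k0 <- k[i0]; k1 <- k[i1]
    q0 <- sum(k0) / sum(s0); q1 <- sum(k1) / sum(s1)
    mu_mom <- ifelse(i0, s * q0, s * q1)
    a <- pearson_dispersion(k, mu_mom, df = n - 2, floor = disp_floor)
    f0 <- fit_group_logmean(k0, s0, a)
    f1 <- fit_group_logmean(k1, s1, a)
    mu0 <- s0 * exp(f0$c); mu1 <- s1 * exp(f1$c)
    info0 <- sum(mu0 / (1 + a * mu0))
    info1 <- sum(mu1 / (1 + a * mu1))
    se_ln <- sqrt(1 / info0 + 1 / info1)
    b <- f1$c - f0$c
    z <- b / se_ln
    lfc[i] <- b / log(2)
    se[i] <- se_ln / log(2)
    stat[i] <- z
    pval[i] <- 2 * stats::pt(-abs(z), df = n - 2)
    zero_flag[i] <- f0$pseudo || f1$pseudo
  }
  padj <- bh_adjust(pval)
  res <- data.frame(
    name = rownames(counts),
    baseMean = baseMean,
    log2FoldChange = lfc,
    lfcSE = se,
    stat = stat,
    pvalue = pval,
    padj = padj,
    significant = padj < alpha_fdr & abs(lfc) > lfc_cut,
    zero_flag = zero_flag,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "alpha_fdr") <- alpha_fdr
  attr(res, "lfc_cut") <- lfc_cut
  attr(res, "n_control") <- sum(i0)
  attr(res, "n_rpl") <- sum(i1)
  class(res) <- c("circ_de", "data.frame")
  res
}

#' @export
print.circ_de <- function(x, ...) {
  cat(sprintf("NB Wald differential expression: %d circRNAs, %d control vs %d RPL\n",
              nrow(x), attr(x, "n_control"), attr(x, "n_rpl")))
  cat(sprintf("significant (padj < %g & |log2FC| > %g): %d\n",
              attr(x, "alpha_fdr"), attr(x, "lfc_cut"), sum(x$significant)))
  print.data.frame(utils::head(x[order(x$padj), ], 10), digits = 4)
  invisible(x)
}

#' @export
summary.circ_de <- function(object, ...) {
  out <- list(n = nrow(object),
              n_significant = sum(object$significant),
              n_up = sum(object$significant & object$log2FoldChange > 0),
              n_down = sum(object$significant & object$log2FoldChange < 0),
              alpha_fdr = attr(object, "alpha_fdr"),
              lfc_cut = attr(object, "lfc_cut"))
  class(out) <- "summary.circ_de"
  out
}

#' @export
print.summary.circ_de <- function(x, ...) {
  cat(sprintf("%d circRNAs tested; %d significant at padj < %g & |log2FC| > %g (%d up, %d down in RPL)\n",
              x$n, x$n_significant, x$alpha_fdr, x$lfc_cut, x$n_up, x$n_down))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input values must lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values (same order).
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    circ_stop("p-values must lie in [0, 1]", "circRPL_value_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Principal component analysis of samples
#'
#' PCA on `log2(normalized count + pseudocount)` over the supplied circRNAs
#' (typically the union of per-project expressed sets, with absent circRNAs
#' as zero counts). Scores are centered; components are ordered by variance
#' explained, and each component's sign is fixed so its largest-magnitude
#' feature loading is positive.
#'
#' @param cm A `circ_counts` object (all projects pooled).
#' @param n_components Number of components to return (default 2).
#' @param pseudocount Added before the log transform, on the normalized-count
#'   scale (default 1e-7, about one read in a 10M-read library).
#' @return List: `scores` (data frame `sample_id, project_id, condition,
#'   PC1..`), `var_explained` (percent per returned component), `loadings`.
#' @export
run_pca <- function(cm, n_components = 2, pseudocount = 1e-7) {
  if (ncol(cm$counts) < n_components) {
    circ_stop("fewer samples than requested components", "circRPL_design_error")
  }
  nrm <- normalize_counts(cm)$normalized
  X <- t(log2(nrm + pseudocount))      # samples x features
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 1)
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(sample_id = cm$samples$sample_id,
                    project_id = cm$samples$project_id,
                    condition = cm$samples$condition,
                    stringsAsFactors = FALSE)
  out[paste0("PC", seq_len(k))] <- as.data.frame(scores)
  list(scores = out, var_explained = ve[seq_len(k)], loadings = loadings)
}

#' Membership-pattern (Venn) region counts across projects
#'
#' @param sets Named list of character vectors (e.g. significant circRNA
#'   names per project).
#' @return Data frame `region, count`: one row per non-empty combination of
#'   set names (joined by "&"), counting elements belonging to exactly that
#'   combination. Region counts sum to the union size.
#' @export
cross_tissue_overlap <- function(sets) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  nm <- names(sets)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, nm))
  pat_of <- function(bits) paste(nm[bits], collapse = "&")
  combos <- unlist(lapply(seq_along(nm), function(k) {
    utils::combn(nm, k, FUN = function(v) paste(v, collapse = "&"))
  }))
  counts <- stats::setNames(integer(length(combos)), combos)
  if (length(universe)) {
    pats <- apply(memb, 1, pat_of)
    tab <- table(pats)
    counts[names(tab)] <- as.integer(tab)
  }
  data.frame(region = combos, count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' circRNAs significant in two or more projects
#'
#' @param sets Named list of significant circRNA identifier vectors.
#' @return Character vector of identifiers appearing in >= 2 sets, sorted.
#' @export
shared_de <- function(sets) {
  all_ids <- unlist(lapply(sets, unique))
  sort(unique(all_ids[duplicated(all_ids)]))
}
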