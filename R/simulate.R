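# Synthetic-data generator: builds, from a seed and a parameter block, every
# input the pipeline consumes — gene annotation, detector call files in both
# dialects, NB junction-count matrix, sample sheet, known/mouse catalogues,
# lift map and gene sets — together with a truth table planting detector
# overlap, expression, differential expression, conservation category and one
# enriched gene set.
#
# Two structural guarantees make planted truth exactly recoverable:
#   * every circRNA owns globally unique start and end positions, so each
#     back-splice site can be given a private lift target and catalogue
#     neighbourhood (category planting never cross-talks between circRNAs);
#   * coordinate jitter and detector dropout are mutually exclusive per
#     circRNA and affect exactly one detector, so expected intersection
#     membership is known in advance.

#' Simulation parameters
#'
#' Builds a validated parameter block for [simulate_world()]. Defaults
#' describe a small two-project case/control study with NB junction counts
#' (Var = mu + alpha*mu^2), two imperfect detectors and partially conserved
#' BSJs.
#'
#' @param seed Integer RNG seed; identical seed + params give byte-identical
#'   outputs.
#' @param n_genes Number of annotated genes.
#' @param exons_per_gene Integer range (length-2) of exon counts per gene.
#' @param n_circ Number of circRNAs.
#' @param frac_exonic,frac_intronic,frac_intergenic Class proportions
#'   (must sum to 1).
#' @param n_projects Number of projects (tissue proxies).
#' @param samples_per_group Samples per condition per project (>= 2).
#' @param mean_expression NB mean scale: expected junction reads at a
#'   typical library size (log-normal spread of sd 1 across circRNAs).
#' @param dispersion NB dispersion alpha; 0 gives Poisson counts.
#' @param frac_de Proportion of circRNAs differentially expressed.
#' @param lfc_de True |log2 fold-change| for DE circRNAs (sign random).
#' @param detector_dropout Probability a true BSJ is missed by exactly one
#'   detector.
#' @param coord_jitter Probability one detector reports one splice site
#'   shifted by 1 nt.
#' @param frac_known Proportion of circRNAs present in the known catalogue.
#' @param frac_conserved Proportion planted as "homologous" in mouse.
#' @param lift_fail_frac Proportion planted as "not-aligned" (site absent
#'   from the lift map).
#' @param library_size_range Length-2 range of total library sizes.
#' @param n_chroms Number of chromosomes.
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 500L,
                       exons_per_gene = c(3L, 8L),
                       n_circ = 300L,
                       frac_exonic = 0.7,
                       frac_intronic = 0.15,
                       frac_intergenic = 0.15,
                       n_projects = 2L,
                       samples_per_group = 5L,
                       mean_expression = 30,
                       dispersion = 0.2,
                       frac_de = 0.2,
                       lfc_de = 1.0,
                       detector_dropout = 0.05,
                       coord_jitter = 0.02,
                       frac_known = 0.6,
                       frac_conserved = 0.45,
                       lift_fail_frac = 0.1,
                       library_size_range = c(5e6, 2e7),
                       n_chroms = 5L) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            exons_per_gene = as.integer(exons_per_gene),
            n_circ = as.integer(n_circ), frac_exonic = frac_exonic,
            frac_intronic = frac_intronic, frac_intergenic = frac_intergenic,
            n_projects = as.integer(n_projects),
            samples_per_group = as.integer(samples_per_group),
            mean_expression = mean_expression, dispersion = dispersion,
            frac_de = frac_de, lfc_de = lfc_de,
            detector_dropout = detector_dropout, coord_jitter = coord_jitter,
            frac_known = frac_known, frac_conserved = frac_conserved,
            lift_fail_frac = lift_fail_frac,
            library_size_range = as.numeric(library_size_range),
            n_chroms = as.integer(n_chroms))
  fracs <- c(p$frac_exonic, p$frac_intronic, p$frac_intergenic, p$frac_de,
             p$detector_dropout, p$coord_jitter, p$frac_known,
             p$frac_conserved, p$lift_fail_frac)
  if (any(fracs < 0 | fracs > 1)) {
    circ_stop("all proportions must lie in [0, 1]", "circRPL_parameter_error")
  }
  if (abs(p$frac_exonic + p$frac_intronic + p$frac_intergenic - 1) > 1e-9) {
    circ_stop("class proportions must sum to 1", "circRPL_parameter_error")
  }
  if (p$frac_conserved + p$lift_fail_frac > 1) {
    circ_stop("frac_conserved + lift_fail_frac must be <= 1",
              "circRPL_parameter_error")
  }
  if (p$samples_per_group < 2 || p$n_projects < 1) {
    circ_stop("need >= 2 samples per group and >= 1 project",
              "circRPL_parameter_error")
  }
  if (p$dispersion < 0 || p$mean_expression <= 0) {
    circ_stop("dispersion must be >= 0 and mean_expression > 0",
              "circRPL_parameter_error")
  }
  if (any(p$library_size_range <= 0) || length(p$library_size_range) != 2) {
    circ_stop("library_size_range must be two positive numbers",
              "circRPL_parameter_error")
  }
  class(p) <- "sim_params"
  p
}

# split the non-homologous, lifted mass among the remaining four categories
CONS_REMAINDER_SPLIT <- c("no homologous" = 0.55, "5' site utilized" = 0.15,
                          "3' site utilized" = 0.15, "both sites utilized" = 0.15)

#' Generate a complete synthetic study
#'
#' Writes every pipeline input under `dir` and returns an in-memory bundle
#' with the planted truth table. See the package vignette for what the
#' generator does and does not emulate.
#'
#' @param params A `sim_params` block.
#' @param dir Output directory (created; files are overwritten).
#' @return A `synthetic_bundle` list: `params`, `dir`, `paths` (named file
#'   paths), `truth` (per-circRNA truth table), `genes`, `exons`, `samples`,
#'   `counts` (a `circ_counts`), `gene_sets`, `background`, `enriched_set`.
#' @export
simulate_world <- function(params, dir) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(p$seed)

  ## ---- genome and annotation ----
  chroms <- paste0("chr", seq_len(p$n_chroms))
  gene_chrom <- chroms[((seq_len(p$n_genes) - 1L) %% p$n_chroms) + 1L]
  cursor <- stats::setNames(rep(10000L, p$n_chroms), chroms)
  genes <- data.frame(gene_name = sprintf("GENE%04d", seq_len(p$n_genes)),
                      chrom = gene_chrom,
                      strand = sample(c("+", "-"), p$n_genes, replace = TRUE),
                      start = 0L, end = 0L, stringsAsFactors = FALSE)
  exon_list <- vector("list", p$n_genes)
  for (i in seq_len(p$n_genes)) {
    chr <- genes$chrom[i]
    gstart <- cursor[chr] + sample(3000:8000, 1)
    n_ex <- sample(p$exons_per_gene[1]:p$exons_per_gene[2], 1)
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE) else integer(0)
    starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len - 1L
    genes$start[i] <- gstart
    genes$end[i] <- ends[n_ex]
    cursor[chr] <- ends[n_ex]
    exon_list[[i]] <- data.frame(gene_name = genes$gene_name[i],
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_list)

  ## ---- circRNA placement (globally unique splice positions) ----
  n_ex_c <- round(p$frac_exonic * p$n_circ)
  n_in_c <- round(p$frac_intronic * p$n_circ)
  n_ig_c <- p$n_circ - n_ex_c - n_in_c
  used <- new.env(hash = TRUE, parent = emptyenv())
  site_free <- function(chr, pos) is.null(used[[paste0(chr, ":", pos)]])
  site_take <- function(chr, pos) used[[paste0(chr, ":", pos)]] <- TRUE

  truth <- data.frame(circ_id = sprintf("CIRC%05d", seq_len(p$n_circ)),
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      class = rep(c("exonic", "intronic", "intergenic"),
                                  c(n_ex_c, n_in_c, n_ig_c)),
                      host_gene = NA_character_, stringsAsFactors = FALSE)

  multi_exon <- which(vapply(exon_list, nrow, 1L) >= 2)
  place_fail <- function() {
    circ_stop("n_circ exceeds placeable loci for this genome",
              "circRPL_parameter_error")
  }
  for (i in seq_len(p$n_circ)) {
    ok <- FALSE
    for (attempt in 1:200) {
      if (truth$class[i] == "exonic") {
        g <- sample.int(p$n_genes, 1)
        ex <- exon_list[[g]]
        a <- sample.int(nrow(ex), 1)
        b <- if (a == nrow(ex)) a else sample(a:nrow(ex), 1)
        chr <- genes$chrom[g]; s <- ex$start[a]; e <- ex$end[b]
        host <- genes$gene_name[g]
      } else if (truth$class[i] == "intronic") {
        if (!length(multi_exon)) place_fail()
        g <- if (length(multi_exon) == 1) multi_exon else sample(multi_exon, 1)
        ex <- exon_list[[g]]
        iv <- sample.int(nrow(ex) - 1, 1)
        lo <- ex$end[iv] + 6L          # 5 nt margin from exon boundaries
        hi <- ex$start[iv + 1] - 6L
        if (hi - lo < 40) next
        chr <- genes$chrom[g]
        s <- sample(lo:(hi - 30L), 1)
        e <- sample((s + 20L):hi, 1)
        host <- genes$gene_name[g]
      } else {
        chr <- sample(chroms, 1)
        gsub_ <- genes[genes$chrom == chr, , drop = FALSE]
        gaps_lo <- c(100L, gsub_$end + 11L)
        gaps_hi <- c(gsub_$start - 11L, max(gsub_$end) + 50000L)
        wide <- which(gaps_hi - gaps_lo > 500)
        if (!length(wide)) next
        w <- if (length(wide) == 1) wide else sample(wide, 1)
        s <- sample(gaps_lo[w]:(gaps_hi[w] - 200L), 1)
        e <- sample((s + 50L):min(s + 2000L, gaps_hi[w]), 1)
        host <- NA_character_
      }
      if (s < e && site_free(chr, s) && site_free(chr, e)) {
        site_take(chr, s); site_take(chr, e)
        truth$chrom[i] <- chr; truth$start[i] <- s; truth$end[i] <- e
        truth$host_gene[i] <- host
        truth$strand[i] <- if (is.na(host)) sample(c("+", "-"), 1) else
          genes$strand[match(host, genes$gene_name)]
        ok <- TRUE
        break
      }
    }
    if (!ok) place_fail()
  }

  ## ---- planted truth flags ----
  truth$known <- stats::runif(p$n_circ) < p$frac_known
  truth$de <- stats::runif(p$n_circ) < p$frac_de
  truth$lfc <- ifelse(truth$de, sample(c(-1, 1), p$n_circ, replace = TRUE) * p$lfc_de, 0)
  rem <- max(1 - p$lift_fail_frac - p$frac_conserved, 0)
  cat_probs <- c("not-aligned" = p$lift_fail_frac,
                 "homologous" = p$frac_conserved,
                 CONS_REMAINDER_SPLIT * rem)
  truth$cons_category <- sample(names(cat_probs), p$n_circ, replace = TRUE,
                                prob = cat_probs)
  dropped <- stats::runif(p$n_circ) < p$detector_dropout
  drop_det <- ifelse(dropped, sample(c("DCC", "CIRI2"), p$n_circ, replace = TRUE),
                     NA_character_)
  jit <- !dropped & stats::runif(p$n_circ) < p$coord_jitter
  jit_det <- ifelse(jit, sample(c("DCC", "CIRI2"), p$n_circ, replace = TRUE),
                    NA_character_)
  jit_site <- ifelse(jit, sample(c("start", "end"), p$n_circ, replace = TRUE),
                     NA_character_)
  jit_delta <- ifelse(jit, sample(c(-1L, 1L), p$n_circ, replace = TRUE), 0L)
  truth$dcc_detected <- !(dropped & drop_det == "DCC")
  truth$ciri_detected <- !(dropped & drop_det == "CIRI2")
  truth$dcc_detected[is.na(truth$dcc_detected)] <- TRUE
  truth$ciri_detected[is.na(truth$ciri_detected)] <- TRUE
  truth$jittered <- jit
  truth$in_intersection <- !dropped & !jit

  ## ---- samples and counts ----
  projects <- sprintf("PROJ%d", seq_len(p$n_projects))
  samples <- do.call(rbind, lapply(projects, function(pr) {
    data.frame(sample_id = c(sprintf("%s_ctrl_%d", pr, seq_len(p$samples_per_group)),
                             sprintf("%s_rpl_%d", pr, seq_len(p$samples_per_group))),
               project_id = pr,
               condition = rep(c("control", "RPL"), each = p$samples_per_group),
               stringsAsFactors = FALSE)
  }))
  samples$library_size <- round(stats::runif(nrow(samples),
                                             p$library_size_range[1],
                                             p$library_size_range[2]))
  s_ref <- mean(p$library_size_range)
  truth$q <- p$mean_expression * exp(stats::rnorm(p$n_circ, 0, 1)) / s_ref
  is_rpl <- samples$condition == "RPL"
  mu <- outer(truth$q, samples$library_size) *
    2^(outer(truth$lfc, as.numeric(is_rpl)))
  counts <- matrix(0L, p$n_circ, nrow(samples))
  nvals <- length(mu)
  counts[] <- if (p$dispersion == 0) {
    stats::rpois(nvals, lambda = mu)
  } else {
    stats::rnbinom(nvals, mu = mu, size = 1 / p$dispersion)
  }
  cm <- circ_counts(counts,
                    truth[, c("chrom", "start", "end", "strand")],
                    samples)

  ## ---- detector call tables (with jitter applied) ----
  det_coords <- function(det) {
    sel <- if (det == "DCC") truth$dcc_detected else truth$ciri_detected
    kk <- truth[sel, c("circ_id", "chrom", "start", "end", "strand", "class"),
                drop = FALSE]
    tweak <- which(jit[sel] & jit_det[sel] == det)
    for (t in tweak) {
      if (jit_site[sel][t] == "start") {
        kk$start[t] <- kk$start[t] + jit_delta[sel][t]
      } else {
        kk$end[t] <- kk$end[t] + jit_delta[sel][t]
      }
    }
    kk
  }
  long_calls <- function(kk, det) {
    n_s <- nrow(samples)
    idx <- match(kk$circ_id, truth$circ_id)
    data.frame(chrom = rep(kk$chrom, n_s),
               start = rep(kk$start, n_s),
               end = rep(kk$end, n_s),
               strand = rep(kk$strand, n_s),
               sample = rep(samples$sample_id, each = nrow(kk)),
               count = as.integer(counts[idx, , drop = FALSE]),
               detector = det,
               circ_type = rep(c(exonic = "exon", intronic = "intron",
                                 intergenic = "intergenic_region")[kk$class], n_s),
               stringsAsFactors = FALSE)
  }
  dcc_calls <- long_calls(det_coords("DCC"), "DCC")
  ciri_calls <- long_calls(det_coords("CIRI2"), "CIRI2")

  ## ---- known catalogue (planted knowns + decoys) ----
  decoy_n <- 50L
  decoys <- data.frame(chrom = "chrU",
                       start = 1000L + 100L * seq_len(decoy_n),
                       end = 1050L + 100L * seq_len(decoy_n),
                       strand = "+", stringsAsFactors = FALSE)
  cat_human <- rbind(truth[truth$known, c("chrom", "start", "end", "strand")],
                     decoys)

  ## ---- conservation planting: lift map and mouse catalogue ----
  lm_rows <- list(); mc_rows <- list()
  w <- 2L
  for (i in seq_len(p$n_circ)) {
    B <- 1000000L + (i - 1L) * 5000L
    st <- split_sites(truth$chrom[i], truth$start[i], truth$end[i], truth$strand[i])
    L5 <- B + 10L; L3 <- B + 1010L
    cat5 <- truth$cons_category[i]
    lift5 <- TRUE; lift3 <- TRUE
    if (cat5 == "not-aligned") {
      fail <- sample(c("5", "3", "both"), 1)
      lift5 <- fail == "3"
      lift3 <- fail == "5"
    }
    if (lift5) lm_rows[[length(lm_rows) + 1L]] <-
      data.frame(src_chrom = truth$chrom[i], src_start = st$p5, src_end = st$p5,
                 tgt_chrom = "chrm1", tgt_start = L5, tgt_end = L5,
                 tgt_strand = "+", stringsAsFactors = FALSE)
    if (lift3) lm_rows[[length(lm_rows) + 1L]] <-
      data.frame(src_chrom = truth$chrom[i], src_start = st$p3, src_end = st$p3,
                 tgt_chrom = "chrm1", tgt_start = L3, tgt_end = L3,
                 tgt_strand = "+", stringsAsFactors = FALSE)
    d5 <- sample((-w):w, 1); d3 <- sample((-w):w, 1)
    add_mouse <- function(a, b) mc_rows[[length(mc_rows) + 1L]] <<-
      data.frame(chrom = "chrm1", start = min(a, b), end = max(a, b),
                 strand = "+", stringsAsFactors = FALSE)
    if (cat5 == "homologous") {
      add_mouse(L5 + d5, L3 + d3)
    } else if (cat5 == "5' site utilized") {
      add_mouse(L5 + d5, L5 + 600L)
    } else if (cat5 == "3' site utilized") {
      add_mouse(L3 - 600L, L3 + d3)
    } else if (cat5 == "both sites utilized") {
      add_mouse(L5 + d5, L5 + 600L)
      add_mouse(L3 - 600L, L3 + d3)
    } else if (cat5 == "no homologous") {
      add_mouse(B + 300L, B + 700L)   # decoy far from both sites
    }
  }
  liftmap <- validate_liftmap(do.call(rbind, lm_rows))
  cat_mouse <- do.call(rbind, mc_rows)

  ## ---- gene sets: one enriched by construction ----
  all_genes <- genes$gene_name
  host_genes <- unique(truth$host_gene[!is.na(truth$host_gene)])
  s_med <- stats::median(samples$library_size)
  expressed_hosts <- unique(truth$host_gene[
    !is.na(truth$host_gene) & truth$q * s_med >= 10 & truth$in_intersection])
  non_hosts <- setdiff(all_genes, host_genes)
  n_h <- min(length(expressed_hosts), 32L)
  n_nh <- min(length(non_hosts), max(1L, round(n_h / 4)))
  enriched <- c(sample(expressed_hosts, n_h), sample(non_hosts, n_nh))
  gene_sets <- list(SET_ENRICHED = sort(enriched))
  for (j in 1:15) {
    gene_sets[[sprintf("SET_RND%02d", j)]] <-
      sort(sample(all_genes, sample(10:60, 1)))
  }

  ## ---- write everything ----
  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    samples = file.path(dir, "samples.tsv"),
    counts = file.path(dir, "counts.tsv"),
    dcc_counts = file.path(dir, "dcc", "CircRNACount.tsv"),
    dcc_coords = file.path(dir, "dcc", "CircCoordinates.tsv"),
    ciri_dir = file.path(dir, "ciri2"),
    catalogue_human = file.path(dir, "catalogue_human.tsv"),
    catalogue_mouse = file.path(dir, "catalogue_mouse.tsv"),
    liftmap = file.path(dir, "liftmap.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    background = file.path(dir, "background.tsv"),
    truth = file.path(dir, "truth_table.tsv"),
    params = file.path(dir, "params.yaml"))
  dir.create(file.path(dir, "dcc"), showWarnings = FALSE)
  write_gtf(genes, exons, paths$gtf)
  write_samplesheet(samples, paths$samples)
  write_counts(cm, paths$counts)
  write_dcc_calls(dcc_calls, paths$dcc_counts, paths$dcc_coords,
                  samples = samples$sample_id)
  write_ciri2_calls(ciri_calls, paths$ciri_dir)
  write_catalogue(cat_human, paths$catalogue_human)
  write_catalogue(cat_mouse, paths$catalogue_mouse)
  write_liftmap(liftmap, paths$liftmap)
  write_gmt(gene_sets, paths$gmt,
            descriptions = stats::setNames(rep("synthetic", length(gene_sets)),
                                           names(gene_sets)))
  write_tsv_plain(data.frame(gene = sort(all_genes), stringsAsFactors = FALSE),
                  paths$background)
  tt <- truth
  tt$host_gene <- ifelse(is.na(tt$host_gene), ".", tt$host_gene)
  write_tsv_plain(tt, paths$truth)
  yaml::write_yaml(unclass(p), paths$params)

  structure(list(params = p, dir = dir, paths = paths, truth = truth,
                 genes = genes, exons = exons, samples = samples, counts = cm,
                 gene_sets = gene_sets, background = sort(all_genes),
                 enriched_set = "SET_ENRICHED",
                 dcc_calls = dcc_calls, ciri_calls = ciri_calls,
                 liftmap = liftmap, cat_mouse = cat_mouse,
                 cat_human = cat_human),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic_bundle: %d circRNAs, %d genes, %d samples in %d project(s) [seed %d]\n",
              nrow(x$truth), nrow(x$genes), nrow(x$samples),
              x$params$n_projects, x$params$seed))
  invisible(x)
}

#' Empirical moment check of simulated counts
#'
#' Recomputes each circRNA's expected count per sample from the truth table
#' and compares the observed sample mean: a well-behaved generator keeps the
#' observed mean within 3 standard errors of its expectation for almost all
#' circRNAs.
#'
#' @param bundle A `synthetic_bundle`.
#' @return Data frame per circRNA: `circ_id, mean_count, expected_mean,
#'   var_count, se_mean, z, within_3se`.
#' @export
empirical_moments <- function(bundle) {
  p <- bundle$params
  truth <- bundle$truth
  samples <- bundle$samples
  counts <- bundle$counts$counts
  is_rpl <- samples$condition == "RPL"
  mu <- outer(truth$q, samples$library_size) *
    2^(outer(truth$lfc, as.numeric(is_rpl)))
  v <- mu + p$dispersion * mu^2
  n <- ncol(counts)
  se <- sqrt(rowSums(v)) / n
  mean_count <- rowMeans(counts)
  expected <- rowMeans(mu)
  z <- ifelse(se > 0, (mean_count - expected) / se, 0)
  data.frame(circ_id = truth$circ_id, mean_count = mean_count,
             expected_mean = expected,
             var_count = apply(counts, 1, stats::var),
             se_mean = se, z = z, within_3se = abs(z) <= 3,
             stringsAsFactors = FALSE)
}
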