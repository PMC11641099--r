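# End-to-end orchestration: harmonize -> annotate -> conserve -> per-project
# filter/DE/ORA -> pooled PCA -> cross-project overlap -> report. All outputs
# are plain TSV; a rerun on the same inputs is byte-identical.

PIPELINE_DEFAULTS <- list(min_count = 5, min_fraction = 0.5, window = 2,
                          alpha_fdr = 0.05, lfc_cut = 0.58, min_size = 5,
                          max_size = 400, match_strand = TRUE,
                          jaccard_cut = 0.5, tol = 2, prefix = "hsa",
                          n_components = 2, pseudocount = 1e-7)

#' Read and validate a run configuration
#'
#' YAML with an `inputs:` block (paths: `dcc_counts, dcc_coords, ciri_dir,
#' counts, samples, gtf, catalogue_human, catalogue_mouse, liftmap, gmt,
#' background`), an optional `params:` block overriding stage parameters
#' (see `PIPELINE_DEFAULTS`), and `outdir`. Every referenced input path must
#' exist.
#'
#' @param path YAML path, or an equivalent list.
#' @return Validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  need <- c("dcc_counts", "dcc_coords", "ciri_dir", "counts", "samples",
            "gtf", "catalogue_human", "catalogue_mouse", "liftmap", "gmt",
            "background")
  missing <- setdiff(need, names(cfg$inputs))
  if (length(missing)) {
    circ_stop(sprintf("config: missing input path(s): %s",
                      paste(missing, collapse = ", ")), "circRPL_config_error")
  }
  for (nm in need) {
    pth <- cfg$inputs[[nm]]
    if (!file.exists(pth) && !dir.exists(pth)) {
      circ_stop(sprintf("config: input '%s' does not exist: %s", nm, pth),
                "circRPL_config_error")
    }
  }
  if (is.null(cfg$outdir)) {
    circ_stop("config: outdir is required", "circRPL_config_error")
  }
  prm <- PIPELINE_DEFAULTS
  prm[names(cfg$params)] <- cfg$params
  cfg$params <- prm
  cfg
}

#' Write a bundle's run configuration
#'
#' Convenience: builds a config list pointing at a [simulate_world()]
#' bundle's files.
#'
#' @param bundle A `synthetic_bundle`.
#' @param outdir Pipeline output directory.
#' @param params Optional stage-parameter overrides.
#' @return Config list suitable for [run_pipeline()].
#' @export
bundle_config <- function(bundle, outdir, params = list()) {
  list(inputs = list(dcc_counts = bundle$paths$dcc_counts,
                     dcc_coords = bundle$paths$dcc_coords,
                     ciri_dir = bundle$paths$ciri_dir,
                     counts = bundle$paths$counts,
                     samples = bundle$paths$samples,
                     gtf = bundle$paths$gtf,
                     catalogue_human = bundle$paths$catalogue_human,
                     catalogue_mouse = bundle$paths$catalogue_mouse,
                     liftmap = bundle$paths$liftmap,
                     gmt = bundle$paths$gmt,
                     background = bundle$paths$background),
       params = params, outdir = outdir)
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline
#'
#' Executes harmonize -> annotate -> conserve -> per-project filter + DE +
#' ORA -> pooled PCA -> cross-project overlap -> report, writing every
#' intermediate table under `config$outdir`. Logs go to stderr; tables carry
#' no timestamps, so a rerun on the same inputs is byte-identical.
#'
#' @param config Config list or YAML path (see [read_run_config()]).
#' @return Invisibly, a list with the main in-memory results: `records`,
#'   `conservation`, `de` (per project), `ora` (per project), `pca`,
#'   `overlap`, `report`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  prm <- cfg$params
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(outdir, paste0(...))

  samples <- stage("load", {
    read_samplesheet(cfg$inputs$samples)
  })
  cons <- stage("harmonize", {
    dcc <- collapse_duplicates(read_dcc_calls(cfg$inputs$dcc_counts,
                                              cfg$inputs$dcc_coords))
    ciri <- collapse_duplicates(read_ciri2_calls(cfg$inputs$ciri_dir))
    cm <- read_counts(cfg$inputs$counts, samples)
    attach_counts(intersect_calls(dcc, ciri, match_strand = prm$match_strand), cm)
  })
  records <- stage("annotate", {
    ann <- read_gtf(cfg$inputs$gtf)
    cat_h <- read_catalogue(cfg$inputs$catalogue_human)
    rec <- annotate_circs(cons, ann, cat_h, tol = prm$tol, prefix = prm$prefix)
    write_circ_records(rec, out("circ_records.tsv"))
    rec
  })
  conservation <- stage("conserve", {
    liftmap <- read_liftmap(cfg$inputs$liftmap)
    cat_m <- read_catalogue(cfg$inputs$catalogue_mouse)
    cc <- classify_conservation_all(records, liftmap, cat_m, window = prm$window)
    write_tsv_plain(data.frame(name = cc$name, lifted_5p = cc$lifted_5p,
                               lifted_3p = cc$lifted_3p, category = cc$category,
                               stringsAsFactors = FALSE), out("conservation.tsv"))
    write_tsv_plain(conservation_summary(cc), out("conservation_summary.tsv"))
    cc
  })

  # consolidated counts as a circ_counts object
  cm_cons <- circ_counts(cons$counts, cons$keys, cons$samples)
  key2name <- stats::setNames(records$name,
                              bsj_id(records$chrom, records$start,
                                     records$end, records$strand))
  gene_sets <- read_gmt(cfg$inputs$gmt)
  background <- utils::read.delim(cfg$inputs$background,
                                  stringsAsFactors = FALSE)$gene
  projects <- unique(samples$project_id)

  de_list <- list(); ora_list <- list(); expressed_keys <- list()
  report_rows <- list()
  for (proj in projects) {
    res <- stage(paste0("de:", proj), {
      sub <- subset_project(cm_cons, proj)
      filt <- filter_expressed(sub, min_count = prm$min_count,
                               min_fraction = prm$min_fraction)
      de <- nb_wald_de(filt, alpha_fdr = prm$alpha_fdr, lfc_cut = prm$lfc_cut)
      de$name <- unname(key2name[de$name])
      df <- as.data.frame(de)
      write_tsv_plain(df, out("de_", proj, ".tsv"))
      list(filt = filt, de = de)
    })
    ora_res <- stage(paste0("enrich:", proj), {
      fid <- rownames(res$filt$counts)
      hosts <- unique(stats::na.omit(
        records$host_gene[match(fid, bsj_id(records$chrom, records$start,
                                            records$end, records$strand))]))
      o <- ora(hosts, gene_sets, background,
               min_size = prm$min_size, max_size = prm$max_size)
      write_tsv_plain(o, out("ora_", proj, ".tsv"))
      cl <- cluster_terms(o, gene_sets, background,
                          jaccard_cut = prm$jaccard_cut, alpha = prm$alpha_fdr)
      write_tsv_plain(cl, out("clusters_", proj, ".tsv"))
      o
    })
    de_list[[proj]] <- res$de
    ora_list[[proj]] <- ora_res
    expressed_keys[[proj]] <- rownames(res$filt$counts)
    report_rows[[proj]] <- data.frame(
      project = proj,
      n_control = sum(samples$project_id == proj & samples$condition == "control"),
      n_rpl = sum(samples$project_id == proj & samples$condition == "RPL"),
      detected_circRNAs = nrow(res$filt$counts),
      de_circRNAs = sum(res$de$significant),
      stringsAsFactors = FALSE)
  }

  pca <- stage("pca", {
    union_keys <- sort(unique(unlist(expressed_keys)))
    if (length(union_keys) >= 2) {
      idx <- match(union_keys, rownames(cm_cons$counts))
      cm_u <- circ_counts(cm_cons$counts[idx, , drop = FALSE],
                          cm_cons$features[idx, , drop = FALSE],
                          cm_cons$samples)
      pp <- run_pca(cm_u, n_components = min(prm$n_components, ncol(cm_u$counts)),
                    pseudocount = prm$pseudocount)
      write_tsv_plain(pp$scores, out("pca_scores.tsv"))
      pp
    } else NULL
  })

  overlap <- stage("overlap", {
    sig_sets <- lapply(de_list, function(d) d$name[d$significant])
    ov <- cross_tissue_overlap(sig_sets)
    write_tsv_plain(ov, out("overlap_regions.tsv"))
    shared <- shared_de(sig_sets)
    write_tsv_plain(data.frame(name = shared, stringsAsFactors = FALSE),
                    out("shared_de.tsv"))
    ov
  })

  report <- stage("report", {
    rep_df <- do.call(rbind, report_rows)
    rownames(rep_df) <- NULL
    write_tsv_plain(rep_df, out("report.tsv"))
    top <- do.call(rbind, lapply(projects, function(proj) {
      d <- de_list[[proj]]
      d <- d[d$significant, , drop = FALSE]
      d <- d[order(d$padj, d$name), , drop = FALSE]
      d <- utils::head(d, 10)
      if (!nrow(d)) return(NULL)
      cbind(data.frame(tissue = proj, stringsAsFactors = FALSE),
            as.data.frame(d)[, c("name", "baseMean", "log2FoldChange",
                                 "lfcSE", "stat", "pvalue", "padj")])
    }))
    if (is.null(top)) {
      top <- data.frame(tissue = character(), name = character(),
                        baseMean = numeric(), log2FoldChange = numeric(),
                        lfcSE = numeric(), stat = numeric(),
                        pvalue = numeric(), padj = numeric(),
                        stringsAsFactors = FALSE)
    }
    write_tsv_plain(top, out("top_de.tsv"))
    yaml::write_yaml(cfg["params"], out("params_echo.yaml"))
    rep_df
  })

  invisible(list(records = records, conservation = conservation, de = de_list,
                 ora = ora_list, pca = pca, overlap = overlap, report = report))
}
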