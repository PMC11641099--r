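# Locus classification (exonic / intronic / intergenic) against the gene
# annotation, standardized circRNA nomenclature, and per-gene / per-chromosome
# summaries.

#' Classify circRNAs against a gene annotation
#'
#' A BSJ is *exonic* when both termini fall within `tol` nt of annotated exon
#' boundaries (start terminus near an exon start — the back-splice acceptor —
#' and end terminus near an exon end — the donor) of one gene; *intronic*
#' when its whole span lies inside a single intron of one gene; *intergenic*
#' when the span overlaps no gene body. A span that overlaps a gene but fits
#' neither pattern defaults to exonic with the best-overlapping gene.
#' Host-gene ties break by (a) largest overlap fraction, (b) alphabetical
#' gene name. The +/-2 nt boundary tolerance absorbs detector wobble at
#' splice sites.
#'
#' @param keys Data frame with `chrom, start, end, strand` (one row per BSJ).
#' @param ann An `annotation_index` from [read_gtf()].
#' @param tol Boundary tolerance in nt (default 2).
#' @return Data frame with columns `circ_class` and `host_gene` (NA for
#'   intergenic), aligned to `keys` rows.
#' @export
classify_circs <- function(keys, ann, tol = 2) {
  spans <- GenomicRanges::GRanges(keys$chrom,
                                  IRanges::IRanges(keys$start, keys$end))
  ov <- GenomicRanges::findOverlaps(spans, ann$genes, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  gene_names <- ann$genes$gene_name
  ex_gene <- ann$exons$gene_name
  ex_start <- GenomicRanges::start(ann$exons)
  ex_end <- GenomicRanges::end(ann$exons)

  n <- nrow(keys)
  cls <- rep("intergenic", n)
  host <- rep(NA_character_, n)

  for (i in unique(qh)) {
    gidx <- sh[qh == i]
    s <- keys$start[i]; e <- keys$end[i]
    cand_exonic <- character(0)
    cand_intronic <- character(0)
    ovl_frac <- numeric(0)
    for (g in gidx) {
      gname <- gene_names[g]
      eidx <- which(ex_gene == gname)
      es <- ex_start[eidx]; ee <- ex_end[eidx]
      if (length(eidx) &&
          any(abs(s - es) <= tol) && any(abs(e - ee) <= tol)) {
        cand_exonic <- c(cand_exonic, gname)
      } else if (length(eidx) >= 2) {
        o <- order(es)
        es_o <- es[o]; ee_o <- ee[o]
        gap_s <- ee_o[-length(ee_o)] + 1L
        gap_e <- es_o[-1] - 1L
        if (any(gap_s <= gap_e & s >= gap_s & e <= gap_e)) {
          cand_intronic <- c(cand_intronic, gname)
        }
      }
      gs <- GenomicRanges::start(ann$genes)[g]
      ge <- GenomicRanges::end(ann$genes)[g]
      ovl <- max(0, min(e, ge) - max(s, gs) + 1) / (e - s + 1)
      ovl_frac <- c(ovl_frac, stats::setNames(ovl, gname))
    }
    pick <- function(cands) {
      fr <- ovl_frac[cands]
      cands[order(-fr, cands)][1]
    }
    if (length(cand_exonic)) {
      cls[i] <- "exonic"; host[i] <- pick(cand_exonic)
    } else if (length(cand_intronic)) {
      cls[i] <- "intronic"; host[i] <- pick(cand_intronic)
    } else {
      # overlaps a gene but matches neither pattern: exonic by best overlap
      cls[i] <- "exonic"; host[i] <- pick(gene_names[gidx])
    }
  }
  data.frame(circ_class = cls, host_gene = host, stringsAsFactors = FALSE)
}

#' @rdname classify_circs
#' @param key A single BSJ as a list or one-row data frame with
#'   `chrom, start, end, strand`.
#' @return For `classify_circ`: list with `circ_class` and `host_gene`.
#' @export
classify_circ <- function(key, ann, tol = 2) {
  df <- as.data.frame(key, stringsAsFactors = FALSE)
  res <- classify_circs(df, ann, tol = tol)
  list(circ_class = res$circ_class[1], host_gene = res$host_gene[1])
}

#' Assign standardized circRNA names
#'
#' Exonic circRNAs are named `hsa-circGENE-NNN` with the three-digit counter
#' assigned sequentially by genomic position `(start, end)` within the host
#' gene; intronic circRNAs are `hsa-ciGENE`, with a positional `-NNN` suffix
#' only when one gene hosts more than one intronic circRNA; intergenic
#' circRNAs are `hsa-circChromK-NNN`, numbered by position within the
#' chromosome (K = chromosome label without any "chr" prefix). Naming is a
#' pure function of the record set: input order never changes a name.
#'
#' @param records Data frame with `chrom, start, end, strand, circ_class,
#'   host_gene`.
#' @param prefix Species prefix (default `"hsa"`).
#' @return `records` with a `name` column added (input row order preserved).
#' @export
assign_names <- function(records, prefix = "hsa") {
  n <- nrow(records)
  nm <- rep(NA_character_, n)
  if (n == 0) {
    records$name <- character(0)
    return(records)
  }
  fmt_num <- function(i) {
    if (any(i > 999)) {
      circ_stop("more than 999 circRNAs in one naming group", "circRPL_overflow_error")
    }
    sprintf("%03d", i)
  }
  idx_exonic <- which(records$circ_class == "exonic")
  for (g in unique(records$host_gene[idx_exonic])) {
    rows <- idx_exonic[records$host_gene[idx_exonic] == g]
    o <- rows[order(records$start[rows], records$end[rows])]
    nm[o] <- paste0(prefix, "-circ", g, "-", fmt_num(seq_along(o)))
  }
  idx_intronic <- which(records$circ_class == "intronic")
  for (g in unique(records$host_gene[idx_intronic])) {
    rows <- idx_intronic[records$host_gene[idx_intronic] == g]
    if (length(rows) == 1) {
      nm[rows] <- paste0(prefix, "-ci", g)
    } else {
      o <- rows[order(records$start[rows], records$end[rows])]
      nm[o] <- paste0(prefix, "-ci", g, "-", fmt_num(seq_along(o)))
    }
  }
  idx_inter <- which(records$circ_class == "intergenic")
  for (chr in unique(records$chrom[idx_inter])) {
    rows <- idx_inter[records$chrom[idx_inter] == chr]
    o <- rows[order(records$start[rows], records$end[rows])]
    nm[o] <- paste0(prefix, "-circChrom", chrom_label(chr), "-", fmt_num(seq_along(o)))
  }
  if (anyNA(nm) || anyDuplicated(nm)) {
    circ_stop("name assignment produced missing or duplicate names",
              "circRPL_value_error")
  }
  records$name <- nm
  records
}

#' Annotate and name a consolidated set
#'
#' Convenience wrapper: classify every consolidated BSJ, flag known/novel,
#' and assign names.
#'
#' @param cons A `consolidated_set`.
#' @param ann An `annotation_index`.
#' @param catalogue Known-circRNA catalogue data frame.
#' @param tol Boundary tolerance for classification.
#' @param prefix Species prefix for names.
#' @return Record data frame: `name, chrom, start, end, strand, class
#'   (circ_class), host_gene, known`.
#' @export
annotate_circs <- function(cons, ann, catalogue, tol = 2, prefix = "hsa") {
  rec <- cons$keys
  cl <- classify_circs(rec, ann, tol = tol)
  rec$circ_class <- cl$circ_class
  rec$host_gene <- cl$host_gene
  rec$known <- flag_known(cons, catalogue)
  rec <- assign_names(rec, prefix = prefix)
  rec[, c("name", "chrom", "start", "end", "strand", "circ_class",
          "host_gene", "known")]
}

#' Per-gene and per-chromosome circRNA counts
#'
#' @param records Named record data frame (see [annotate_circs()]).
#' @return Data frame `(gene, n_circRNAs)` resp. `(chrom, n_circRNAs)`,
#'   ordered by count (descending) then name.
#' @export
per_gene_summary <- function(records) {
  hosts <- records$host_gene[!is.na(records$host_gene)]
  if (!length(hosts)) {
    return(data.frame(gene = character(), n_circRNAs = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(hosts)
  out <- data.frame(gene = names(tab), n_circRNAs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_circRNAs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname per_gene_summary
#' @export
per_chrom_summary <- function(records) {
  if (!nrow(records)) {
    return(data.frame(chrom = character(), n_circRNAs = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(records$chrom)
  out <- data.frame(chrom = names(tab), n_circRNAs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_circRNAs, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}
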