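# Readers and writers for every external table the pipeline touches.
#
# Canonical internal convention for BSJ coordinates: 1-based, fully closed,
# for every module. Each reader declares the dialect of its source format and
# converts on read:
#   * DCC dialect: 0-based start, 1-based end (BED-like start).
#   * CIRI2 dialect: 1-based closed, identical to the canonical convention.
# Detector calls are held in "long" form: one row per (BSJ, sample).

CALL_COLS <- c("chrom", "start", "end", "strand", "sample", "count", "detector")

#' Read DCC-style circRNA calls
#'
#' Reads the two-file DCC output layout: a `CircRNACount` table (Chr, Start,
#' End, then one junction-read count column per sample) and a matching
#' `CircCoordinates` table (Chr, Start, End, ... , Strand) with identical row
#' order. Coordinates are converted from the DCC dialect (0-based start,
#' 1-based end) to the canonical 1-based closed convention.
#'
#' @param count_path Path to the CircRNACount-style TSV.
#' @param coords_path Path to the CircCoordinates-style TSV.
#' @return A data frame of calls in long form with columns
#'   `chrom, start, end, strand, sample, count, detector` (`detector = "DCC"`).
#' @export
read_dcc_calls <- function(count_path, coords_path) {
  counts <- read_tsv_checked(count_path, c("Chr", "Start", "End"), "DCC CircRNACount")
  coords <- read_tsv_checked(coords_path, c("Chr", "Start", "End", "Strand"),
                             "DCC CircCoordinates")
  if (nrow(counts) != nrow(coords)) {
    circ_stop(sprintf("DCC files disagree on row count (%d vs %d)",
                      nrow(counts), nrow(coords)), "circRPL_dialect_error")
  }
  if (nrow(counts) > 0 &&
      !all(counts$Chr == coords$Chr & counts$Start == coords$Start &
           counts$End == coords$End)) {
    circ_stop("DCC files disagree on coordinates at matching rows",
              "circRPL_dialect_error")
  }
  sample_cols <- setdiff(names(counts), c("Chr", "Start", "End"))
  if (nrow(counts) == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sample = character(),
                      count = integer(), detector = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cnt <- as.matrix(counts[, sample_cols, drop = FALSE])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    circ_stop("DCC counts must be non-negative integers", "circRPL_value_error")
  }
  keys <- data.frame(chrom = as.character(counts$Chr),
                     start = as.integer(counts$Start) + 1L,  # 0-based -> 1-based
                     end = as.integer(counts$End),
                     strand = as.character(coords$Strand),
                     stringsAsFactors = FALSE)
  check_bsj_coords(keys, "DCC calls")
  out <- data.frame(
    chrom = rep(keys$chrom, times = length(sample_cols)),
    start = rep(keys$start, times = length(sample_cols)),
    end = rep(keys$end, times = length(sample_cols)),
    strand = rep(keys$strand, times = length(sample_cols)),
    sample = rep(sample_cols, each = nrow(keys)),
    count = as.integer(cnt),
    detector = "DCC",
    stringsAsFactors = FALSE)
  out
}

#' Write DCC-style call files
#'
#' Inverse of [read_dcc_calls()]: serializes long-form calls into the two-file
#' DCC dialect (0-based start in both files).
#'
#' @param calls Long-form call data frame (see [read_dcc_calls()]).
#' @param count_path,coords_path Output paths.
#' @param samples Sample column order; defaults to order of appearance.
#' @export
write_dcc_calls <- function(calls, count_path, coords_path,
                            samples = unique(calls$sample)) {
  keys <- unique(calls[, c("chrom", "start", "end", "strand")])
  keys <- keys[order(keys$chrom, keys$start, keys$end, keys$strand), , drop = FALSE]
  kid <- bsj_id(keys$chrom, keys$start, keys$end, keys$strand)
  cnt <- matrix(0L, nrow = nrow(keys), ncol = length(samples),
                dimnames = list(kid, samples))
  if (nrow(calls)) {
    cid <- bsj_id(calls$chrom, calls$start, calls$end, calls$strand)
    cnt[cbind(match(cid, kid), match(calls$sample, samples))] <- as.integer(calls$count)
  }
  count_df <- data.frame(Chr = keys$chrom, Start = keys$start - 1L, End = keys$end,
                         stringsAsFactors = FALSE, check.names = FALSE)
  count_df[samples] <- as.data.frame(cnt, check.names = FALSE)
  coords_df <- data.frame(Chr = keys$chrom, Start = keys$start - 1L, End = keys$end,
                          Strand = keys$strand, stringsAsFactors = FALSE)
  write_tsv_plain(count_df, count_path)
  write_tsv_plain(coords_df, coords_path)
  invisible(c(count_path, coords_path))
}

parse_ciri2_id <- function(id, path, rows) {
  m <- regmatches(id, regexec("^([^:]+):([0-9]+)\\|([0-9]+)$", id))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad)) {
    circ_stop(sprintf("CIRI2 file %s: unparsable circRNA_ID '%s' at row %d",
                      path, id[bad[1]], rows[bad[1]]), "circRPL_value_error")
  }
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read CIRI2-style circRNA calls
#'
#' Accepts a directory of per-sample TSVs (sample name = file name without
#' extension), a character vector of such files, or a single merged TSV with a
#' `sample` column. Required columns: `circRNA_ID` (`chr:start|end`, 1-based
#' closed — already the canonical convention), `junction_reads`, `strand`;
#' `circRNA_type` is kept when present.
#'
#' @param path Directory, file, or vector of per-sample files.
#' @return Long-form call data frame (`detector = "CIRI2"`) with an extra
#'   `circ_type` column (`NA` when absent from the source).
#' @export
read_ciri2_calls <- function(path) {
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) {
      circ_stop(sprintf("CIRI2 directory %s contains no .tsv files", path),
                "circRPL_format_error")
    }
  } else {
    files <- path
  }
  pieces <- lapply(files, function(f) {
    df <- read_tsv_checked(f, c("circRNA_ID", "junction_reads", "strand"),
                           "CIRI2 calls")
    if (nrow(df) == 0) return(NULL)
    key <- parse_ciri2_id(as.character(df$circRNA_ID), f, seq_len(nrow(df)) + 1L)
    sample <- if ("sample" %in% names(df)) as.character(df$sample) else
      rep(sub("\\.tsv$", "", basename(f)), nrow(df))
    data.frame(chrom = key$chrom, start = key$start, end = key$end,
               strand = as.character(df$strand), sample = sample,
               count = as.integer(df$junction_reads), detector = "CIRI2",
               circ_type = if ("circRNA_type" %in% names(df))
                 as.character(df$circRNA_type) else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sample = character(),
                      count = integer(), detector = character(),
                      circ_type = character(), stringsAsFactors = FALSE)
    return(out)
  }
  check_bsj_coords(out, "CIRI2 calls")
  if (any(out$count < 0)) {
    circ_stop("CIRI2 junction_reads must be non-negative", "circRPL_value_error")
  }
  dup <- duplicated(paste(out$sample, bsj_id(out$chrom, out$start, out$end, out$strand)))
  if (any(dup)) {
    circ_stop("CIRI2 calls: duplicate (sample, BSJ) rows", "circRPL_duplicate_error")
  }
  rownames(out) <- NULL
  out
}

#' Write CIRI2-style call files
#'
#' One TSV per sample under `dir`, in the dialect read by [read_ciri2_calls()].
#'
#' @param calls Long-form call data frame.
#' @param dir Output directory (created if needed).
#' @export
write_ciri2_calls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!"circ_type" %in% names(calls)) calls$circ_type <- NA_character_
  for (s in sort(unique(calls$sample))) {
    sub <- calls[calls$sample == s, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$start, sub$end), , drop = FALSE]
    df <- data.frame(circRNA_ID = bsj_id(sub$chrom, sub$start, sub$end),
                     chr = sub$chrom, start = sub$start, end = sub$end,
                     junction_reads = sub$count, strand = sub$strand,
                     circRNA_type = ifelse(is.na(sub$circ_type), ".", sub$circ_type),
                     stringsAsFactors = FALSE)
    write_tsv_plain(df, file.path(dir, paste0(s, ".tsv")))
  }
  invisible(dir)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `project_id`, `condition` (`control`/`RPL`) and
#' `library_size` (total sequenced reads, used as the size factor downstream).
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_samplesheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "project_id", "condition",
                                 "library_size"), "sample sheet")
  df$sample_id <- as.character(df$sample_id)
  df$project_id <- as.character(df$project_id)
  df$condition <- as.character(df$condition)
  df$library_size <- as.numeric(df$library_size)
  validate_samplesheet(df)
}

validate_samplesheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    circ_stop("sample sheet: duplicated sample_id", "circRPL_format_error")
  }
  if (!all(df$condition %in% c("control", "RPL"))) {
    circ_stop("sample sheet: condition must be 'control' or 'RPL'",
              "circRPL_format_error")
  }
  if (any(df$library_size <= 0)) {
    circ_stop("sample sheet: library_size must be > 0", "circRPL_format_error")
  }
  df
}

#' @export
write_samplesheet <- function(samples, path) {
  write_tsv_plain(samples[, c("sample_id", "project_id", "condition",
                              "library_size")], path)
}

#' Read a circRNA x sample junction-count matrix
#'
#' TSV with columns `chrom, start, end, strand` followed by one junction-read
#' count column per sample. Sample order is taken from the sample sheet,
#' never from file column order; every sheet sample must be present and every
#' count column must be in the sheet.
#'
#' @param path TSV path.
#' @param samples Sample sheet data frame (see [read_samplesheet()]).
#' @return A `circ_counts` object: list with `counts` (integer matrix, rows
#'   named by canonical BSJ id), `features` (coordinate data frame) and
#'   `samples` (the sheet).
#' @export
read_counts <- function(path, samples) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "strand"), "count matrix")
  sample_cols <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  extra <- setdiff(sample_cols, samples$sample_id)
  if (length(extra)) {
    circ_stop(sprintf("count matrix: sample(s) not in sample sheet: %s",
                      paste(extra, collapse = ", ")), "circRPL_metadata_error")
  }
  missing <- setdiff(samples$sample_id, sample_cols)
  if (length(missing)) {
    circ_stop(sprintf("count matrix: sheet sample(s) absent: %s",
                      paste(missing, collapse = ", ")), "circRPL_metadata_error")
  }
  features <- data.frame(chrom = as.character(df$chrom),
                         start = as.integer(df$start),
                         end = as.integer(df$end),
                         strand = as.character(df$strand),
                         stringsAsFactors = FALSE)
  check_bsj_coords(features, "count matrix")
  counts <- as.matrix(df[, samples$sample_id, drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) {
    circ_stop("count matrix: negative counts", "circRPL_value_error")
  }
  circ_counts(counts, features, samples)
}

#' Construct a circ_counts object
#'
#' @param counts Integer matrix, circRNAs x samples.
#' @param features Data frame `chrom, start, end, strand` aligned to rows.
#' @param samples Sample sheet aligned to columns.
#' @return A `circ_counts` object.
#' @export
circ_counts <- function(counts, features, samples) {
  key <- bsj_id(features$chrom, features$start, features$end, features$strand)
  if (anyDuplicated(key)) {
    circ_stop("count matrix: duplicate BSJ keys", "circRPL_format_error")
  }
  if (ncol(counts) != nrow(samples)) {
    circ_stop("count matrix: column count differs from sample sheet length",
              "circRPL_metadata_error")
  }
  rownames(counts) <- key
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, features = features, samples = samples),
            class = "circ_counts")
}

#' @export
print.circ_counts <- function(x, ...) {
  cat(sprintf("circ_counts: %d circRNAs x %d samples (%d project(s))\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$project_id))))
  invisible(x)
}

#' @export
write_counts <- function(cm, path) {
  df <- cbind(cm$features,
              as.data.frame(cm$counts, check.names = FALSE, row.names = NULL))
  write_tsv_plain(df, path)
}

#' Subset a count matrix to one project
#'
#' @param cm A `circ_counts` object.
#' @param project A project_id present in the sample sheet.
#' @return A `circ_counts` restricted to that project's samples.
#' @export
subset_project <- function(cm, project) {
  keep <- cm$samples$project_id == project
  if (!any(keep)) {
    circ_stop(sprintf("no samples for project '%s'", project),
              "circRPL_metadata_error")
  }
  circ_counts(cm$counts[, keep, drop = FALSE], cm$features,
              cm$samples[keep, , drop = FALSE])
}

#' Read a gene annotation (GTF) into an interval index
#'
#' Parses Ensembl-attribute-style GTF via rtracklayer, keeps `gene` and
#' `exon` features, and indexes them as GRanges for overlap queries. Every
#' record must carry a `gene_name` attribute. When explicit `gene` rows are
#' absent, gene spans are derived from their exons.
#'
#' @param path GTF path.
#' @return An `annotation_index`: list with `genes` and `exons` GRanges
#'   (metadata column `gene_name`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("gene", "exon")]
  if (!"gene_name" %in% names(S4Vectors::mcols(gr)) ||
      anyNA(gr$gene_name)) {
    circ_stop(sprintf("GTF %s: every gene/exon record needs a gene_name attribute",
                      path), "circRPL_format_error")
  }
  exons <- gr[gr$type == "exon"]
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0 && length(exons) > 0) {
    spl <- split(exons, exons$gene_name)
    genes <- unlist(range(spl))
    genes$gene_name <- names(genes)
    names(genes) <- NULL
  }
  ann <- structure(list(genes = genes, exons = exons), class = "annotation_index")
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ov <- GenomicRanges::findOverlaps(ann$exons, ann$genes, type = "within")
  ok <- ann$exons$gene_name[S4Vectors::queryHits(ov)] ==
    ann$genes$gene_name[S4Vectors::subjectHits(ov)]
  covered <- unique(S4Vectors::queryHits(ov)[ok])
  if (length(covered) < length(ann$exons)) {
    circ_stop("annotation: exon interval outside its gene span",
              "circRPL_format_error")
  }
  ann
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf("annotation_index: %d genes, %d exons\n",
              length(x$genes), length(x$exons)))
  invisible(x)
}

#' Write a minimal gene/exon GTF
#'
#' @param genes Data frame `gene_name, chrom, strand, start, end`.
#' @param exons Data frame `gene_name, start, end`.
#' @param path Output path.
#' @export
write_gtf <- function(genes, exons, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_str <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_name, g$gene_name)
    lines <- c(lines, paste(g$chrom, "sim", "gene", g$start, g$end, ".",
                            g$strand, ".", attr_str, sep = "\t"))
    ex <- exons[exons$gene_name == g$gene_name, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      ea <- sprintf('gene_id "%s"; gene_name "%s"; exon_number "%d";',
                    g$gene_name, g$gene_name, j)
      lines <- c(lines, paste(g$chrom, "sim", "exon", ex$start[j], ex$end[j], ".",
                              g$strand, ".", ea, sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT path (set name, description, then member genes, tab-separated).
#' @return Named list of character vectors; set descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short)) {
    circ_stop(sprintf("GMT %s: line %d has fewer than 3 fields", path, short[1]),
              "circRPL_format_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "description") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, ""), con)
  invisible(path)
}

#' Read a circRNA catalogue
#'
#' BED-like TSV with columns `chrom, start, end, strand` in 1-based closed
#' coordinates (e.g. a CIRCpedia-style known-circRNA list).
#'
#' @param path TSV path.
#' @return Data frame of BSJ keys, sorted canonically, duplicates removed.
#' @export
read_catalogue <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "strand"), "catalogue")
  df <- data.frame(chrom = as.character(df$chrom), start = as.integer(df$start),
                   end = as.integer(df$end), strand = as.character(df$strand),
                   stringsAsFactors = FALSE)
  check_bsj_coords(df, "catalogue")
  df <- unique(df)
  df <- df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
write_catalogue <- function(cat, path) {
  cat <- unique(cat[, c("chrom", "start", "end", "strand")])
  cat <- cat[order(cat$chrom, cat$start, cat$end, cat$strand), , drop = FALSE]
  write_tsv_plain(cat, path)
}

#' Read an interval lift map
#'
#' TSV mapping equal-width source intervals to target-species intervals:
#' `src_chrom, src_start, src_end, tgt_chrom, tgt_start, tgt_end, tgt_strand`,
#' 1-based closed. `tgt_strand` `"-"` flips orientation within the interval.
#' Source intervals must not overlap.
#'
#' @param path TSV path.
#' @return Validated lift-map data frame.
#' @export
read_liftmap <- function(path) {
  df <- read_tsv_checked(path, c("src_chrom", "src_start", "src_end",
                                 "tgt_chrom", "tgt_start", "tgt_end",
                                 "tgt_strand"), "lift map")
  for (col in c("src_start", "src_end", "tgt_start", "tgt_end")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$src_chrom <- as.character(df$src_chrom)
  df$tgt_chrom <- as.character(df$tgt_chrom)
  df$tgt_strand <- as.character(df$tgt_strand)
  validate_liftmap(df)
}

validate_liftmap <- function(df) {
  if (any(df$src_end - df$src_start != df$tgt_end - df$tgt_start)) {
    circ_stop("lift map: source and target interval widths differ",
              "circRPL_map_error")
  }
  if (!all(df$tgt_strand %in% c("+", "-"))) {
    circ_stop("lift map: tgt_strand must be + or -", "circRPL_map_error")
  }
  for (chr in unique(df$src_chrom)) {
    sub <- df[df$src_chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$src_start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$src_start[-1] <= sub$src_end[-nrow(sub)])) {
      circ_stop(sprintf("lift map: overlapping source intervals on %s", chr),
                "circRPL_map_error")
    }
  }
  df
}

#' @export
write_liftmap <- function(map, path) {
  map <- map[order(map$src_chrom, map$src_start), , drop = FALSE]
  write_tsv_plain(map[, c("src_chrom", "src_start", "src_end", "tgt_chrom",
                          "tgt_start", "tgt_end", "tgt_strand")], path)
}

#' Read/write consolidated circRNA records
#'
#' Output of the annotation stage: `name, chrom, start, end, strand, class,
#' host_gene, known`.
#'
#' @param path TSV path.
#' @return Data frame of records.
#' @export
read_circ_records <- function(path) {
  df <- read_tsv_checked(path, c("name", "chrom", "start", "end", "strand",
                                 "class", "host_gene", "known"), "circ records")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$known <- as.logical(df$known)
  df$host_gene[df$host_gene == "."] <- NA_character_
  df
}

#' @rdname read_circ_records
#' @param records Record data frame.
#' @export
write_circ_records <- function(records, path) {
  if (!"class" %in% names(records) && "circ_class" %in% names(records)) {
    records$class <- records$circ_class
  }
  out <- records[, c("name", "chrom", "start", "end", "strand", "class",
                     "host_gene", "known")]
  out$host_gene <- ifelse(is.na(out$host_gene), ".", out$host_gene)
  write_tsv_plain(out, path)
}
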