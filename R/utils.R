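# Internal helpers shared across modules.

VALID_STRANDS <- c("+", "-", ".")

circ_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "circRPL_error")))
}

#' Canonical BSJ identifier
#'
#' Builds the canonical string identifier of a back-splice junction from its
#' 1-based, fully closed genomic coordinates. Two BSJs are the same circRNA
#' exactly when their identifiers are equal.
#'
#' @param chrom Chromosome name.
#' @param start 1-based leftmost base of the circRNA (inclusive).
#' @param end 1-based rightmost base (inclusive), `end >= start`.
#' @param strand `"+"`, `"-"` or `"."`; omit (`NULL`) for a strand-less key.
#' @return Character vector of identifiers, `chrom:start|end` with `:strand`
#'   appended when strand is given.
#' @export
bsj_id <- function(chrom, start, end, strand = NULL) {
  if (length(chrom) == 0) return(character(0))
  if (is.null(strand)) {
    paste0(chrom, ":", start, "|", end)
  } else {
    paste0(chrom, ":", start, "|", end, ":", strand)
  }
}

check_bsj_coords <- function(df, where = "input") {
  if (any(df$start < 1L)) {
    circ_stop(sprintf("%s: BSJ start below 1 (coordinates are 1-based)", where),
              "circRPL_value_error")
  }
  if (any(df$end < df$start)) {
    bad <- which(df$end < df$start)[1]
    circ_stop(sprintf("%s: BSJ end < start at row %d", where, bad),
              "circRPL_value_error")
  }
  if (!all(df$strand %in% VALID_STRANDS)) {
    circ_stop(sprintf("%s: unknown strand symbol (allowed: + - .)", where),
              "circRPL_value_error")
  }
  invisible(df)
}

# strip a leading "chr" prefix: "chr3" -> "3" (used by intergenic names)
chrom_label <- function(chrom) sub("^chr", "", chrom)

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    circ_stop(sprintf("%s: file not found: %s", what, path), "circRPL_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    circ_stop(sprintf("%s (%s): missing mandatory column(s): %s",
                      what, path, paste(missing, collapse = ", ")),
              "circRPL_format_error")
  }
  df
}

write_tsv_plain <- function(df, path) {
  # byte-stable writer: fixed quoting, LF endings, no row names
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
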