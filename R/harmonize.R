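# Consolidation of the two detectors' BSJ calls: exact-coordinate
# intersection, count attachment from the designated quantification table,
# and known/novel flagging against a reference catalogue.

#' Intersect BSJ calls from two detectors
#'
#' A circRNA is kept only when both detectors called the exact same
#' back-splice junction (no positional fuzz). With `match_strand = TRUE`
#' (default) the strand is part of the match; with `FALSE` matching is on
#' `(chrom, start, end)` only, and the consolidated strand is resolved per
#' BSJ by majority vote across the two detectors' records, preferring a
#' defined strand over ".".
#'
#' @param dcc,ciri Long-form call data frames in canonical coordinates
#'   (see [read_dcc_calls()], [read_ciri2_calls()]).
#' @param match_strand Require strand agreement for a match.
#' @param project_id Optional project label carried in the result.
#' @return A `consolidated_set`: list with `keys` (data frame of consolidated
#'   BSJs), `counts` (NULL until [attach_counts()]), `samples`, `provenance`
#'   and `project_id`.
#' @export
intersect_calls <- function(dcc, ciri, match_strand = TRUE, project_id = NA_character_) {
  dk <- unique(dcc[, c("chrom", "start", "end", "strand")])
  ck <- unique(ciri[, c("chrom", "start", "end", "strand")])
  if (match_strand) {
    did <- bsj_id(dk$chrom, dk$start, dk$end, dk$strand)
    cid <- bsj_id(ck$chrom, ck$start, ck$end, ck$strand)
    common <- intersect(did, cid)
    keys <- dk[match(common, did), , drop = FALSE]
  } else {
    did <- bsj_id(dk$chrom, dk$start, dk$end)
    cid <- bsj_id(ck$chrom, ck$start, ck$end)
    common <- intersect(did, cid)
    keys <- dk[match(common, did), , drop = FALSE]
    # resolve strand by majority over all matching detector records
    all_k <- rbind(dk, ck)
    all_id <- bsj_id(all_k$chrom, all_k$start, all_k$end)
    keys$strand <- vapply(common, function(id) {
      s <- all_k$strand[all_id == id]
      s_def <- s[s != "."]
      if (!length(s_def)) return(".")
      tab <- sort(table(s_def), decreasing = TRUE)
      # tie -> "+" before "-" (names are sorted within equal counts)
      names(tab)[1]
    }, "")
  }
  keys <- keys[order(keys$chrom, keys$start, keys$end, keys$strand), , drop = FALSE]
  rownames(keys) <- NULL
  structure(list(keys = keys, counts = NULL, samples = NULL,
                 provenance = data.frame(
                   key = bsj_id(keys$chrom, keys$start, keys$end, keys$strand),
                   dcc = rep(TRUE, nrow(keys)), ciri = rep(TRUE, nrow(keys)),
                   stringsAsFactors = FALSE),
                 project_id = project_id),
            class = "consolidated_set")
}

#' @export
print.consolidated_set <- function(x, ...) {
  cat(sprintf("consolidated_set: %d BSJs called by both detectors%s%s\n",
              nrow(x$keys),
              if (!is.na(x$project_id)) paste0(" [", x$project_id, "]") else "",
              if (is.null(x$counts)) " (no counts attached)" else ""))
  invisible(x)
}

#' Attach quantification counts to a consolidated set
#'
#' Counts come from a single designated quantification source (the
#' CIRIquant-role matrix), never summed across detectors. Consolidated BSJs
#' absent from the matrix get explicit zero counts with a warning.
#'
#' @param cons A `consolidated_set`.
#' @param cm A `circ_counts` object keyed by BSJ.
#' @return The `consolidated_set` with `counts` (matrix, rows = consolidated
#'   BSJs, columns = sheet samples) and `samples` filled in.
#' @export
attach_counts <- function(cons, cm) {
  kid <- bsj_id(cons$keys$chrom, cons$keys$start, cons$keys$end, cons$keys$strand)
  idx <- match(kid, rownames(cm$counts))
  out <- matrix(0L, nrow = length(kid), ncol = ncol(cm$counts),
                dimnames = list(kid, colnames(cm$counts)))
  hit <- !is.na(idx)
  out[hit, ] <- cm$counts[idx[hit], , drop = FALSE]
  if (any(!hit)) {
    warning(sprintf("%d consolidated BSJ(s) absent from the count matrix; zeros attached",
                    sum(!hit)), call. = FALSE)
  }
  cons$counts <- out
  cons$samples <- cm$samples
  cons
}

#' Flag known versus novel circRNAs
#'
#' A consolidated BSJ is "known" exactly when its `(chrom, start, end,
#' strand)` matches a catalogue entry; anything else is novel.
#'
#' @param cons A `consolidated_set`.
#' @param catalogue Catalogue data frame (see [read_catalogue()]).
#' @return Logical vector aligned to `cons$keys` rows.
#' @export
flag_known <- function(cons, catalogue) {
  kid <- bsj_id(cons$keys$chrom, cons$keys$start, cons$keys$end, cons$keys$strand)
  cat_id <- bsj_id(catalogue$chrom, catalogue$start, catalogue$end, catalogue$strand)
  kid %in% cat_id
}

#' Collapse duplicate calls within one detector
#'
#' The same BSJ reported twice for one sample by one detector is collapsed to
#' the maximum count, with a warning.
#'
#' @param calls Long-form call data frame.
#' @return De-duplicated calls.
#' @export
collapse_duplicates <- function(calls) {
  key <- paste(calls$detector, calls$sample,
               bsj_id(calls$chrom, calls$start, calls$end, calls$strand))
  if (!anyDuplicated(key)) return(calls)
  warning("duplicate (detector, sample, BSJ) calls collapsed by max count",
          call. = FALSE)
  mx <- tapply(calls$count, key, max)
  keep <- !duplicated(key)
  out <- calls[keep, , drop = FALSE]
  out$count <- as.integer(mx[key[keep]])
  rownames(out) <- NULL
  out
}
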