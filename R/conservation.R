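# Cross-species conservation of back-splice sites: interval-map coordinate
# lifting of the 5' and 3' splice positions and six-way category assignment
# against a reference-species (mouse) circRNA catalogue.

#' Conservation category labels
#'
#' The six mutually exclusive categories, in reporting order.
#' @export
CONS_CATEGORIES <- c("not-aligned", "no homologous", "5' site utilized",
                     "3' site utilized", "both sites utilized", "homologous")

#' Lift one genomic position through an interval map
#'
#' Applies a liftOver-style interval map: if `pos` falls inside a mapped
#' source interval, it is shifted by the interval's constant offset (and
#' mirrored within the interval when the target strand is "-"); otherwise
#' the position does not lift.
#'
#' @param chrom Source chromosome.
#' @param pos 1-based source position.
#' @param liftmap Lift-map data frame (see [read_liftmap()]).
#' @return A list `(chrom, pos, strand)` on success, or `NULL` when the
#'   position is not covered by the map.
#' @export
lift_site <- function(chrom, pos, liftmap) {
  hit <- which(liftmap$src_chrom == chrom &
               liftmap$src_start <= pos & pos <= liftmap$src_end)
  if (!length(hit)) return(NULL)
  h <- liftmap[hit[1], ]
  off <- pos - h$src_start
  tpos <- if (h$tgt_strand == "+") h$tgt_start + off else h$tgt_end - off
  list(chrom = h$tgt_chrom, pos = as.integer(tpos), strand = h$tgt_strand)
}

# 5'/3' splice positions on the transcribed strand: for "+" (and unstranded
# ".") the 5' acceptor is the start and the 3' donor the end; flipped for "-".
split_sites <- function(chrom, start, end, strand) {
  if (identical(strand, "-")) {
    list(p5 = end, p3 = start)
  } else {
    list(p5 = start, p3 = end)
  }
}

#' Classify cross-species conservation of one BSJ
#'
#' The 5' and 3' splice positions are lifted to the reference species with
#' [lift_site()]. If either position fails to lift the BSJ is "not-aligned".
#' Otherwise each catalogue circRNA whose own splice positions (either
#' terminus; catalogue strand is ignored, since the lift map may flip
#' orientation) fall within +/-`window` nt of a lifted position "uses" that
#' site; the BSJ is "homologous" when one catalogue circRNA uses both sites,
#' "both sites utilized" when both sites are used but only by different
#' circRNAs, "5' site utilized" / "3' site utilized" when exactly one site is
#' used, and "no homologous" when neither is.
#'
#' @param key One BSJ: list or one-row data frame `chrom, start, end, strand`.
#' @param liftmap Lift-map data frame.
#' @param mouse_catalogue Reference-species catalogue data frame.
#' @param window Matching half-window in nt (default 2).
#' @return List: `lifted_5p`, `lifted_3p` (positions or NA) and `category`.
#' @export
classify_conservation <- function(key, liftmap, mouse_catalogue, window = 2) {
  key <- as.list(as.data.frame(key, stringsAsFactors = FALSE))
  sites <- split_sites(key$chrom, key$start, key$end, key$strand)
  l5 <- lift_site(key$chrom, sites$p5, liftmap)
  l3 <- lift_site(key$chrom, sites$p3, liftmap)
  if (is.null(l5) || is.null(l3)) {
    return(list(lifted_5p = if (is.null(l5)) NA_integer_ else l5$pos,
                lifted_3p = if (is.null(l3)) NA_integer_ else l3$pos,
                category = "not-aligned"))
  }
  near <- function(l) {
    which(mouse_catalogue$chrom == l$chrom &
          (abs(mouse_catalogue$start - l$pos) <= window |
           abs(mouse_catalogue$end - l$pos) <= window))
  }
  m5 <- near(l5)
  m3 <- near(l3)
  category <- if (length(intersect(m5, m3))) {
    "homologous"
  } else if (length(m5) && length(m3)) {
    "both sites utilized"
  } else if (length(m5)) {
    "5' site utilized"
  } else if (length(m3)) {
    "3' site utilized"
  } else {
    "no homologous"
  }
  list(lifted_5p = l5$pos, lifted_3p = l3$pos, category = category)
}

#' Classify conservation for a set of records
#'
#' @param records Data frame with `chrom, start, end, strand` (and optionally
#'   `name`, carried through).
#' @inheritParams classify_conservation
#' @return Data frame: input columns plus `lifted_5p`, `lifted_3p`,
#'   `category`.
#' @export
classify_conservation_all <- function(records, liftmap, mouse_catalogue, window = 2) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    classify_conservation(records[i, c("chrom", "start", "end", "strand")],
                          liftmap, mouse_catalogue, window = window)
  })
  records$lifted_5p <- vapply(res, function(r) as.integer(r$lifted_5p), 1L)
  records$lifted_3p <- vapply(res, function(r) as.integer(r$lifted_3p), 1L)
  records$category <- vapply(res, function(r) r$category, "")
  records
}

#' Summarize conservation categories
#'
#' @param calls Data frame with a `category` column
#'   (see [classify_conservation_all()]).
#' @return Data frame `category, count, percent` over categories that occur,
#'   in canonical category order; percents sum to 100.
#' @export
conservation_summary <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(category = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  tab <- table(factor(calls$category, levels = CONS_CATEGORIES))
  tab <- tab[tab > 0]
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / nrow(calls), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}
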