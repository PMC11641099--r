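# Shared fixtures (built in code at test time) and independent oracle
# implementations used to cross-check the package's algorithms.

.fixture_env <- new.env(parent = emptyenv())

# Default synthetic study, generated once per test session.
cached_bundle <- function() {
  if (is.null(.fixture_env$default)) {
    dir <- file.path(tempdir(), "circRPL_bundle_default")
    .fixture_env$default <- simulate_world(sim_params(seed = 101), dir)
  }
  .fixture_env$default
}

# Larger bundle for the conservation / naming stress checks.
cached_big_bundle <- function() {
  if (is.null(.fixture_env$big)) {
    dir <- file.path(tempdir(), "circRPL_bundle_big")
    .fixture_env$big <- simulate_world(
      sim_params(seed = 202, n_circ = 1000, n_genes = 1500, n_chroms = 8,
                 lift_fail_frac = 0.15, frac_conserved = 0.35),
      dir)
  }
  .fixture_env$big
}

truth_key <- function(truth) bsj_id(truth$chrom, truth$start, truth$end, truth$strand)

# random BSJ key table (used by round-trip and intersection checks)
random_keys <- function(n, chroms = paste0("chr", 1:4)) {
  start <- sample.int(1e6, n)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(5000, n),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- independent oracles ----

# O(n^2) pairwise intersection comparator
oracle_intersect <- function(a, b, match_strand = TRUE) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      same <- a$chrom[i] == b$chrom[j] && a$start[i] == b$start[j] &&
        a$end[i] == b$end[j] &&
        (!match_strand || a$strand[i] == b$strand[j])
      if (same) {
        hits[[length(hits) + 1L]] <- a[i, , drop = FALSE]
        break
      }
    }
  }
  if (!length(hits)) return(character(0))
  k <- do.call(rbind, hits)
  sort(unique(if (match_strand) bsj_id(k$chrom, k$start, k$end, k$strand)
              else bsj_id(k$chrom, k$start, k$end)))
}

# BH step-up written from the definition, independent of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# exhaustive conservation classifier: enumerates the per-base lift table and
# scans every catalogue entry at every window offset
oracle_conservation <- function(key, liftmap, mouse, window = 2) {
  lift1 <- function(chrom, pos) {
    for (r in seq_len(nrow(liftmap))) {
      if (liftmap$src_chrom[r] != chrom) next
      for (off in 0:(liftmap$src_end[r] - liftmap$src_start[r])) {
        if (liftmap$src_start[r] + off == pos) {
          tp <- if (liftmap$tgt_strand[r] == "+") liftmap$tgt_start[r] + off
                else liftmap$tgt_end[r] - off
          return(list(chrom = liftmap$tgt_chrom[r], pos = tp))
        }
      }
    }
    NULL
  }
  if (key$strand == "-") { p5 <- key$end; p3 <- key$start }
  else { p5 <- key$start; p3 <- key$end }
  l5 <- lift1(key$chrom, p5); l3 <- lift1(key$chrom, p3)
  if (is.null(l5) || is.null(l3)) return("not-aligned")
  uses <- function(l) {
    hit <- logical(nrow(mouse))
    for (r in seq_len(nrow(mouse))) {
      if (mouse$chrom[r] != l$chrom) next
      for (d in -window:window) {
        if (mouse$start[r] == l$pos + d || mouse$end[r] == l$pos + d) {
          hit[r] <- TRUE
        }
      }
    }
    which(hit)
  }
  m5 <- uses(l5); m3 <- uses(l3)
  if (length(intersect(m5, m3))) return("homologous")
  if (length(m5) && length(m3)) return("both sites utilized")
  if (length(m5)) return("5' site utilized")
  if (length(m3)) return("3' site utilized")
  "no homologous"
}

# union-find connected components over an edge list of node names
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (length(edges)) {
    for (e in edges) parent[[find(e[1])]] <- find(e[2])
  }
  comp <- vapply(nodes, find, "")
  split(nodes, comp)
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  hashes <- unname(tools::md5sum(file.path(dir, files)))
  stats::setNames(hashes, files)
}
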