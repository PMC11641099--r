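# Locus classification, nomenclature and summaries.

tiny_annotation <- function() {
  if (is.null(.fixture_env$tiny_ann)) {
    dir <- file.path(tempdir(), "circRPL_tiny_ann")
    dir.create(dir, showWarnings = FALSE)
    genes <- data.frame(gene_name = c("ABC", "XYZ"), chrom = c("chr1", "chr3"),
                        strand = c("+", "-"), start = c(1000L, 5000L),
                        end = c(3000L, 6000L), stringsAsFactors = FALSE)
    exons <- data.frame(gene_name = c("ABC", "ABC", "ABC", "ABC", "XYZ", "XYZ"),
                        start = c(1000L, 1500L, 2000L, 2600L, 5000L, 5800L),
                        end = c(1100L, 1600L, 2100L, 3000L, 5100L, 6000L),
                        stringsAsFactors = FALSE)
    write_gtf(genes, exons, file.path(dir, "tiny.gtf"))
    .fixture_env$tiny_ann <- read_gtf(file.path(dir, "tiny.gtf"))
  }
  .fixture_env$tiny_ann
}

test_that("exon-boundary spans are exonic, intron-interior spans intronic, gaps intergenic", {
  ann <- tiny_annotation()
  # spans exon2 start .. exon4 end of ABC
  expect_equal(classify_circ(list(chrom = "chr1", start = 1500L, end = 3000L,
                                  strand = "+"), ann),
               list(circ_class = "exonic", host_gene = "ABC"))
  # within boundary tolerance of +/-2 nt
  expect_equal(classify_circ(list(chrom = "chr1", start = 1502L, end = 2999L,
                                  strand = "+"), ann)$circ_class, "exonic")
  # strictly inside intron 1 of ABC (1101..1499)
  expect_equal(classify_circ(list(chrom = "chr1", start = 1150L, end = 1400L,
                                  strand = "+"), ann),
               list(circ_class = "intronic", host_gene = "ABC"))
  # overlaps no gene body
  expect_equal(classify_circ(list(chrom = "chr1", start = 3500L, end = 4200L,
                                  strand = "+"), ann)$circ_class, "intergenic")
  # overlaps a gene but fits neither pattern -> exonic fallback
  expect_equal(classify_circ(list(chrom = "chr1", start = 1050L, end = 1550L,
                                  strand = "+"), ann),
               list(circ_class = "exonic", host_gene = "ABC"))
})

test_that("planted classes and host genes are recovered from the synthetic bundle", {
  b <- cached_bundle()
  ann <- read_gtf(b$paths$gtf)
  cl <- classify_circs(b$truth, ann)
  expect_identical(cl$circ_class, b$truth$class)
  expect_identical(cl$host_gene, b$truth$host_gene)
})

test_that("names follow the nomenclature rules", {
  rec <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr3", "chr3"),
    start = c(1500L, 1000L, 1150L, 9000L, 700L),
    end = c(3000L, 2100L, 1400L, 9600L, 1400L),
    strand = "+",
    circ_class = c("exonic", "exonic", "intronic", "intergenic", "intergenic"),
    host_gene = c("ABC", "ABC", "ABC", NA, NA),
    stringsAsFactors = FALSE)
  named <- assign_names(rec)
  # exonic: sequential three-digit counter ordered by (start, end) in the gene
  expect_equal(named$name[named$start == 1000L], "hsa-circABC-001")
  expect_equal(named$name[named$start == 1500L], "hsa-circABC-002")
  # single intronic circRNA: no numeric suffix
  expect_equal(named$name[named$circ_class == "intronic"], "hsa-ciABC")
  # intergenic: numbered by position within the chromosome
  expect_equal(named$name[named$start == 700L], "hsa-circChrom3-001")
  expect_equal(named$name[named$start == 9000L], "hsa-circChrom3-002")

  # a second intronic circRNA in the same gene forces the -NNN suffix
  rec2 <- rbind(rec, data.frame(chrom = "chr1", start = 2200L, end = 2400L,
                                strand = "+", circ_class = "intronic",
                                host_gene = "ABC", stringsAsFactors = FALSE))
  named2 <- assign_names(rec2)
  expect_setequal(named2$name[named2$circ_class == "intronic"],
                  c("hsa-ciABC-001", "hsa-ciABC-002"))

  # numbering overflow
  many <- data.frame(chrom = "chr1", start = seq_len(1000L) * 10L,
                     end = seq_len(1000L) * 10L + 5L, strand = "+",
                     circ_class = "exonic", host_gene = "BIG",
                     stringsAsFactors = FALSE)
  expect_error(assign_names(many), class = "circRPL_overflow_error")
})

test_that("naming is a pure function of the record set and names are well-formed", {
  b <- cached_bundle()
  ann <- read_gtf(b$paths$gtf)
  rec <- b$truth[, c("chrom", "start", "end", "strand")]
  cl <- classify_circs(rec, ann)
  rec$circ_class <- cl$circ_class
  rec$host_gene <- cl$host_gene
  base <- assign_names(rec)
  base_map <- setNames(base$name, truth_key(base))
  set.seed(12)
  for (i in 1:5) {
    perm <- sample(nrow(rec))
    shuf <- assign_names(rec[perm, ])
    expect_identical(setNames(shuf$name, truth_key(shuf))[names(base_map)],
                     base_map)
  }
  expect_true(all(grepl("^hsa-(circ|ci)[A-Za-z0-9.\\-]+(-\\d{3})?$", base$name)))
  expect_false(anyDuplicated(base$name) > 0)
})

test_that("per-gene and per-chromosome summaries aggregate exactly", {
  rec <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = 1:4, end = 2:5, strand = "+",
                    circ_class = "exonic",
                    host_gene = c("A", "A", "A", "B"),
                    stringsAsFactors = FALSE)
  rec <- assign_names(rec)
  pg <- per_gene_summary(rec)
  expect_equal(pg, data.frame(gene = c("A", "B"), n_circRNAs = c(3L, 1L),
                              stringsAsFactors = FALSE))
  pc <- per_chrom_summary(rec)
  expect_equal(pc$n_circRNAs, c(3L, 1L))
  expect_equal(sum(pc$n_circRNAs), nrow(rec))

  empty <- rec[0, ]
  expect_equal(nrow(per_gene_summary(empty)), 0L)
  expect_equal(nrow(per_chrom_summary(empty)), 0L)

  b <- cached_bundle()
  ann <- read_gtf(b$paths$gtf)
  cl <- classify_circs(b$truth, ann)
  recb <- cbind(b$truth[, c("chrom", "start", "end", "strand")], cl)
  pg_b <- per_gene_summary(assign_names(recb))
  truth_tab <- table(b$truth$host_gene[!is.na(b$truth$host_gene)])
  expect_identical(setNames(pg_b$n_circRNAs, pg_b$gene)[names(truth_tab)],
                   setNames(as.integer(truth_tab), names(truth_tab)))
})
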