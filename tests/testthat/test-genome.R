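test_that("load_genome reads FASTA + GFF3 and preserves counts", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  writeLines(c(">chrA", strrep("ACGT", 75),
               ">p1 plasmid", strrep("GATC", 50)), fa)
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA1",
               "chrA\tsrc\tgene\t161\t300\t.\t-\t.\tID=gA2",
               "p1\tsrc\tgene\t10\t50\t.\t+\t.\tID=gP1"), gff)
  ann <- load_genome(fa, gff)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$replicons), 2)
  expect_equal(nrow(ann$genes), 3)
  expect_equal(ann$replicons$kind, c("chromosome", "plasmid"))
  expect_equal(nchar(ann$sequences[["chrA"]]), 300)

  # gene beyond replicon end is rejected with a bounds error
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tgene\t200\t400\t.\t+\t.\tID=bad"), gff)
  expect_error(load_genome(fa, gff), "outside replicon")

  # empty annotation (header only) is a valid genome with 0 genes
  writeLines("##gff-version 3", gff)
  ann0 <- load_genome(fa, gff)
  expect_equal(nrow(ann0$genes), 0)
})

test_that("genome_annotation rejects inconsistent inputs", {
  reps <- data.frame(id = "r", length = 100)
  expect_error(
    genome_annotation(reps, toy_genes("other", 1, 10)), "unknown replicon")
  expect_error(
    genome_annotation(reps, sequences = c(r = strrep("A", 99))),
    "disagrees")
  expect_error(
    genome_annotation(reps, sequences = c(r = strrep("X", 100))), "only")
})

test_that("extract_igrs finds gaps with the minimum-length rule", {
  ann <- toy_genome(c(chr = 300), toy_genes("chr", c(1, 161), c(100, 300)),
                    topology = "linear")
  igrs <- extract_igrs(ann, min_len = 60)
  expect_equal(nrow(igrs), 1)
  expect_equal(igrs$start, 101)
  expect_equal(igrs$end, 160)
  expect_equal(igrs$length, 60)

  # a 49 bp gap falls below the 60 bp rule
  ann2 <- toy_genome(c(chr = 300), toy_genes("chr", c(1, 150), c(100, 300)),
                     topology = "linear")
  expect_equal(nrow(extract_igrs(ann2, min_len = 60)), 0)
  expect_equal(extract_igrs(ann2, min_len = 40)$length, 49)
})

test_that("circular replicons wrap the terminal gap across the origin", {
  ann <- toy_genome(c(chr = 300), toy_genes("chr", 101, 200))
  igrs <- extract_igrs(ann, min_len = 60)
  expect_equal(nrow(igrs), 1)
  expect_equal(igrs$start, 201)
  expect_equal(igrs$end, 100)
  # brute force: number of positions not covered by the gene
  expect_equal(igrs$length, 300 - 100)

  # circular replicon without genes is one whole-length IGR
  ann0 <- toy_genome(c(chr = 500))
  igrs0 <- extract_igrs(ann0)
  expect_equal(igrs0$length, 500)
})

test_that("gene union and unfiltered gaps tile each replicon exactly", {
  withr::with_seed(4, {
    for (rep_i in 1:5) {
      L <- sample(200:600, 1)
      ngene <- sample(1:6, 1)
      starts <- sort(sample(seq_len(L - 20), ngene))
      ends <- pmin(L, starts + sample(10:80, ngene, replace = TRUE))
      ann <- toy_genome(c(chr = L), toy_genes("chr", starts, ends))
      igrs <- extract_igrs(ann, min_len = 1)
      covered <- integer(L)
      ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
      for (k in seq_along(ir)) {
        covered[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <-
          covered[IRanges::start(ir)[k]:IRanges::end(ir)[k]] + 1L
      }
      for (k in seq_len(nrow(igrs))) {
        pos <- if (igrs$start[k] <= igrs$end[k]) {
          igrs$start[k]:igrs$end[k]
        } else {
          c(igrs$start[k]:L, 1:igrs$end[k])
        }
        covered[pos] <- covered[pos] + 1L
      }
      expect_true(all(covered == 1L))
    }
  })
})

test_that("extract_igrs is idempotent and order-invariant", {
  genes <- toy_genes("chr", c(50, 400, 200), c(120, 480, 300))
  ann1 <- toy_genome(c(chr = 600), genes)
  ann2 <- toy_genome(c(chr = 600), genes[c(3, 1, 2), ])
  expect_equal(extract_igrs(ann1), extract_igrs(ann2))
  expect_equal(extract_igrs(ann1), extract_igrs(ann1))
})

test_that("igr_sequence returns forward-strand and wrapped subsequences", {
  reps <- data.frame(id = "r", length = 5, topology = "circular",
                     kind = "chromosome")
  ann <- genome_annotation(reps, sequences = c(r = "AACGT"))
  expect_equal(igr_sequence(list(replicon = "r", start = 2, end = 4), ann),
               "ACG")
  # wrapped region (4-2): positions 4,5,1,2
  expect_equal(igr_sequence(list(replicon = "r", start = 4, end = 2), ann),
               "GTAA")
  ann60 <- toy_genome(c(chr = 200))
  s <- igr_sequence(list(replicon = "chr", start = 41, end = 100), ann60)
  expect_equal(nchar(s), 60)
  ann_noseq <- genome_annotation(data.frame(id = "r", length = 5))
  expect_error(
    igr_sequence(list(replicon = "r", start = 1, end = 2), ann_noseq),
    "no sequences")
})

test_that("IGR writers emit 1-based TSV and 0-based half-open BED", {
  ann <- toy_genome(c(chr = 300), toy_genes("chr", c(1, 161), c(100, 300)),
                    topology = "linear")
  igrs <- extract_igrs(ann)
  dir <- withr::local_tempdir()
  write_igrs(igrs, ann, tsv = file.path(dir, "i.tsv"),
             bed = file.path(dir, "i.bed"))
  tsv <- read.table(file.path(dir, "i.tsv"), header = TRUE, sep = "\t")
  expect_equal(tsv$start, 101)
  bed <- read.table(file.path(dir, "i.bed"), sep = "\t")
  expect_equal(bed$V2, 100)  # 0-based start
  expect_equal(bed$V3, 160)  # half-open end
})
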