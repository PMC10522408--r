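test_that("FASTA reading upper-cases, maps ambiguity codes to N and keeps ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "acgtn"), f)
  asm <- read_fasta(f)
  expect_identical(names(asm), "s1")
  expect_identical(as.character(asm[["s1"]]), "ACGTN")

  writeLines(c(">a", "ACR"), f)
  expect_warning(asm2 <- read_fasta(f), "replaced by N")
  expect_identical(as.character(asm2[["a"]]), "ACN")
})

test_that("FASTA duplicate ids and empty files are hard errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round trip preserves records", {
  asm <- genome_assembly(c(s1 = rand_dna(150, seed = 1), s2 = rand_dna(90)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(asm, f)
  back <- read_fasta(f)
  expect_identical(unclass(back), unclass(asm))
})

test_that("GFF3 import converts coordinates and assigns per-scaffold ranks", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
    "s1\tsrc\tgene\t501\t600\t.\t+\t.\tID=g2",
    "s1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g3",
    "s1\tsrc\texon\t101\t140\t.\t+\t.\tID=g3.e1;Parent=g3",
    "s1\tsrc\texon\t161\t200\t.\t+\t.\tID=g3.e2;Parent=g3"), f)
  ann <- read_gff3(f)
  expect_identical(ann$start[ann$gene_id == "g1"], 0L)  # 1-based -> 0-based
  expect_identical(ann$end[ann$gene_id == "g1"], 9L)
  ranks <- setNames(ann$rank, ann$gene_id)
  expect_identical(ranks[c("g1", "g3", "g2")], c(g1 = 0L, g3 = 1L, g2 = 2L))
  expect_identical(nrow(ann$exons[[which(ann$gene_id == "g3")]]), 2L)
})

test_that("GFF3 exon outside its gene span names the offending gene", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tsrc\tgene\t1\t40\t.\t+\t.\tID=gX",
    "s1\tsrc\texon\t51\t60\t.\t+\t.\tID=gX.e1;Parent=gX"), f)
  expect_error(read_gff3(f), "gX")
})

test_that("gene ranks are a bijection onto 0..n-1 per scaffold", {
  ls <- plant_gene_landscape(3, 20, 2, 2, 2, seed = 8)
  for (sc in unique(ls$annot$scaffold)) {
    r <- sort(ls$annot$rank[ls$annot$scaffold == sc])
    expect_identical(r, seq_along(r) - 1L)
  }
})

test_that("homology filters apply e-value, OR-coverage and top-5 rules", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "q1\ts1\t90\t100\t5\t0\t1\t100\t1\t100\t1e-4\t50\t90\t90",   # e-value fail
    "q1\ts2\t90\t100\t5\t0\t1\t100\t1\t100\t1e-10\t80\t40\t60",  # OR coverage
    "q1\ts3\t90\t100\t5\t0\t1\t100\t1\t100\t1e-10\t80\t40\t40",  # both low
    "q1\tq1\t100\t100\t0\t0\t1\t100\t1\t100\t0\t200\t100\t100",  # self hit
    vapply(1:7, function(i) sprintf(
      "q2\tt%d\t90\t100\t5\t0\t1\t100\t1\t100\t1e-%d\t80\t60\t60",
      i, 5 + i), ""))
  writeLines(rows, f)
  h <- read_homology_table(f)
  expect_identical(h$subject_id[h$query_id == "q1"], "s2")
  q2 <- h[h$query_id == "q2", ]
  expect_identical(nrow(q2), 5L)                      # top five per query
  expect_false(is.unsorted(q2$evalue))                # ordered by e-value
  expect_identical(q2$subject_id, paste0("t", 7:3))
  expect_lte(nrow(h), 5L * length(unique(h$query_id)))
})

test_that("12-column tables need a lengths companion for coverage", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t90\t80\t5\t0\t1\t80\t1\t80\t1e-10\t80", f)
  expect_error(read_homology_table(f), "lengths")
  h <- read_homology_table(f, lengths = c(q1 = 100, s1 = 200))
  expect_equal(h$query_cov, 80)    # 80/100
  expect_equal(h$subject_cov, 40)
})

test_that("malformed homology rows are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t90\t100\t5\t0\t1\t100\t1\t100\t1e-10\t80\t60\t60",
               "bad\trow"), f)
  expect_error(read_homology_table(f), "line 2")
})

test_that("BED round trip is identity and zero-width records error", {
  fi <- feature_intervals(c("s1", "s2"), c(0L, 5L), c(10L, 25L), c("x", "y"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(fi, f)
  expect_identical(as.data.frame(read_bed(f)), as.data.frame(fi))
  first <- readLines(f)[1]
  expect_identical(first, "s1\t0\t10\tx")
  writeLines("s1\t5\t5\tz", f)
  expect_error(read_bed(f), "start >= end")
  expect_error(feature_intervals("s1", 5L, 5L, "z"), "start")
})
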