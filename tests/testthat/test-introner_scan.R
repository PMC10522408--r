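test_that("introns are extracted in transcription order with strand", {
  asm <- genome_assembly(c(s1 = rand_dna(300, seed = 14)))
  plus <- gene_annotation(data.frame(
    gene_id = "gp", scaffold = "s1", start = 0L, end = 60L, strand = "+",
    exons = I(list(matrix(c(0L, 10L, 20L, 30L, 40L, 60L), ncol = 2,
                          byrow = TRUE))), stringsAsFactors = FALSE))
  ip <- extract_introns(plus, asm)
  expect_identical(ip$intron_index, 1:2)
  expect_identical(ip$sequence[1], substr(asm[["s1"]], 11, 20))
  minus <- plus
  minus$strand <- "-"
  im <- extract_introns(minus, asm)
  expect_identical(im$sequence[1], rc(substr(asm[["s1"]], 31, 40)))
  expect_identical(im$sequence[2], rc(substr(asm[["s1"]], 11, 20)))
  single <- gene_annotation(data.frame(
    gene_id = "gs", scaffold = "s1", start = 0L, end = 30L, strand = "+",
    exons = I(list(matrix(c(0L, 30L), ncol = 2))), stringsAsFactors = FALSE))
  expect_identical(nrow(extract_introns(single, asm)), 0L)
})

test_that("inverted repeats are found with maximal arms and mismatch budget", {
  set.seed(22)
  arm <- "GATCC"
  intron <- paste0(arm, "TTTTTTTGGGGGGGCCCAAA", rc(arm))
  hit <- find_inverted_repeats(intron, min_arm = 5, end_window = 30)
  expect_identical(nrow(hit), 1L)
  expect_gte(hit$arm_len, 5L)
  # the reported arms satisfy the repeat relation when re-extracted
  a <- substr(intron, hit$a_start + 1, hit$a_end)
  b <- substr(intron, hit$b_start + 1, hit$b_end)
  expect_identical(b, rc(a))
  # pure poly-A has no inverted repeat (needs poly-T arm)
  expect_identical(nrow(find_inverted_repeats(strrep("A", 60),
                                              min_arm = 6)), 0L)
  # one planted mismatch is found at budget 1, rejected at 0
  arm8 <- "GATCCGTA"
  armb <- rc(arm8)
  substr(armb, 4, 4) <- if (substr(armb, 4, 4) == "A") "C" else "A"
  intr <- paste0(arm8, strrep("T", 20), armb)
  expect_identical(nrow(find_inverted_repeats(intr, min_arm = 8,
                                              max_mismatch = 0)), 0L)
  hit1 <- find_inverted_repeats(intr, min_arm = 8, max_mismatch = 1)
  expect_identical(nrow(hit1), 1L)
  expect_identical(hit1$mismatches, 1L)
})

test_that("direct repeats respect window and overlap rules", {
  intron <- paste0("TTAA", strrep("G", 30), "TTAA")
  hit <- find_direct_repeats(intron, min_arm = 4)
  expect_identical(nrow(hit), 1L)
  expect_identical(substr(intron, hit$a_start + 1, hit$a_end),
                   substr(intron, hit$b_start + 1, hit$b_end))
  # too short for two non-overlapping arms
  expect_identical(nrow(find_direct_repeats("TTAATT", min_arm = 4)), 0L)
  # repeat in the middle only, outside both end windows
  mid <- paste0(strrep("A", 40), "TTAACCGG", strrep("G", 5), "TTAACCGG",
                strrep("C", 40))
  expect_identical(nrow(find_direct_repeats(mid, min_arm = 8,
                                            end_window = 10)), 0L)
})

test_that("inverted hits map onto themselves under reverse complement", {
  set.seed(33)
  arm <- "GGATCCA"
  intron <- paste0(arm, rand_dna(16), rc(arm))
  h1 <- find_inverted_repeats(intron, min_arm = 7)
  h2 <- find_inverted_repeats(rc(intron), min_arm = 7)
  expect_identical(nrow(h1), 1L)
  expect_identical(nrow(h2), 1L)
  expect_identical(h1$arm_len, h2$arm_len)
  L <- nchar(intron)
  expect_identical(h2$a_start, L - h1$b_end)
  expect_identical(h2$b_end, L - h1$a_start)
})

test_that("planted introners are recovered end to end", {
  ls <- plant_gene_landscape(2, 12, 0, 0, 0, wgd = FALSE,
                             single_exon_fraction = 0, seed = 27)
  multi <- ls$annot$gene_id[vapply(ls$annot$exons, nrow, 1L) > 1]
  target <- multi[1]
  mod <- insert_introner(ls$annot, ls$assembly, target, 1, "GATCCG",
                         spacer_len = 8, inverted = TRUE, seed = 3)
  introns <- extract_introns(mod$annot, mod$assembly)
  iseq <- introns$sequence[introns$gene_id == target &
                             introns$intron_index == 1]
  hit <- find_inverted_repeats(iseq, min_arm = 6, end_window = nchar(iseq))
  expect_identical(nrow(hit), 1L)
  mod2 <- insert_introner(ls$annot, ls$assembly, target, 1, "TTGGCC",
                          spacer_len = 8, inverted = FALSE, seed = 3)
  introns2 <- extract_introns(mod2$annot, mod2$assembly)
  iseq2 <- introns2$sequence[introns2$gene_id == target &
                               introns2$intron_index == 1]
  expect_identical(nrow(find_direct_repeats(
    iseq2, min_arm = 6, end_window = nchar(iseq2))), 1L)
  # downstream coordinates shift by the insert length
  ins_len <- 20L    # two 6 nt arms + 8 nt spacer
  old <- ls$annot
  shifted <- mod$annot
  sc <- old$scaffold[old$gene_id == target]
  ins_pos <- mod$truth$genomic_insert_pos
  downstream <- old$gene_id[old$scaffold == sc & old$start >= ins_pos]
  for (g in downstream) {
    expect_identical(shifted$start[shifted$gene_id == g],
                     old$start[old$gene_id == g] + ins_len)
  }
})

test_that("reference motif scanning and gene statistics work together", {
  ls <- plant_gene_landscape(2, 10, 0, 0, 0, wgd = FALSE,
                             single_exon_fraction = 0, seed = 41)
  multi <- ls$annot$gene_id[vapply(ls$annot$exons, nrow, 1L) > 1]
  mod <- insert_introner(ls$annot, ls$assembly, multi[1], 1, "GATCCGTTAGC",
                         spacer_len = 5, inverted = TRUE, seed = 8)
  hits <- scan_introners(mod$annot, mod$assembly,
                         motifs = c(ie1 = "GATCCGTTAGC"))
  ref_hits <- hits[hits$repeat_type == "reference_motif", ]
  expect_identical(unique(ref_hits$gene_id), multi[1])
  # statistics restricted to reference-motif hits: one of the two TD genes
  stats <- ie_gene_stats(ref_hits, mod$annot,
                         td_blocks = list(structure(
                           list(scaffold = "x", genes = multi[1:2],
                                size = 2L), class = "td_block")))
  expect_equal(stats$pct_ie_td_genes, 50)
  none <- ie_gene_stats(hits[0, ], mod$annot)
  expect_equal(none$pct_ie_genes, 0)
})
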