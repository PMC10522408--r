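test_that("TD blocks are maximal runs of consecutive homologous genes", {
  ids <- paste0("g", 1:10)
  starts <- seq(0L, by = 1000L, length.out = 10)
  ann <- gene_annotation(data.frame(
    gene_id = ids, scaffold = "s1", start = starts, end = starts + 300L,
    strand = "+",
    exons = I(lapply(starts, function(s) matrix(c(s, s + 300L), ncol = 2))),
    stringsAsFactors = FALSE))
  hits <- mk_hits(c("g4", "g5"), c("g5", "g6"))   # ranks 3,4,5 consecutive
  blocks <- find_td_blocks(ann, hits)
  expect_length(blocks, 1)
  expect_identical(blocks[[1]]$genes, c("g4", "g5", "g6"))
  expect_identical(blocks[[1]]$size, 3L)
  # non-adjacent homologs do not form a block
  expect_length(find_td_blocks(ann, mk_hits("g4", "g6")), 0)
  # two separate runs on one scaffold give two blocks
  two <- find_td_blocks(ann, mk_hits(c("g1", "g8"), c("g2", "g9")))
  expect_length(two, 2)
})

test_that("codon alignment validates frames and stops, and places gaps", {
  cds <- "ATGAAATTTGGGCCC"
  aln <- align_codons(cds, cds)
  expect_identical(nrow(aln$codons), 5L)
  expect_false(any(aln$aln1 == "---"))
  # one deleted codon gives exactly one gap codon
  del <- "ATGAAAGGGCCC"
  aln2 <- align_codons(cds, del)
  expect_identical(sum(aln2$aln2 == "---"), 1L)
  expect_identical(nrow(aln2$codons), 4L)
  expect_error(align_codons("ATGA", cds), "divisible by 3")
  expect_error(align_codons("ATGTAAGGG", cds, id1 = "badseq"), "badseq")
  # terminal stop is trimmed silently
  aln3 <- align_codons(paste0(cds, "TAA"), cds)
  expect_identical(nrow(aln3$codons), 5L)
})

test_that("NG86 matches hand-counted synonymous example and conventions", {
  a <- strrep("GGT", 100)
  b <- paste0(strrep("GGT", 99), "GGC")
  r <- ng86(align_codons(a, b))
  # GGN is fourfold degenerate at position 3: one synonymous site per
  # codon, so S = 100, sd = 1, pS = 0.01, Jukes-Cantor corrected
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$s_sites, 100)
  expect_equal(r$ks, -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  expect_equal(r$omega, 0)
  ident <- ng86(align_codons(a, a))
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)
  expect_true(is.nan(ident$omega))
  # ka > 0 with ks = 0 is +Inf (the infinity the block mean ignores)
  nonsyn <- ng86(align_codons(strrep("AAA", 20),
                              paste0(strrep("AAA", 19), "GAA")))
  expect_identical(nonsyn$omega, Inf)
})

test_that("NG86 sites are conserved and the statistic is symmetric", {
  set.seed(3)
  for (i in 1:5) {
    cp <- evolve_codon_pair(80, 0.2, 0.5, seed = i * 7)
    aln <- align_codons(cp$cds1, cp$cds2)
    r12 <- ng86(aln)
    expect_equal(r12$s_sites + r12$n_sites, 3 * nrow(aln$codons))
    r21 <- ng86(align_codons(cp$cds2, cp$cds1))
    expect_equal(r12$ka, r21$ka, tolerance = 1e-12)
    expect_equal(r12$ks, r21$ks, tolerance = 1e-12)
  }
})

test_that("omega recovery covers the simulated truth", {
  est <- vapply(1:40, function(s) {
    cp <- evolve_codon_pair(300, 0.3, 0.2, seed = 1000 + s)
    ng86(align_codons(cp$cds1, cp$cds2))$omega
  }, 1.0)
  fin <- est[is.finite(est)]
  expect_gte(mean(fin), 0.15)
  expect_lte(mean(fin), 0.25)
})

test_that("block summaries ignore infinities and classify selection", {
  blk <- structure(list(scaffold = "s1", genes = c("x", "y", "z"), size = 3L,
                        pair_results = NULL, mean_omega = NA_real_,
                        mean_ks = NA_real_, selection_class = NA_character_),
                   class = "td_block")
  mk_res <- function(om, ks = 0.2) {
    structure(list(ka = if (is.finite(om)) om * ks else 1, ks = ks,
                   omega = om, n_sites = 1, s_sites = 1, nd = 0, sd = 0),
              class = "kaks_result")
  }
  filled <- summarize_td_block(blk, lapply(c(0.4, 0.6, Inf), mk_res))
  expect_equal(filled$mean_omega, 0.5)
  expect_identical(filled$selection_class, "purifying")
  # adding a ks = 0 (infinite omega) pair leaves the mean unchanged
  with_inf <- summarize_td_block(blk, lapply(c(0.4, 0.6, Inf, Inf), mk_res))
  expect_equal(with_inf$mean_omega, filled$mean_omega)
  undef <- summarize_td_block(blk, lapply(c(NaN, NaN), mk_res))
  expect_identical(undef$selection_class, "undefined")
  pos <- summarize_td_block(blk, lapply(c(1.5, 2.5), mk_res))
  expect_equal(pos$mean_omega, 2)
  expect_identical(pos$selection_class, "positive")
})

test_that("TD summary table counts genes, sizes and single-exon fractions", {
  ls <- plant_gene_landscape(3, 40, 5, 0, 0, wgd = FALSE,
                             single_exon_fraction = 0.2, seed = 19)
  blocks <- find_td_blocks(ls$annot, ls$hits)
  tab <- td_summary_table(ls$annot, blocks)
  expect_identical(tab$n_td_blocks, 5L)
  expect_identical(tab$n_td_genes, 10L)
  expect_equal(tab$median_block_size, 2)
  expect_identical(tab$max_block_size, 2L)
  expect_equal(tab$pct_single_exon, 100 * round(0.2 * 120) / 120)
  # brute-force recount of block-size statistics
  sizes <- vapply(blocks, `[[`, 1L, "size")
  expect_equal(tab$median_block_size, median(sizes))
  expect_identical(tab$max_block_size, max(sizes))
  # hand-built sizes {2,2,3}
  ids <- paste0("g", 1:12)
  starts <- seq(0L, by = 500L, length.out = 12)
  ann <- gene_annotation(data.frame(
    gene_id = ids, scaffold = "s1", start = starts, end = starts + 200L,
    strand = "+",
    exons = I(lapply(starts, function(s) matrix(c(s, s + 200L), ncol = 2))),
    stringsAsFactors = FALSE))
  h <- mk_hits(c("g1", "g4", "g7", "g8"), c("g2", "g5", "g8", "g9"))
  b <- find_td_blocks(ann, h)
  t2 <- td_summary_table(ann, b)
  expect_identical(t2$n_td_genes, 7L)
  expect_identical(t2$n_td_blocks, 3L)
  expect_equal(t2$median_block_size, 2)
  expect_identical(t2$max_block_size, 3L)
})
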