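# one gene per 1000 bp, ids in rank order on one scaffold
linear_annot <- function(ids, scaffold = "s1") {
  n <- length(ids)
  starts <- seq(0L, by = 1000L, length.out = n)
  gene_annotation(data.frame(
    gene_id = ids, scaffold = scaffold, start = starts,
    end = starts + 500L, strand = "+",
    exons = I(lapply(starts, function(s) matrix(c(s, s + 500L), ncol = 2))),
    stringsAsFactors = FALSE))
}

test_that("collinear chains are found in both orientations and gated at 5", {
  a <- linear_annot(paste0("a", 1:10), "sa")
  b <- linear_annot(paste0("b", 1:10), "sb")
  hits <- mk_hits(paste0("a", 1:10), paste0("b", 1:10))
  blocks <- detect_collinear_blocks(a, b, hits)
  expect_length(blocks, 1)
  expect_identical(blocks[[1]]$n_anchors, 10L)
  expect_identical(blocks[[1]]$orientation, "same")

  b_rev <- linear_annot(paste0("b", 10:1), "sb")
  blocks_inv <- detect_collinear_blocks(a, b_rev, hits)
  expect_length(blocks_inv, 1)
  expect_identical(blocks_inv[[1]]$orientation, "inverted")

  few <- mk_hits(paste0("a", 1:4), paste0("b", 1:4))
  expect_length(detect_collinear_blocks(a, b, few), 0)
})

test_that("block detection is symmetric with roles swapped", {
  a <- linear_annot(paste0("a", 1:8), "sa")
  b <- linear_annot(paste0("b", c(1:3, 5:8, 4)), "sb")
  hits <- mk_hits(paste0("a", 1:8), paste0("b", 1:8))
  ab <- detect_collinear_blocks(a, b, hits)
  ba <- detect_collinear_blocks(b, a, hits)
  expect_identical(length(ab), length(ba))
  expect_identical(sort(ab[[1]]$anchors$gene_a), sort(ba[[1]]$anchors$gene_b))
})

test_that("every anchor pair is backed by an input hit", {
  ls <- plant_gene_landscape(4, 60, 6, 6, 6, wgd = TRUE, seed = 31)
  blocks <- detect_collinear_blocks(ls$annot, ls$annot, ls$hits,
                                    mode = "intra")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  hk <- key(ls$hits$query_id, ls$hits$subject_id)
  for (bl in blocks) {
    expect_true(all(key(bl$anchors$gene_a, bl$anchors$gene_b) %in% hk))
  }
})

test_that("duplication classes follow the distance rules and precedence", {
  ann <- linear_annot(paste0("g", 1:25))
  # g1/g2 adjacent; g3/g9 five intervening; g10/g22 eleven intervening
  hits <- mk_hits(c("g1", "g3", "g10"), c("g2", "g9", "g22"))
  lab <- classify_duplicates(ann, hits)
  got <- setNames(lab$label, lab$gene_id)
  expect_identical(unname(got[c("g1", "g2")]), rep("tandem", 2))
  expect_identical(unname(got[c("g3", "g9")]), rep("proximal", 2))
  expect_identical(unname(got[c("g10", "g22")]), rep("dispersed", 2))
  expect_identical(unname(got["g25"]), "singleton")
  # proximal boundary: exactly 10 intervening genes stays proximal,
  # 11 becomes dispersed
  h2 <- mk_hits(c("g1", "g12"), c("g12", "g24"))
  got2 <- setNames(classify_duplicates(ann, h2)$label, ann$gene_id)
  expect_identical(unname(got2["g1"]), "proximal")    # ranks 0 and 11
  expect_identical(unname(got2["g24"]), "dispersed")  # ranks 11 and 23
  expect_error(classify_duplicates(ann, mk_hits("g1", "zz")),
               "absent from annotation")
})

test_that("labels partition genes and wgd count is monotone in min_anchors", {
  ls <- plant_gene_landscape(5, 80, 10, 10, 10, wgd = TRUE, seed = 13)
  lab <- classify_duplicates(ls$annot, ls$hits)
  expect_identical(sort(lab$gene_id), sort(ls$annot$gene_id))
  expect_identical(sum(duplication_summary(lab)), nrow(ls$annot))
  n_wgd <- vapply(c(5L, 10L, 40L), function(m) {
    sum(classify_duplicates(ls$annot, ls$hits, min_anchors = m)$label == "wgd")
  }, 1L)
  expect_true(all(diff(n_wgd) <= 0))
})

test_that("planted landscape labels are recovered near-perfectly", {
  ls <- plant_gene_landscape(5, 100, 20, 20, 20, wgd = TRUE,
                             single_exon_fraction = 0.2, seed = 17)
  lab <- classify_duplicates(ls$annot, ls$hits)
  pred <- setNames(lab$label, lab$gene_id)[names(ls$truth$labels)]
  expect_gte(mean(pred == ls$truth$labels), 0.98)
})

test_that("Ka+Ks deduplication keeps the most similar partner and refilters", {
  a <- linear_annot(paste0("a", 1:6), "sa")
  b <- linear_annot(paste0("b", 1:6), "sb")
  hits <- rbind(mk_hits(paste0("a", 1:6), paste0("b", 1:6)),
                mk_hits("a1", "b2"))
  blocks <- detect_collinear_blocks(a, b, homology_hits(hits))
  expect_length(blocks, 1)
  lookup <- data.frame(gene_a = paste0("a", 1:6),
                       gene_b = paste0("b", 1:6),
                       ka_ks = c(0.1, 0.2, 0.1, 0.1, 0.1, 0.1))
  out <- dedup_wgd_pairs(blocks, lookup)
  expect_length(out, 1)
  expect_identical(out[[1]]$n_anchors, 6L)       # no multi-partner genes here

  # a1 anchored to both b1 (0.1) and b6 (0.8): only (a1, b1) survives
  anchors <- data.frame(gene_a = c("a1", "a2", "a3", "a4", "a5", "a1"),
                        gene_b = c("b1", "b2", "b3", "b4", "b5", "b6"),
                        rank_a = c(0L, 1L, 2L, 3L, 4L, 5L),
                        rank_b = 0:5, stringsAsFactors = FALSE)
  bl <- list(collinear_block("sa", "sb", anchors, "same"))
  lk <- data.frame(gene_a = c("a1", "a2", "a3", "a4", "a5", "a1"),
                   gene_b = c("b1", "b2", "b3", "b4", "b5", "b6"),
                   ka_ks = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.8))
  out2 <- dedup_wgd_pairs(bl, lk)
  expect_length(out2, 1)
  expect_identical(out2[[1]]$n_anchors, 5L)
  expect_false("b6" %in% out2[[1]]$anchors$gene_b)

  # dropping below five anchors drops the block
  anchors6 <- data.frame(gene_a = c("a1", "a1", "a2", "a2", "a3", "a3"),
                         gene_b = paste0("b", 1:6),
                         rank_a = c(0L, 0L, 1L, 1L, 2L, 2L), rank_b = 0:5,
                         stringsAsFactors = FALSE)
  # strictly increasing rank_a required; construct by rank trick
  anchors6$rank_a <- 0:5
  bl6 <- list(collinear_block("sa", "sb", anchors6, "same"))
  lk6 <- data.frame(gene_a = anchors6$gene_a, gene_b = anchors6$gene_b,
                    ka_ks = c(0.1, 0.8, 0.1, 0.8, 0.1, 0.8))
  expect_length(dedup_wgd_pairs(bl6, lk6), 0)
  # missing Ka+Ks scores as +Inf with a warning
  expect_warning(dedup_wgd_pairs(bl, lk[1:5, ]), "\\+Inf")
})
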