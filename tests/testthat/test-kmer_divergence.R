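test_that("k-mer counting handles N windows, strands and conservation", {
  p <- count_kmers(genome_assembly(c(s = "ACGT")), k = 2, canonical = FALSE)
  expect_identical(setNames(p$counts, intradiv:::decode_kmers(p$codes, 2)),
                   c(AC = 1L, CG = 1L, GT = 1L))
  p2 <- count_kmers(genome_assembly(c(s = "AANAA")), k = 2, canonical = FALSE)
  expect_identical(setNames(p2$counts, intradiv:::decode_kmers(p2$codes, 2)),
                   c(AA = 2L))
  p3 <- count_kmers(genome_assembly(c(s = "AAA")), k = 2, canonical = TRUE)
  expect_identical(setNames(p3$counts, intradiv:::decode_kmers(p3$codes, 2)),
                   c(AA = 2L))
  # conservation: total counts == number of N-free windows
  seqs <- genome_assembly(c(a = rand_dna(400, seed = 3), b = "ACGTNNACGTACG"))
  for (k in c(2, 5, 11)) {
    pr <- count_kmers(seqs, k = k)
    n_win <- sum(vapply(as.character(seqs), function(s) {
      b <- is.na(intradiv:::dna_to_int(s))
      n <- nchar(s) - k + 1
      if (n < 1) return(0L)
      sum(vapply(seq_len(n), function(i) !any(b[i:(i + k - 1)]), TRUE))
    }, 1L))
    expect_identical(pr$n_positions, n_win)
    expect_identical(sum(pr$counts), n_win)
  }
  expect_warning(count_kmers(genome_assembly(c(s = "ACG")), k = 10),
                 "empty profile")
})

test_that("D2S equals the brute-force word loop and self-distance is zero", {
  set.seed(11)
  for (k in c(2, 3, 5)) {
    s1 <- rand_dna(300)
    s2 <- rand_dna(300)
    p1 <- count_kmers(genome_assembly(c(x = s1)), k = k, canonical = FALSE)
    p2 <- count_kmers(genome_assembly(c(x = s2)), k = k, canonical = FALSE)
    expect_equal(d2s_similarity(p1, p2), brute_d2s(s1, s2, k),
                 tolerance = 1e-10)
    expect_lt(abs(d2s_distance(p1, p1)), 1e-12)
    d12 <- suppressWarnings(d2s_distance(p1, p2))
    d21 <- suppressWarnings(d2s_distance(p2, p1))
    if (is.finite(d12)) {
      expect_equal(d12, d21, tolerance = 1e-12)
    } else {
      expect_identical(d12, d21)   # unrelated profiles: both +Inf
    }
  }
  # self-similarity identity: D2S(X,X) = sum |X~| / sqrt(2)
  p <- count_kmers(genome_assembly(c(x = rand_dna(200))), k = 3,
                   canonical = FALSE)
  u <- p$codes
  Xc <- p$counts - p$n_positions *
    intradiv:::.kmer_bg_prob(u, 3, p$bg_freq)
  expect_equal(d2s_similarity(p, p), sum(abs(Xc)) / sqrt(2),
               tolerance = 1e-10)
})

test_that("mismatched profiles are rejected", {
  p2 <- count_kmers(genome_assembly(c(x = rand_dna(50, seed = 1))), k = 2)
  p3 <- count_kmers(genome_assembly(c(x = rand_dna(50))), k = 3)
  expect_error(d2s_similarity(p2, p3), "different k")
})

test_that("d increases with substitution rate on synthetic pairs", {
  d <- vapply(c(0.01, 0.05, 0.10), function(p) {
    gp <- make_genome_pair(L = 100000, p_sub = p, seed = 42)
    d2s_distance(count_kmers(gp$genome1), count_kmers(gp$genome2))
  }, 1.0)
  expect_true(all(diff(d) > 0))
  expect_gt(d[1], 0)
})

test_that("core k-mers and x behave on identity, disjointness and arithmetic", {
  g <- genome_assembly(c(s = rand_dna(500, seed = 5)))
  p <- count_kmers(g, k = 5)
  rep2 <- core_kmers(list(a = p, b = p))
  expect_equal(unname(rep2$x), c(100, 100))
  pa <- count_kmers(genome_assembly(c(s = strrep("A", 50))), k = 4)
  pc <- count_kmers(genome_assembly(c(s = strrep("AC", 25))), k = 4)
  expect_equal(unname(core_kmers(list(pa, pc))$x), c(0, 0))
  # synthetic distinct-count arithmetic: |A|=10, |B|=20, overlap 5
  mk <- function(codes) {
    structure(list(k = 23L, canonical = TRUE, codes = as.numeric(codes),
                   counts = rep(1L, length(codes)),
                   n_positions = length(codes),
                   bg_freq = rep(0.25, 4)), class = "kmer_profile")
  }
  repx <- core_kmers(list(A = mk(1:10), B = mk(6:25)))
  expect_equal(unname(repx$x), c(50, 25))
  expect_error(core_kmers(list(p)), "at least two")
})

test_that("x is invariant to scaffold order and within-isolate duplication", {
  s1 <- rand_dna(300, seed = 7)
  s2 <- rand_dna(300)
  other <- count_kmers(genome_assembly(c(z = rand_dna(300))), k = 7)
  a1 <- count_kmers(genome_assembly(c(p = s1, q = s2)), k = 7)
  a2 <- count_kmers(genome_assembly(c(q = s2, p = s1)), k = 7)
  a3 <- count_kmers(genome_assembly(c(p = s1, q = s2, p2 = s1)), k = 7)
  x1 <- core_kmers(list(a1, other))$x
  expect_equal(unname(core_kmers(list(a2, other))$x), unname(x1))
  expect_equal(unname(core_kmers(list(a3, other))$x), unname(x1))
})

test_that("core k-mer occurrences map to BED with strand awareness", {
  asm <- genome_assembly(c(s1 = "AAA"))
  hits <- map_core_kmers_to_bed(asm, core = "AA", canonical = FALSE)
  expect_identical(hits$start, c(0L, 1L))
  expect_identical(hits$end, c(2L, 3L))
  # canonical matching finds the reverse complement
  rc_hits <- map_core_kmers_to_bed(genome_assembly(c(s1 = "TTT")),
                                   core = "AA", canonical = TRUE)
  expect_identical(rc_hits$start, c(0L, 1L))
  empty <- map_core_kmers_to_bed(asm, core = character(0), canonical = FALSE)
  expect_identical(nrow(empty), 0L)
})

test_that("interval intersection follows half-open semantics", {
  A <- feature_intervals("s1", 0L, 10L, "a")
  B <- feature_intervals("s1", 5L, 15L, "b")
  out <- intersect_features(A, B)
  expect_identical(c(out$start, out$end), c(5L, 10L))
  expect_identical(nrow(intersect_features(
    feature_intervals("s1", 0L, 5L), feature_intervals("s1", 5L, 9L))), 0L)
  inner <- feature_intervals("s1", 2L, 4L, "in")
  outer <- feature_intervals("s1", 0L, 10L, "out")
  got <- intersect_features(inner, outer)
  expect_identical(c(got$start, got$end), c(2L, 4L))
})
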