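# Shared fixture builders and independent oracles.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Independent brute-force D2S oracle: loops over all 4^k words, counting
# occurrences by direct substring comparison and centering by a zero-order
# background; words observed in neither sequence contribute nothing (the
# statistic is defined over the union of observed words).
brute_d2s <- function(s1, s2, k) {
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1],
                 1, paste, collapse = "")
  wincount <- function(s) {
    n <- nchar(s) - k + 1L
    table(factor(substring(s, 1:n, k:(n + k - 1L)), levels = words))
  }
  bg <- function(s) {
    t <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    as.numeric(t / sum(t))
  }
  X <- as.numeric(wincount(s1))
  Y <- as.numeric(wincount(s2))
  b1 <- bg(s1); b2 <- bg(s2)
  n1 <- nchar(s1) - k + 1L
  n2 <- nchar(s2) - k + 1L
  total <- 0
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  for (i in seq_along(words)) {
    if (X[i] == 0 && Y[i] == 0) next
    letters_i <- base_idx[strsplit(words[i], "")[[1]]]
    Xc <- X[i] - n1 * prod(b1[letters_i])
    Yc <- Y[i] - n2 * prod(b2[letters_i])
    den <- sqrt(Xc^2 + Yc^2)
    if (den > 0) total <- total + Xc * Yc / den
  }
  total
}

# a minimal two-scaffold annotation built in code
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    scaffold = c("s1", "s1", "s2"),
    start = c(0L, 100L, 10L), end = c(50L, 180L, 90L),
    strand = c("+", "-", "+"),
    exons = I(list(matrix(c(0L, 50L), ncol = 2),
                   matrix(c(100L, 130L, 150L, 180L), ncol = 2, byrow = TRUE),
                   matrix(c(10L, 90L), ncol = 2))),
    stringsAsFactors = FALSE))
}

# homology hit rows with sensible defaults
mk_hits <- function(q, s, evalue = 1e-20, bitscore = 100, qcov = 90,
                    scov = 90, pid = 95, len = 100L) {
  n <- length(q)
  homology_hits(data.frame(
    query_id = q, subject_id = s, pct_identity = rep_len(pid, n),
    aln_len = rep_len(len, n), evalue = rep_len(evalue, n),
    bitscore = rep_len(bitscore, n), query_cov = rep_len(qcov, n),
    subject_cov = rep_len(scov, n), stringsAsFactors = FALSE))
}

# a compact three-stage pipeline run used by determinism checks
small_sim <- list(L = 10000L, p_sub = 0.01, n_scaffolds = 2L,
                  genes_per_scaffold = 20L, n_tandem = 2L, n_proximal = 2L,
                  n_dispersed = 2L, wgd = TRUE, single_exon_fraction = 0.3)

run_all_stages <- function(root, seed) {
  sim_dir <- file.path(root, "sim")
  run_simulate(list(seed = seed, out_dir = sim_dir, sim = small_sim))
  run_divergence(list(
    seed = seed, out_dir = file.path(root, "div"),
    isolates = list(iso1 = list(fasta = file.path(sim_dir, "iso1.fasta")),
                    iso2 = list(fasta = file.path(sim_dir, "iso2.fasta"))),
    min_report_len = c(100, 1000)))
  run_duplication(list(
    seed = seed, out_dir = file.path(root, "dup"),
    isolates = list(
      a = list(fasta = file.path(sim_dir, "land_a.fasta"),
               gff3 = file.path(sim_dir, "land_a.gff3"),
               cds = file.path(sim_dir, "land_a_cds.fasta"),
               homology = file.path(sim_dir, "land_a_hits.tsv")),
      b = list(fasta = file.path(sim_dir, "land_b.fasta"),
               gff3 = file.path(sim_dir, "land_b.gff3"),
               cds = file.path(sim_dir, "land_b_cds.fasta"),
               homology = file.path(sim_dir, "land_b_hits.tsv"))),
    cross_homology = file.path(sim_dir, "cross_hits.tsv"),
    inflations = c(1.5, 4)))
  root
}
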