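# Tandem-duplication (TD) block detection, codon alignment, Nei-Gojobori
# (1986) Ka/Ks with Jukes-Cantor correction, and per-block selection
# summaries (mean omega over finite values, infinity-ignoring).

# --- genetic-code machinery -------------------------------------------------

.kaks_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (!is.null(.kaks_env$codons)) return(invisible())
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  syn_sites <- numeric(length(codons))
  names(syn_sites) <- codons
  for (ci in seq_along(codons)) {
    cd <- strsplit(codons[ci], "")[[1]]
    s <- 0
    for (pos in 1:3) {
      for (alt in setdiff(DNA_BASES, cd[pos])) {
        mut <- cd
        mut[pos] <- alt
        mutc <- paste(mut, collapse = "")
        # changes to stop codons count as nonsynonymous
        if (gc_map[[mutc]] != "*" && gc_map[[mutc]] == aa[ci]) s <- s + 1 / 3
      }
    }
    syn_sites[ci] <- s
  }
  .kaks_env$codons <- codons
  .kaks_env$aa <- setNames(aa, codons)
  .kaks_env$syn_sites <- syn_sites
  .kaks_env$diff_cache <- new.env(parent = emptyenv())
  invisible()
}

# (nd, sd) for one codon pair: equal-weight average over all minimal
# substitution pathways, excluding pathways through stop codons (all
# pathways used if every one is blocked)
.codon_pair_diffs <- function(c1, c2) {
  .codon_table()
  key <- paste0(c1, c2)
  hit <- .kaks_env$diff_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- .kaks_env$aa
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  dpos <- which(a1 != a2)
  d <- length(dpos)
  if (d == 0L) {
    res <- c(nd = 0, sd = 0)
  } else {
    perms <- if (d == 1L) list(dpos) else {
      if (d == 2L) list(dpos, rev(dpos)) else {
        idx <- list()
        for (p in seq_len(6)) idx[[p]] <- dpos[.perm3[[p]]]
        idx
      }
    }
    path_nd <- path_sd <- numeric(0)
    path_ok <- logical(0)
    for (ord in perms) {
      cur <- a1
      nd <- sd <- 0
      ok <- TRUE
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- a2[pos]
        from <- paste(cur, collapse = "")
        to <- paste(nxt, collapse = "")
        if (aa[[to]] == "*" || aa[[from]] == "*") ok <- FALSE
        if (aa[[from]] != "*" && aa[[to]] != "*" && aa[[from]] == aa[[to]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      path_nd <- c(path_nd, nd)
      path_sd <- c(path_sd, sd)
      path_ok <- c(path_ok, ok)
    }
    use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
    res <- c(nd = mean(path_nd[use]), sd = mean(path_sd[use]))
  }
  assign(key, res, .kaks_env$diff_cache)
  res
}

.perm3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

.split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

.validate_cds <- function(cds, id) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length of ", id, " is not divisible by 3")
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS ", id, " contains non-ACGT characters")
  }
  codons <- .split_codons(cds)
  .codon_table()
  aas <- .kaks_env$aa[codons]
  if (length(codons) && aas[length(codons)] == "*") {
    codons <- codons[-length(codons)]   # trim terminal stop
    aas <- aas[-length(aas)]
  }
  if (any(aas == "*")) {
    stop("internal stop codon in CDS ", id)
  }
  paste(codons, collapse = "")
}

# --- operations -------------------------------------------------------------

#' Find tandem-duplication blocks
#'
#' A TD block is a maximal run of two or more genes at consecutive ranks
#' on one scaffold in which every adjacent gene pair is homologous
#' (present in the filtered hit table).
#'
#' @param annot A [gene_annotation()].
#' @param hits Filtered within-genome [homology_hits()].
#' @return List of `td_block` objects (fields `scaffold`, `genes`, `size`;
#'   pair-level Ka/Ks left unfilled).
#' @export
find_td_blocks <- function(annot, hits) {
  if (nrow(hits) == 0L) return(list())
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  hk <- unique(key(hits$query_id, hits$subject_id))
  blocks <- list()
  for (sc in unique(annot$scaffold)) {
    g <- annot[annot$scaffold == sc, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    if (nrow(g) < 2L) next
    adj <- key(g$gene_id[-nrow(g)], g$gene_id[-1]) %in% hk
    r <- rle(adj)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      genes <- g$gene_id[starts[i]:(ends[i] + 1L)]
      blocks[[length(blocks) + 1L]] <- structure(
        list(scaffold = sc, genes = genes, size = length(genes),
             pair_results = NULL, mean_omega = NA_real_,
             mean_ks = NA_real_, selection_class = NA_character_),
        class = "td_block")
    }
  }
  blocks
}

#' @export
print.td_block <- function(x, ...) {
  cat("td_block:", x$scaffold, "|", x$size, "genes",
      if (!is.na(x$mean_omega)) paste0("| mean omega ",
                                       signif(x$mean_omega, 3)) else "", "\n")
  invisible(x)
}

#' Align two coding sequences codon-wise
#'
#' The CDSs (in frame, terminal stop trimmed, no internal stops) are
#' translated, globally aligned as proteins (BLOSUM62, affine gaps: open
#' 11, extend 1) and the alignment is back-translated to codons.  Gapped
#' codon columns are recorded but excluded from Ka/Ks.
#'
#' @param cds1,cds2 In-frame coding sequences (character strings).
#' @param id1,id2 Names used in error messages.
#' @return Object of class `codon_alignment`: list with aligned codon
#'   vectors `aln1`, `aln2` (gap codon `"---"`) and `codons`, a
#'   data frame of gap-free codon columns.
#' @export
align_codons <- function(cds1, cds2, id1 = "seq1", id2 = "seq2") {
  cds1 <- .validate_cds(cds1, id1)
  cds2 <- .validate_cds(cds2, id2)
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds1)))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(cds2)))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  co1 <- .split_codons(cds1)
  co2 <- .split_codons(cds2)
  aln1 <- aln2 <- character(length(a1))
  i1 <- i2 <- 0L
  for (i in seq_along(a1)) {
    if (a1[i] == "-") aln1[i] <- "---" else {
      i1 <- i1 + 1L
      aln1[i] <- co1[i1]
    }
    if (a2[i] == "-") aln2[i] <- "---" else {
      i2 <- i2 + 1L
      aln2[i] <- co2[i2]
    }
  }
  ok <- aln1 != "---" & aln2 != "---"
  structure(list(aln1 = aln1, aln2 = aln2,
                 codons = data.frame(c1 = aln1[ok], c2 = aln2[ok],
                                     stringsAsFactors = FALSE)),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous site counts per codon are the per-position fractions of the
#' three possible nucleotide changes that are synonymous (changes to stop
#' codons count as nonsynonymous), averaged between the two sequences.
#' Differences per codon average all minimal substitution pathways with
#' equal weight, excluding pathways through stop codons.  Proportions are
#' Jukes-Cantor corrected: \eqn{d = -\frac{3}{4}\ln(1-\frac{4}{3}p)}.
#' Conventions for \eqn{\omega = Ka/Ks}: `NaN` (undefined) when
#' `ka == ks == 0`; `+Inf` when `ka > 0, ks == 0`; a rate is `NaN` when
#' its proportion is >= 3/4 (correction undefined).
#'
#' @param aln A [align_codons()] result (or any list with a `codons`
#'   data frame of gap-free codon pairs).
#' @return Object of class `kaks_result`: list with `ka`, `ks`, `omega`,
#'   `n_sites`, `s_sites`, `nd`, `sd`.
#' @export
ng86 <- function(aln) {
  codons <- aln$codons
  if (nrow(codons) == 0L) stop("no gap-free codon columns")
  .codon_table()
  ss <- .kaks_env$syn_sites
  s_sites <- sum((ss[codons$c1] + ss[codons$c2]) / 2)
  n_sites <- 3 * nrow(codons) - s_sites
  nd <- sd <- 0
  for (i in seq_len(nrow(codons))) {
    dd <- .codon_pair_diffs(codons$c1[i], codons$c2[i])
    nd <- nd + dd[["nd"]]
    sd <- sd + dd[["sd"]]
  }
  jc <- function(p) {
    if (p >= 0.75) return(NaN)
    -0.75 * log(1 - 4 * p / 3)
  }
  pN <- nd / n_sites
  pS <- if (s_sites > 0) sd / s_sites else NaN
  ka <- jc(pN)
  ks <- jc(pS)
  omega <- if (is.nan(ka) || is.nan(ks)) {
    NaN
  } else if (ks == 0 && ka == 0) {
    NaN
  } else if (ks == 0) {
    Inf
  } else {
    ka / ks
  }
  structure(list(ka = ka, ks = ks, omega = omega, n_sites = n_sites,
                 s_sites = s_sites, nd = nd, sd = sd),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("kaks_result: ka = %.4g, ks = %.4g, omega = %.4g\n",
              x$ka, x$ks, x$omega))
  invisible(x)
}

#' Compute pairwise Ka/Ks for all gene pairs of a TD block
#'
#' @param block A `td_block` from [find_td_blocks()].
#' @param cds Named character vector of in-frame CDS keyed by gene id.
#' @return The block with `pair_results` filled (one [ng86()] result per
#'   unordered gene pair) and summary fields set via
#'   [summarize_td_block()].
#' @export
score_td_block <- function(block, cds) {
  missing <- setdiff(block$genes, names(cds))
  if (length(missing)) {
    stop("no CDS for gene(s): ", paste(head(missing, 5), collapse = ", "))
  }
  pairs <- utils::combn(block$genes, 2)
  results <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    r <- ng86(align_codons(cds[[g1]], cds[[g2]], g1, g2))
    r$gene_a <- g1
    r$gene_b <- g2
    r
  })
  summarize_td_block(block, results)
}

#' Summarise a TD block from its pairwise Ka/Ks results
#'
#' Mean omega is computed over finite omega values only: +Inf (ks = 0
#' with ka > 0) and NaN (0/0) pairs are ignored.  The selection class is
#' `purifying` (mean omega < 1), `positive` (> 1), `neutral` (= 1) or
#' `undefined` (no finite omega).
#'
#' @param block A `td_block`.
#' @param pair_results List of [ng86()] results for the block's gene
#'   pairs.
#' @return The filled `td_block`.
#' @export
summarize_td_block <- function(block, pair_results) {
  om <- vapply(pair_results, `[[`, 1.0, "omega")
  ks <- vapply(pair_results, `[[`, 1.0, "ks")
  fin_om <- om[is.finite(om)]
  fin_ks <- ks[is.finite(ks)]
  block$pair_results <- pair_results
  block$mean_omega <- if (length(fin_om)) mean(fin_om) else NA_real_
  block$mean_ks <- if (length(fin_ks)) mean(fin_ks) else NA_real_
  block$selection_class <- if (length(fin_om) == 0L) {
    "undefined"
  } else if (block$mean_omega < 1) {
    "purifying"
  } else if (block$mean_omega > 1) {
    "positive"
  } else {
    "neutral"
  }
  block
}

#' Per-genome tandem-duplication summary
#'
#' Reports the TD gene and block counts, block-size statistics,
#' single-exon gene statistics, and (when blocks carry mean omega) the
#' fraction of blocks under purifying (mean omega < 1) versus positive
#' (mean omega > 1) selection.
#'
#' @param annot A [gene_annotation()].
#' @param blocks List of `td_block` objects for that genome.
#' @return One-row data frame with columns `n_genes`, `n_td_genes`,
#'   `pct_td_genes`, `n_td_blocks`, `median_block_size`,
#'   `max_block_size`, `n_single_exon`, `pct_single_exon`,
#'   `pct_single_exon_td`, `frac_blocks_purifying`,
#'   `frac_blocks_positive`.
#' @export
td_summary_table <- function(annot, blocks) {
  td_genes <- unique(unlist(lapply(blocks, `[[`, "genes")))
  sizes <- vapply(blocks, `[[`, 1L, "size")
  ne <- n_exons(annot)
  single <- names(ne)[ne == 1L]
  om <- vapply(blocks, function(b) b$mean_omega %||% NA_real_, 1.0)
  has_om <- !is.na(om)
  data.frame(
    n_genes = nrow(annot),
    n_td_genes = length(td_genes),
    pct_td_genes = 100 * length(td_genes) / nrow(annot),
    n_td_blocks = length(blocks),
    median_block_size = if (length(sizes)) median(sizes) else NA_real_,
    max_block_size = if (length(sizes)) max(sizes) else NA_integer_,
    n_single_exon = length(single),
    pct_single_exon = 100 * length(single) / nrow(annot),
    pct_single_exon_td = if (length(td_genes)) {
      100 * length(intersect(single, td_genes)) / length(td_genes)
    } else NA_real_,
    frac_blocks_purifying = if (any(has_om)) {
      sum(om[has_om] < 1) / sum(has_om)
    } else NA_real_,
    frac_blocks_positive = if (any(has_om)) {
      sum(om[has_om] > 1) / sum(has_om)
    } else NA_real_)
}
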