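# Synthetic-data generators with complete ground truth: diverged genome
# pairs, gene landscapes with planted duplication classes, codon pairs
# evolved at controlled Ks and omega, intronic introner insertions, and
# two-isolate protein similarity graphs.  All generators are
# bit-reproducible from (parameters, seed).

#' Generate a pair of diverged genome assemblies
#'
#' An ancestor sequence is drawn i.i.d. at the requested GC content; the
#' second copy receives Bernoulli(`p_sub`) substitutions (uniform over
#' the three alternative bases), then `n_inversions` random segment
#' inversions, then geometric-length indels at per-base rate `p_indel`.
#' Every event is recorded in the truth log.
#'
#' @param L Ancestor length in bp.
#' @param gc GC content of the ancestor (default 0.5).
#' @param p_sub Per-base substitution probability (0 <= p_sub < 0.75).
#' @param p_indel Per-base indel initiation probability.
#' @param n_inversions Number of random segment inversions.
#' @param seed Integer seed.
#' @return List with `genome1`, `genome2` ([genome_assembly()], one
#'   scaffold `chr1` each) and `truth` (substitution positions on the
#'   ancestor, indel and inversion records, realised rates).
#' @export
make_genome_pair <- function(L, gc = 0.5, p_sub = 0, p_indel = 0,
                             n_inversions = 0L, seed = 1L) {
  stopifnot(p_sub >= 0, p_sub < 0.75, L >= 1)
  with_seed(seed, {
    anc <- random_dna(L, gc)
    b <- dna_to_int(anc)
    sub_pos <- which(runif(L) < p_sub)
    derived <- b
    if (length(sub_pos)) {
      shift <- sample.int(3L, length(sub_pos), replace = TRUE)
      derived[sub_pos] <- (derived[sub_pos] + shift) %% 4L
    }
    seq2 <- int_to_dna(derived)

    inversions <- data.frame(start = integer(0), end = integer(0))
    if (n_inversions > 0L) {
      inv_len <- pmax(100L, as.integer(round(L * runif(n_inversions,
                                                       0.01, 0.05))))
      for (i in seq_len(n_inversions)) {
        st <- sample.int(L - inv_len[i] + 1L, 1L)
        en <- st + inv_len[i] - 1L
        seg <- revcomp(substr(seq2, st, en))
        seq2 <- paste0(substr(seq2, 1L, st - 1L), seg,
                       substr(seq2, en + 1L, nchar(seq2)))
        inversions <- rbind(inversions, data.frame(start = st - 1L, end = en))
      }
    }

    indels <- data.frame(pos = integer(0), type = character(0),
                         len = integer(0))
    if (p_indel > 0) {
      n_ev <- rbinom(1L, nchar(seq2), p_indel)
      if (n_ev > 0L) {
        pos <- sort(sample.int(nchar(seq2), n_ev))
        type <- sample(c("ins", "del"), n_ev, replace = TRUE)
        len <- stats::rgeom(n_ev, 0.5) + 1L
        for (i in rev(seq_len(n_ev))) {     # right to left keeps coordinates
          if (type[i] == "ins") {
            seq2 <- paste0(substr(seq2, 1L, pos[i]), random_dna(len[i], gc),
                           substr(seq2, pos[i] + 1L, nchar(seq2)))
          } else {
            en <- min(pos[i] + len[i] - 1L, nchar(seq2))
            seq2 <- paste0(substr(seq2, 1L, pos[i] - 1L),
                           substr(seq2, en + 1L, nchar(seq2)))
          }
        }
        indels <- data.frame(pos = pos - 1L, type = type, len = len)
      }
    }

    list(genome1 = genome_assembly(c(chr1 = anc)),
         genome2 = genome_assembly(c(chr1 = seq2)),
         truth = list(seed = seed, L = L, gc = gc, p_sub = p_sub,
                      p_indel = p_indel, n_inversions = n_inversions,
                      sub_positions = sub_pos - 1L,
                      realized_p_sub = length(sub_pos) / L,
                      inversions = inversions, indels = indels))
  })
}

# a random in-frame CDS (no internal stop, no terminal stop)
.random_cds <- function(n_codons) {
  .codon_table()
  sense <- .kaks_env$codons[.kaks_env$aa != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Plant a gene landscape with known duplication classes
#'
#' Builds one genome of `n_scaffolds` scaffolds with `genes_per_scaffold`
#' genes each (plus a duplicated scaffold when `wgd = TRUE`).  Planted
#' pairs copy a gene's sequence to a second slot: `tandem` at the
#' adjacent rank, `proximal` with 1-10 intervening genes, `dispersed`
#' with > 10 intervening genes or on another scaffold.  With
#' `wgd = TRUE` scaffold 1's gene order is duplicated onto a new
#' scaffold with 10% random gene loss, creating a planted collinear
#' block.  A homology table with perfect hits between copies is emitted,
#' together with in-frame CDS per gene and a truth log of intended
#' labels.  All genes are on the + strand; exactly
#' `round(single_exon_fraction * n_genes)` genes are single-exon.
#'
#' @param n_scaffolds,genes_per_scaffold Landscape dimensions.
#' @param n_tandem,n_proximal,n_dispersed Number of planted pairs per
#'   class.
#' @param wgd Duplicate scaffold 1 (with 10% gene loss)?
#' @param single_exon_fraction Fraction of single-exon genes.
#' @param seed Integer seed.
#' @return List with `assembly`, `annot`, `hits` ([homology_hits()]),
#'   `cds` (named character vector) and `truth` (per-gene `labels`, the
#'   planted pair table and WGD block info).
#' @export
plant_gene_landscape <- function(n_scaffolds = 5L, genes_per_scaffold = 100L,
                                 n_tandem = 20L, n_proximal = 20L,
                                 n_dispersed = 20L, wgd = FALSE,
                                 single_exon_fraction = 0.3, seed = 1L) {
  with_seed(seed, {
    ns <- n_scaffolds
    gps <- genes_per_scaffold
    scafs <- paste0("scaf", seq_len(ns))
    gene_grid <- matrix(paste0("g", rep(seq_len(ns), each = gps), "_",
                               rep(seq_len(gps), ns)), nrow = gps)
    colnames(gene_grid) <- scafs
    all_genes <- as.vector(gene_grid)

    # slots available for planting (scaffold 1 reserved when wgd)
    plant_scafs <- if (wgd) 2:ns else seq_len(ns)
    if (length(plant_scafs) < 1L) stop("not enough scaffolds for planting")
    used <- matrix(FALSE, nrow = gps, ncol = ns)
    copy_of <- setNames(rep(NA_character_, length(all_genes)), all_genes)
    labels <- setNames(rep("singleton", length(all_genes)), all_genes)
    pair_rows <- list()

    claim <- function(sc, r1, r2) {
      if (any(used[c(r1, r2), sc])) return(FALSE)
      used[c(r1, r2), sc] <<- TRUE
      TRUE
    }
    plant_pair <- function(class, gap_range, cross_scaffold = FALSE) {
      for (attempt in 1:500) {
        sc <- sample(plant_scafs, 1L)
        if (cross_scaffold && length(plant_scafs) >= 2L) {
          sc2 <- sample(setdiff(plant_scafs, sc), 1L)
          r1 <- sample.int(gps, 1L)
          r2 <- sample.int(gps, 1L)
          if (used[r1, sc] || used[r2, sc2]) next
          used[r1, sc] <<- TRUE
          used[r2, sc2] <<- TRUE
          g1 <- gene_grid[r1, sc]
          g2 <- gene_grid[r2, sc2]
        } else {
          gap <- sample(gap_range, 1L)
          r1 <- sample.int(gps - gap - 1L, 1L)
          r2 <- r1 + gap + 1L
          if (!claim(sc, r1, r2)) next
          g1 <- gene_grid[r1, sc]
          g2 <- gene_grid[r2, sc]
        }
        copy_of[g2] <<- g1
        labels[c(g1, g2)] <<- class
        pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
          gene_a = g1, gene_b = g2, class = class,
          stringsAsFactors = FALSE)
        return(TRUE)
      }
      stop("could not place a ", class, " pair; landscape too crowded")
    }
    for (i in seq_len(n_tandem)) plant_pair("tandem", 0L)
    for (i in seq_len(n_proximal)) plant_pair("proximal", 1:10)
    for (i in seq_len(n_dispersed)) {
      cross <- runif(1) < 0.5 || gps < 14L
      plant_pair("dispersed", if (cross) 0L else 11:min(gps - 2L, 25L),
                 cross_scaffold = cross)
    }

    # per-gene CDS: fresh sequence unless the gene is a planted copy
    n_codons <- sample(100:300, length(all_genes), replace = TRUE)
    cds <- setNames(character(length(all_genes)), all_genes)
    for (g in all_genes[is.na(copy_of)]) {
      cds[[g]] <- .random_cds(n_codons[[match(g, all_genes)]])
    }
    for (g in all_genes[!is.na(copy_of)]) {
      cds[[g]] <- cds[[copy_of[[g]]]]
    }

    # WGD scaffold: copy scaffold 1's gene order with 10% loss
    wgd_src <- character(0)
    wgd_genes <- character(0)
    if (wgd) {
      keep <- runif(gps) >= 0.10
      wgd_src <- gene_grid[keep, 1L]
      wgd_genes <- paste0(wgd_src, "_w")
      for (i in seq_along(wgd_src)) cds[[wgd_genes[i]]] <- cds[[wgd_src[i]]]
      labels[wgd_src] <- "wgd"
      labels <- c(labels, setNames(rep("wgd", length(wgd_genes)), wgd_genes))
    }

    # exact single-exon allocation: round(fraction * n) genes, chosen once
    gene_order <- c(as.vector(gene_grid), wgd_genes)
    n_total <- length(gene_order)
    n_single <- round(single_exon_fraction * n_total)
    single_set <- if (n_single > 0L) {
      gene_order[sample.int(n_total, n_single)]
    } else character(0)

    # assemble scaffolds: spacer + gene + spacer + gene ...
    scaf_list <- c(scafs, if (wgd) "scafW")
    gene_cols <- c(lapply(seq_len(ns), function(s) gene_grid[, s]),
                   if (wgd) list(wgd_genes))
    seqs <- character(length(scaf_list))
    rows <- list()
    for (s in seq_along(scaf_list)) {
      pos <- 0L
      parts <- character(0)
      for (g in gene_cols[[s]]) {
        spacer <- random_dna(sample(100:300, 1L))
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        gseq <- cds[[g]]
        if (g %in% single_set) {
          exons <- matrix(c(pos, pos + nchar(gseq)), ncol = 2)
          body <- gseq
        } else {
          nex <- sample(2:3, 1L)
          clen <- nchar(gseq) / 3L
          cuts <- sort(sample(seq_len(clen - 1L), nex - 1L)) * 3L
          pieces <- substring(gseq, c(1L, cuts + 1L), c(cuts, nchar(gseq)))
          introns <- vapply(seq_len(nex - 1L),
                            function(i) random_dna(sample(60:200, 1L)), "")
          body <- pieces[1]
          exon_start <- pos
          exons <- matrix(c(exon_start, exon_start + nchar(pieces[1])),
                          ncol = 2)
          for (i in seq_len(nex - 1L)) {
            body <- paste0(body, introns[i], pieces[i + 1L])
            est <- exons[nrow(exons), 2] + nchar(introns[i])
            exons <- rbind(exons, c(est, est + nchar(pieces[i + 1L])))
          }
        }
        colnames(exons) <- c("start", "end")
        parts <- c(parts, body)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, scaffold = scaf_list[s], start = pos,
          end = pos + nchar(body), strand = "+", exons = I(list(exons)),
          stringsAsFactors = FALSE)
        pos <- pos + nchar(body)
      }
      parts <- c(parts, random_dna(sample(100:300, 1L)))
      seqs[s] <- paste(parts, collapse = "")
    }
    assembly <- genome_assembly(setNames(seqs, scaf_list))
    annot <- gene_annotation(do.call(rbind, rows))

    # perfect homology hits between copies (both directions)
    hit_pairs <- do.call(rbind, c(pair_rows, list(
      if (wgd) data.frame(gene_a = wgd_src, gene_b = wgd_genes,
                          class = "wgd", stringsAsFactors = FALSE))))
    hits <- if (is.null(hit_pairs) || nrow(hit_pairs) == 0L) {
      homology_hits(data.frame(
        query_id = character(0), subject_id = character(0),
        pct_identity = numeric(0), aln_len = integer(0),
        evalue = numeric(0), bitscore = numeric(0),
        query_cov = numeric(0), subject_cov = numeric(0)))
    } else {
      plen <- nchar(cds[hit_pairs$gene_a]) / 3L
      homology_hits(data.frame(
        query_id = c(hit_pairs$gene_a, hit_pairs$gene_b),
        subject_id = c(hit_pairs$gene_b, hit_pairs$gene_a),
        pct_identity = 100, aln_len = as.integer(rep(plen, 2)),
        evalue = 0, bitscore = rep(2 * plen, 2),
        query_cov = 100, subject_cov = 100, stringsAsFactors = FALSE))
    }

    list(assembly = assembly, annot = annot, hits = hits, cds = cds,
         truth = list(
           seed = seed, labels = labels[annot$gene_id],
           pairs = if (is.null(hit_pairs)) data.frame() else hit_pairs,
           wgd_scaffolds = if (wgd) c("scaf1", "scafW") else character(0),
           n_wgd_anchors = length(wgd_genes),
           single_exon_genes = intersect(single_set, annot$gene_id)))
  })
}

#' Evolve a codon pair at controlled Ks and omega
#'
#' Starting from a random stop-free CDS, single-nucleotide substitutions
#' are proposed uniformly over positions and alternative bases; proposals
#' creating a stop codon are rejected.  Synonymous proposals are accepted
#' with probability 1 and nonsynonymous with probability `omega` (for
#' `omega > 1` the roles invert: nonsynonymous accepted with probability
#' 1, synonymous with `1/omega`).  Evolution stops once realised
#' synonymous substitutions per synonymous site (sites counted on the
#' ancestor, Nei-Gojobori style) reach `ks_target`.
#'
#' @param n_codons CDS length in codons.
#' @param ks_target Target synonymous substitutions per synonymous site.
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param seed Integer seed.
#' @return List with `cds1`, `cds2` and `truth` (realised syn/nonsyn
#'   event counts and site counts).
#' @export
evolve_codon_pair <- function(n_codons, ks_target, omega, seed = 1L) {
  stopifnot(omega >= 0, ks_target >= 0, n_codons >= 1)
  .codon_table()
  with_seed(seed, {
    cds1 <- .random_cds(n_codons)
    codons <- .split_codons(cds1)
    S <- sum(.kaks_env$syn_sites[codons])
    seq2 <- strsplit(cds1, "")[[1]]
    n_syn <- n_nonsyn <- 0L
    p_syn <- if (omega > 1) 1 / omega else 1
    p_non <- min(omega, 1)
    attempts <- 0L
    max_attempts <- 2000L * n_codons + 10000L
    aa <- .kaks_env$aa
    while (ks_target > 0 && n_syn / S < ks_target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not reach ks_target (omega/length pathological)")
      }
      pos <- sample.int(3L * n_codons, 1L)
      old <- seq2[pos]
      alt <- sample(setdiff(DNA_BASES, old), 1L)
      ci <- (pos - 1L) %/% 3L
      cod_old <- paste(seq2[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
      new3 <- seq2[(3L * ci + 1L):(3L * ci + 3L)]
      new3[pos - 3L * ci] <- alt
      cod_new <- paste(new3, collapse = "")
      if (aa[[cod_new]] == "*") next
      syn <- aa[[cod_new]] == aa[[cod_old]]
      p_acc <- if (syn) p_syn else p_non
      if (p_acc < 1 && runif(1) >= p_acc) next
      seq2[pos] <- alt
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
    list(cds1 = cds1, cds2 = paste(seq2, collapse = ""),
         truth = list(seed = seed, n_syn = n_syn, n_nonsyn = n_nonsyn,
                      syn_sites = S, nonsyn_sites = 3 * n_codons - S,
                      omega = omega, ks_target = ks_target))
  })
}

#' Insert an introner element into an intron
#'
#' Inserts `arm + spacer + revcomp(arm)` (inverted, the default) or
#' `arm + spacer + arm` (direct) at the 5' end of the chosen intron and
#' shifts all downstream coordinates consistently.  For the de novo scan
#' to recover the planted element within its default end window, the
#' target intron should be short (shorter than the scan's `end_window`)
#' or the scan run with a wider window.
#'
#' @param annot A [gene_annotation()].
#' @param assembly The matching [genome_assembly()].
#' @param gene_id,intron_index Target intron (transcription order).
#' @param arm_seq Arm sequence (5' arm, as read on the transcript).
#' @param spacer_len Length of the random spacer between the arms.
#' @param inverted Insert an inverted (TRUE) or direct (FALSE) repeat.
#' @param seed Integer seed (spacer sequence).
#' @return List with modified `assembly`, `annot` and `truth` (intron-
#'   relative arm coordinates and the genomic insertion point).
#' @export
insert_introner <- function(annot, assembly, gene_id, intron_index,
                            arm_seq, spacer_len = 10L, inverted = TRUE,
                            seed = 1L) {
  i <- match(gene_id, annot$gene_id)
  if (is.na(i)) stop("gene ", gene_id, " not in annotation")
  ex <- annot$exons[[i]]
  n_intr <- nrow(ex) - 1L
  if (intron_index < 1L || intron_index > n_intr) {
    stop("gene ", gene_id, " has no intron ", intron_index)
  }
  strand <- annot$strand[i]
  gidx <- if (strand == "+") intron_index else n_intr + 1L - intron_index
  istart <- ex[gidx, 2]          # genomic 0-based half-open intron
  iend <- ex[gidx + 1L, 1]
  if (iend <= istart) stop("target intron has zero length")
  with_seed(seed, {
    spacer <- random_dna(spacer_len)
    arm2 <- if (inverted) revcomp(arm_seq) else arm_seq
    insert_tx <- paste0(arm_seq, spacer, arm2)       # transcript orientation
    insert_gen <- if (strand == "+") insert_tx else revcomp(insert_tx)
    # 5' end of the intron in genomic coordinates
    ins_pos <- if (strand == "+") istart else iend   # insert before ins_pos
    scaf <- annot$scaffold[i]
    seqs <- unclass(assembly)
    s <- seqs[[scaf]]
    seqs[[scaf]] <- paste0(substr(s, 1L, ins_pos), insert_gen,
                           substr(s, ins_pos + 1L, nchar(s)))
    shift <- nchar(insert_gen)
    df <- as.data.frame(annot)
    for (j in seq_len(nrow(df))) {
      if (df$scaffold[j] != scaf) next
      exj <- df$exons[[j]]
      exj[exj[, 1] >= ins_pos, 1] <- exj[exj[, 1] >= ins_pos, 1] + shift
      exj[exj[, 2] > ins_pos, 2] <- exj[exj[, 2] > ins_pos, 2] + shift
      df$exons[[j]] <- exj
      if (df$start[j] >= ins_pos) df$start[j] <- df$start[j] + shift
      if (df$end[j] > ins_pos) df$end[j] <- df$end[j] + shift
    }
    df$rank <- NULL
    new_annot <- gene_annotation(df)
    arm_len <- nchar(arm_seq)
    list(assembly = genome_assembly(seqs), annot = new_annot,
         truth = list(gene_id = gene_id, intron_index = intron_index,
                      genomic_insert_pos = ins_pos,
                      a_start = 0L, a_end = arm_len,
                      b_start = arm_len + spacer_len,
                      b_end = 2L * arm_len + spacer_len,
                      inverted = inverted, arm_seq = arm_seq))
  })
}

#' Simulate a two-isolate protein similarity graph
#'
#' Families of four proteins (two per isolate) carry strong within-
#' isolate edges and weaker cross-isolate edges, so that low inflation
#' merges each family into one mixed cluster while high inflation splits
#' it into isolate-specific halves; a set of tightly linked cross-isolate
#' ortholog pairs and isolate-specific singletons is added.  This is the
#' regime in which the isolate-specific fraction grows with the
#' inflation parameter.
#'
#' @param n_families Number of four-protein families.
#' @param n_ortholog_pairs Number of tight cross-isolate pairs.
#' @param n_singletons Number of isolate-specific singletons.
#' @param seed Integer seed.
#' @return A [build_graph()] `similarity_graph`.
#' @export
simulate_similarity_graph <- function(n_families = 20L,
                                      n_ortholog_pairs = 10L,
                                      n_singletons = 6L, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    iso <- character(0)
    addh <- function(q, s, w) {
      rows[[length(rows) + 1L]] <<- data.frame(
        query_id = q, subject_id = s, pct_identity = 90, aln_len = 200L,
        evalue = 1e-30, bitscore = w, query_cov = 90, subject_cov = 90,
        stringsAsFactors = FALSE)
    }
    for (f in seq_len(n_families)) {
      a1 <- sprintf("A_f%02d_1", f); a2 <- sprintf("A_f%02d_2", f)
      b1 <- sprintf("B_f%02d_1", f); b2 <- sprintf("B_f%02d_2", f)
      iso[c(a1, a2)] <- "isoA"
      iso[c(b1, b2)] <- "isoB"
      within_w <- runif(1, 80, 100)
      cross_w <- runif(1, 10, 0.98 * within_w)  # split point varies by family
      addh(a1, a2, within_w)
      addh(b1, b2, runif(1, 0.9, 1) * within_w)
      addh(a1, b1, cross_w)
      addh(a2, b2, runif(1, 0.9, 1) * cross_w)
    }
    for (p in seq_len(n_ortholog_pairs)) {
      a <- sprintf("A_o%02d", p); b <- sprintf("B_o%02d", p)
      iso[a] <- "isoA"; iso[b] <- "isoB"
      addh(a, b, runif(1, 150, 200))
    }
    for (s in seq_len(n_singletons)) {
      id <- sprintf("%s_s%02d", if (s %% 2 == 0) "A" else "B", s)
      iso[id] <- if (s %% 2 == 0) "isoA" else "isoB"
    }
    hits <- homology_hits(do.call(rbind, rows))
    build_graph(hits, iso)
  })
}
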