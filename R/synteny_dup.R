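# Collinear gene-block detection between annotated genomes and the
# five-way gene-duplication classifier (singleton / dispersed / proximal /
# tandem / WGD), plus the Ka+Ks-based deduplication of anchor pairs.
#
# Gene positions are summarised by their per-scaffold rank (order of gene
# start); homologous gene pairs become dots in rank space and collinear
# blocks are maximal strictly monotone chains of dots.

#' Construct a collinear block
#' @param scaffold_a,scaffold_b Scaffold ids.
#' @param anchors Data frame with columns `gene_a`, `gene_b`, `rank_a`,
#'   `rank_b`, ordered along the chain.
#' @param orientation `"same"` or `"inverted"`.
#' @return Object of class `collinear_block`.
#' @export
collinear_block <- function(scaffold_a, scaffold_b, anchors, orientation) {
  if (is.unsorted(anchors$rank_a, strictly = TRUE)) {
    stop("anchor ranks on scaffold A must be strictly increasing")
  }
  rb <- anchors$rank_b
  ok <- if (orientation == "same") !is.unsorted(rb, strictly = TRUE)
        else !is.unsorted(rev(rb), strictly = TRUE)
  if (!ok) stop("anchor ranks on scaffold B must be strictly monotone")
  structure(list(scaffold_a = scaffold_a, scaffold_b = scaffold_b,
                 anchors = anchors, orientation = orientation,
                 n_anchors = nrow(anchors)),
            class = "collinear_block")
}

#' @export
print.collinear_block <- function(x, ...) {
  cat("collinear_block:", x$scaffold_a, "~", x$scaffold_b,
      paste0("(", x$orientation, "),"), x$n_anchors, "anchors\n")
  invisible(x)
}

# homologous gene-pair dots in rank space for one scaffold pair:
# best chain by anchor count, ties broken by smaller total rank gap
.best_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  o <- order(ra, rb)
  ra <- ra[o]; rb <- rb[o]
  f <- rep(1L, n)          # chain length ending at i
  g <- numeric(n)          # total rank gap of that chain
  parent <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- rb[i] - rb[j]
      if (da >= 1L && db >= 1L && da <= max_gap + 1L && db <= max_gap + 1L) {
        cand_f <- f[j] + 1L
        cand_g <- g[j] + (da - 1L) + (db - 1L)
        if (cand_f > f[i] || (cand_f == f[i] && cand_g < g[i])) {
          f[i] <- cand_f
          g[i] <- cand_g
          parent[i] <- j
        }
      }
    }
  }
  best <- which(f == max(f))
  best <- best[which.min(g[best])]
  chain <- integer(0)
  i <- best
  while (i != 0L) {
    chain <- c(i, chain)
    i <- parent[i]
  }
  o[chain]
}

#' Detect collinear gene blocks from homology hits
#'
#' Homologous gene pairs are plotted as dots `(rank_a, rank_b)` for every
#' scaffold pair; maximal chains with strictly monotone ranks on both
#' axes and inter-anchor rank gaps of at most `max_gap` are extracted
#' greedily (best chain first, its dots removed, repeat).  Chains of at
#' least `min_anchors` anchors are reported, in both orientations
#' (`same` = both ranks increasing, `inverted` = second axis decreasing).
#'
#' @param annot_a,annot_b [gene_annotation()] tables.  Pass the same
#'   object twice with `mode = "intra"` for within-genome blocks.
#' @param hits A filtered [homology_hits()] table linking gene ids of the
#'   two annotations.
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @param max_gap Maximum intervening gene ranks between consecutive
#'   anchors on either axis (default 25).
#' @param mode `"inter"` for two different genomes, `"intra"` for
#'   within-genome blocks (unordered gene pairs, self pairs dropped).
#' @param min_diag_sep In `intra` mode, same-scaffold gene pairs closer
#'   than this many ranks are excluded from chaining, so tandem and
#'   proximal arrays near the self-comparison diagonal cannot masquerade
#'   as segmental duplication (default: `max_gap`).
#' @return List of [collinear_block()] objects.
#' @export
detect_collinear_blocks <- function(annot_a, annot_b, hits, min_anchors = 5L,
                                    max_gap = 25L,
                                    mode = c("inter", "intra"),
                                    min_diag_sep = max_gap) {
  mode <- match.arg(mode)
  info_a <- setNames(seq_len(nrow(annot_a)), annot_a$gene_id)
  info_b <- setNames(seq_len(nrow(annot_b)), annot_b$gene_id)
  q_in_a <- hits$query_id %in% annot_a$gene_id &
    hits$subject_id %in% annot_b$gene_id
  q_in_b <- hits$query_id %in% annot_b$gene_id &
    hits$subject_id %in% annot_a$gene_id
  pairs <- rbind(
    data.frame(gene_a = hits$query_id[q_in_a],
               gene_b = hits$subject_id[q_in_a], stringsAsFactors = FALSE),
    data.frame(gene_a = hits$subject_id[q_in_b],
               gene_b = hits$query_id[q_in_b], stringsAsFactors = FALSE))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  if (mode == "intra") {
    swap <- pairs$gene_a > pairs$gene_b
    tmp <- pairs$gene_a[swap]
    pairs$gene_a[swap] <- pairs$gene_b[swap]
    pairs$gene_b[swap] <- tmp
  }
  pairs <- unique(pairs)
  if (nrow(pairs) == 0L) return(list())
  ia <- info_a[pairs$gene_a]
  ib <- info_b[pairs$gene_b]
  dots <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    scaf_a = annot_a$scaffold[ia], scaf_b = annot_b$scaffold[ib],
    rank_a = annot_a$rank[ia], rank_b = annot_b$rank[ib],
    stringsAsFactors = FALSE)
  if (mode == "intra") {
    # orient unordered same-scaffold pairs consistently in rank space
    flip <- dots$scaf_a == dots$scaf_b & dots$rank_a > dots$rank_b
    if (any(flip)) {
      tmp <- dots[flip, c("gene_a", "scaf_a", "rank_a")]
      dots[flip, c("gene_a", "scaf_a", "rank_a")] <-
        dots[flip, c("gene_b", "scaf_b", "rank_b")]
      dots[flip, c("gene_b", "scaf_b", "rank_b")] <- tmp
      dots <- unique(dots)
    }
    near_diag <- dots$scaf_a == dots$scaf_b &
      abs(dots$rank_a - dots$rank_b) <= min_diag_sep
    dots <- dots[!near_diag, , drop = FALSE]
    if (nrow(dots) == 0L) return(list())
  }
  blocks <- list()
  for (key in unique(paste(dots$scaf_a, dots$scaf_b, sep = "\r"))) {
    d <- dots[paste(dots$scaf_a, dots$scaf_b, sep = "\r") == key, ,
              drop = FALSE]
    repeat {
      if (nrow(d) < min_anchors) break
      ch_same <- .best_chain(d$rank_a, d$rank_b, max_gap)
      ch_inv <- .best_chain(d$rank_a, -d$rank_b, max_gap)
      use_inv <- length(ch_inv) > length(ch_same)
      ch <- if (use_inv) ch_inv else ch_same
      if (length(ch) < min_anchors) break
      anchors <- d[ch, c("gene_a", "gene_b", "rank_a", "rank_b")]
      rownames(anchors) <- NULL
      blocks[[length(blocks) + 1L]] <- collinear_block(
        d$scaf_a[1], d$scaf_b[1], anchors,
        orientation = if (use_inv) "inverted" else "same")
      d <- d[-ch, , drop = FALSE]
    }
  }
  blocks
}

#' Classify genes into the five duplication classes
#'
#' Genes with no surviving homology hit are `singleton`.  Duplicated
#' genes are assigned with precedence `wgd > tandem > proximal >
#' dispersed`: `wgd` when the gene anchors any within-genome collinear
#' block of at least `min_anchors` genes; `tandem` when some homolog is
#' rank-adjacent on the same scaffold; `proximal` when a same-scaffold
#' homolog has 1 to `proximal_max` intervening genes; `dispersed`
#' otherwise (farther away or on another scaffold).
#'
#' @param annot A [gene_annotation()].
#' @param hits Filtered within-genome [homology_hits()]; every gene id in
#'   `hits` must be present in `annot`.
#' @param min_anchors,max_gap Collinearity parameters for the WGD test.
#' @param proximal_max Largest intervening-gene count still `proximal`
#'   (default 10).
#' @return Data frame of class `duplication_labels` with columns
#'   `gene_id`, `label`.
#' @export
classify_duplicates <- function(annot, hits, min_anchors = 5L, max_gap = 25L,
                                proximal_max = 10L) {
  hit_genes <- unique(c(hits$query_id, hits$subject_id))
  missing <- setdiff(hit_genes, annot$gene_id)
  if (length(missing)) {
    stop("gene(s) in hits but absent from annotation: ",
         paste(head(missing, 5), collapse = ", "))
  }
  pairs <- unique(rbind(
    data.frame(a = hits$query_id, b = hits$subject_id,
               stringsAsFactors = FALSE),
    data.frame(a = hits$subject_id, b = hits$query_id,
               stringsAsFactors = FALSE)))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]

  idx <- setNames(seq_len(nrow(annot)), annot$gene_id)
  label <- setNames(rep("singleton", nrow(annot)), annot$gene_id)
  if (nrow(pairs)) {
    label[unique(pairs$a)] <- "dispersed"
    same_scaf <- annot$scaffold[idx[pairs$a]] == annot$scaffold[idx[pairs$b]]
    dr <- abs(annot$rank[idx[pairs$a]] - annot$rank[idx[pairs$b]])
    prox <- unique(pairs$a[same_scaf & dr >= 2L & dr <= proximal_max + 1L])
    label[prox] <- "proximal"
    tand <- unique(pairs$a[same_scaf & dr == 1L])
    label[tand] <- "tandem"
    blocks <- detect_collinear_blocks(annot, annot, hits,
                                      min_anchors = min_anchors,
                                      max_gap = max_gap, mode = "intra")
    wgd_genes <- unique(unlist(lapply(blocks, function(b) {
      c(b$anchors$gene_a, b$anchors$gene_b)
    })))
    label[wgd_genes] <- "wgd"
  }
  out <- data.frame(gene_id = annot$gene_id,
                    label = unname(label[annot$gene_id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("duplication_labels", "data.frame")
  out
}

#' Deduplicate collinear-block anchors by Ka+Ks
#'
#' When a gene anchors several partners across blocks, only its most
#' similar pairing (lowest Ka+Ks) is retained; an anchor survives when it
#' is the best pairing for both of its genes.  Blocks are then re-filtered
#' to `min_anchors`.
#'
#' @param blocks List of [collinear_block()] objects.
#' @param kaks_lookup Data frame with columns `gene_a`, `gene_b` and
#'   either `ka_ks` or both `ka` and `ks` (unordered pairs).  Anchors with
#'   no entry score +Inf (lowest priority) with a warning.
#' @param min_anchors Minimum anchors per surviving block.
#' @return Filtered list of [collinear_block()] objects.
#' @export
dedup_wgd_pairs <- function(blocks, kaks_lookup, min_anchors = 5L) {
  if (length(blocks) == 0L) return(blocks)
  if (!"ka_ks" %in% names(kaks_lookup)) {
    kaks_lookup$ka_ks <- kaks_lookup$ka + kaks_lookup$ks
  }
  key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  score_map <- setNames(kaks_lookup$ka_ks,
                        key(kaks_lookup$gene_a, kaks_lookup$gene_b))
  all_anchors <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    cbind(blocks[[i]]$anchors[, c("gene_a", "gene_b")], block = i)
  }))
  sc <- unname(score_map[key(all_anchors$gene_a, all_anchors$gene_b)])
  if (anyNA(sc)) {
    warning(sum(is.na(sc)), " anchor pair(s) without Ka+Ks; treated as +Inf")
    sc[is.na(sc)] <- Inf
  }
  best_for <- function(genes) {
    tapply(sc, genes, min)
  }
  best_a <- best_for(all_anchors$gene_a)
  best_b <- best_for(all_anchors$gene_b)
  keep <- sc <= best_a[all_anchors$gene_a] &
    sc <= best_b[all_anchors$gene_b]
  # a gene may tie between partners; keep only its first best anchor
  ki <- which(keep)
  tie <- duplicated(all_anchors$gene_a[ki]) | duplicated(all_anchors$gene_b[ki])
  keep[ki[tie]] <- FALSE
  out <- list()
  for (i in seq_along(blocks)) {
    sel <- keep[all_anchors$block == i]
    anchors <- blocks[[i]]$anchors[sel, , drop = FALSE]
    if (nrow(anchors) >= min_anchors) {
      rownames(anchors) <- NULL
      out[[length(out) + 1L]] <- collinear_block(
        blocks[[i]]$scaffold_a, blocks[[i]]$scaffold_b, anchors,
        blocks[[i]]$orientation)
    }
  }
  out
}

#' Summarise duplication labels
#' @param labels A `duplication_labels` data frame.
#' @return Named integer vector of per-class gene counts.
#' @export
duplication_summary <- function(labels) {
  lv <- c("singleton", "dispersed", "proximal", "tandem", "wgd")
  counts <- table(factor(labels$label, levels = lv))
  setNames(as.integer(counts), lv)
}

#' Tabulate collinear blocks
#'
#' One row per anchor with block id, scaffolds and orientation, plus the
#' percentage of genes (of each annotation) involved in blocks.
#'
#' @param blocks List of [collinear_block()] objects.
#' @param annot_a,annot_b Optional annotations to compute gene
#'   percentages against.
#' @return List with `anchors` (data frame) and `pct_genes_a`,
#'   `pct_genes_b` (NA when annotations are not supplied).
#' @export
collinearity_table <- function(blocks, annot_a = NULL, annot_b = NULL) {
  if (length(blocks) == 0L) {
    return(list(anchors = data.frame(
      block = integer(0), scaffold_a = character(0),
      scaffold_b = character(0), orientation = character(0),
      gene_a = character(0), gene_b = character(0)),
      pct_genes_a = if (is.null(annot_a)) NA_real_ else 0,
      pct_genes_b = if (is.null(annot_b)) NA_real_ else 0))
  }
  tab <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block = i, scaffold_a = b$scaffold_a,
               scaffold_b = b$scaffold_b, orientation = b$orientation,
               gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
               stringsAsFactors = FALSE)
  }))
  pct <- function(annot, genes) {
    if (is.null(annot)) return(NA_real_)
    100 * length(intersect(genes, annot$gene_id)) / nrow(annot)
  }
  list(anchors = tab,
       pct_genes_a = pct(annot_a, unique(tab$gene_a)),
       pct_genes_b = pct(annot_b, unique(tab$gene_b)))
}
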