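# Lightweight whole-genome aligner: unique exact-match anchoring (MUM-style
# seeds), highest-scoring collinear chaining, gap closing by global
# alignment of short inter-anchor gaps, and the two summary statistics:
# Q (percentage of query bases covered by alignments) and ID
# (length-weighted identity of aligned regions).  Designed for desk-scale
# genomes (up to a few Mb); coordinate tables from external aligners can
# be imported with read_coords_table() for larger inputs.

#' Construct an alignment set
#'
#' @param blocks Data frame of alignment blocks (possibly 0 rows) with
#'   columns `ref_scaffold`, `qry_scaffold`, `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end` (0-based half-open, query coordinates always
#'   on the forward strand), `strand`, `length` (alignment columns),
#'   `identity` (percent).
#' @param ref_total,qry_total Total genome lengths in bp.
#' @param min_report_len Minimum block length (columns) retained.
#' @return Object of class `alignment_set`.
#' @export
alignment_set <- function(blocks, ref_total, qry_total, min_report_len = 0L) {
  needed <- c("ref_scaffold", "qry_scaffold", "ref_start", "ref_end",
              "qry_start", "qry_end", "strand", "length", "identity")
  if (!all(needed %in% names(blocks))) {
    stop("missing block column(s): ",
         paste(setdiff(needed, names(blocks)), collapse = ", "))
  }
  if (nrow(blocks)) {
    if (any(blocks$identity < 0 | blocks$identity > 100)) {
      stop("block identity out of [0, 100]")
    }
    if (any(blocks$length < blocks$ref_end - blocks$ref_start) ||
        any(blocks$length < blocks$qry_end - blocks$qry_start)) {
      stop("block length (columns) smaller than its intervals")
    }
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, ref_total = ref_total,
                 qry_total = qry_total, min_report_len = min_report_len),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", nrow(x$blocks), "block(s), min_report_len =",
      x$min_report_len, "\n")
  invisible(x)
}

# seed codes + 1-based positions for every scaffold of an assembly
.seed_scan <- function(assembly, s) {
  res <- lapply(names(assembly), function(sc) {
    w <- encode_kmers_keep_pos(as.character(assembly[[sc]]), s, canonical = FALSE)
    if (length(w$codes) == 0L) return(NULL)
    data.frame(code = w$codes, pos = w$pos, scaf = sc, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) {
    return(data.frame(code = numeric(0), pos = integer(0), scaf = character(0)))
  }
  do.call(rbind, res)
}

#' Find exact-match anchors between two assemblies
#'
#' Anchors are maximal exact matches assembled from fixed-length seed
#' words that occur exactly once in the reference and once in the query
#' (both query strands considered), i.e. MUM-style uniqueness.  Runs of
#' consecutive unique seeds on one diagonal are merged, and runs on the
#' same diagonal separated by identical intervening sequence are joined,
#' reconstructing the full exact match.
#'
#' @param ref,qry [genome_assembly()] objects.
#' @param min_anchor Minimum anchor length in bp (>= 12).
#' @param unique_only Require seed uniqueness in both genomes (MUM
#'   semantics, default). With `FALSE`, repeated seeds also anchor
#'   (first-occurrence pairing).
#' @return Data frame with one row per anchor: `ref_scaffold`,
#'   `qry_scaffold`, `strand`, `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end` (0-based half-open, forward query coordinates) and
#'   `length`.
#' @export
find_anchors <- function(ref, qry, min_anchor = 20L, unique_only = TRUE) {
  if (min_anchor < 12L) stop("min_anchor must be >= 12")
  s <- as.integer(min(min_anchor, 26L))
  rsc <- .seed_scan(ref, s)

  qlen <- setNames(nchar(unclass(qry)), names(qry))
  qf <- .seed_scan(qry, s)
  qrev <- genome_assembly(setNames(revcomp(as.character(qry)), names(qry)))
  qr <- .seed_scan(qrev, s)
  qall_codes <- c(qf$code, qr$code)

  rcnt <- tabulate(match(rsc$code, unique(rsc$code)))
  runiq <- unique(rsc$code)[rcnt == 1L]
  qcnt <- tabulate(match(qall_codes, unique(qall_codes)))
  quniq <- unique(qall_codes)[qcnt == 1L]

  anchors <- list()
  for (strand in c("+", "-")) {
    qsc <- if (strand == "+") qf else qr
    if (unique_only) {
      keep_r <- rsc[!is.na(match(rsc$code, runiq)), , drop = FALSE]
      keep_q <- qsc[!is.na(match(qsc$code, quniq)), , drop = FALSE]
    } else {
      keep_r <- rsc[!duplicated(rsc$code), , drop = FALSE]
      keep_q <- qsc[!duplicated(qsc$code), , drop = FALSE]
    }
    m <- match(keep_r$code, keep_q$code)
    hit <- !is.na(m)
    if (!any(hit)) next
    df <- data.frame(rpos = keep_r$pos[hit], rscaf = keep_r$scaf[hit],
                     qpos = keep_q$pos[m[hit]], qscaf = keep_q$scaf[m[hit]],
                     stringsAsFactors = FALSE)
    df$diag <- df$rpos - df$qpos
    df <- df[order(df$rscaf, df$qscaf, df$diag, df$rpos), , drop = FALSE]
    grp <- paste(df$rscaf, df$qscaf, df$diag, sep = "\r")
    new_run <- c(TRUE, grp[-1] != grp[-nrow(df)] |
                   diff(df$rpos) != 1L)
    run_id <- cumsum(new_run)
    first <- which(new_run)
    last <- c(first[-1] - 1L, nrow(df))
    runs <- data.frame(rscaf = df$rscaf[first], qscaf = df$qscaf[first],
                       rstart = df$rpos[first], rend = df$rpos[last] + s - 1L,
                       qstart = df$qpos[first], qend = df$qpos[last] + s - 1L,
                       stringsAsFactors = FALSE)
    # join runs on one diagonal separated by identical sequence (seed
    # uniqueness can split one exact match into several runs)
    runs <- .join_split_runs(runs, ref,
                             if (strand == "+") qry else qrev)
    runs$strand <- strand
    anchors[[strand]] <- runs
  }
  if (length(anchors) == 0L) {
    return(data.frame(ref_scaffold = character(0), qry_scaffold = character(0),
                      strand = character(0), ref_start = integer(0),
                      ref_end = integer(0), qry_start = integer(0),
                      qry_end = integer(0), length = integer(0)))
  }
  a <- do.call(rbind, anchors)
  a <- a[a$rend - a$rstart + 1L >= min_anchor, , drop = FALSE]
  len <- a$rend - a$rstart + 1L
  # convert strand-space (reverse-complement) query coords to forward
  qs <- a$qstart - 1L
  qe <- a$qend
  neg <- a$strand == "-"
  if (any(neg)) {
    L <- qlen[a$qscaf[neg]]
    tmp_s <- L - a$qend[neg]
    tmp_e <- L - (a$qstart[neg] - 1L)
    qs[neg] <- tmp_s
    qe[neg] <- tmp_e
  }
  out <- data.frame(ref_scaffold = a$rscaf, qry_scaffold = a$qscaf,
                    strand = a$strand, ref_start = a$rstart - 1L,
                    ref_end = a$rend, qry_start = as.integer(qs),
                    qry_end = as.integer(qe), length = len,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# merge runs on one diagonal when the sequence between them is identical
.join_split_runs <- function(runs, ref, qry_strand) {
  if (nrow(runs) < 2L) return(runs)
  o <- order(runs$rscaf, runs$qscaf, runs$rstart - runs$qstart, runs$rstart)
  runs <- runs[o, , drop = FALSE]
  keep <- logical(nrow(runs))
  cur <- 1L
  keep[1L] <- TRUE
  for (i in 2L:nrow(runs)) {
    same <- runs$rscaf[i] == runs$rscaf[cur] &&
      runs$qscaf[i] == runs$qscaf[cur] &&
      (runs$rstart[i] - runs$qstart[i]) == (runs$rstart[cur] - runs$qstart[cur]) &&
      runs$rstart[i] > runs$rend[cur]
    if (same) {
      rgap <- substr(ref[[runs$rscaf[cur]]], runs$rend[cur] + 1L,
                     runs$rstart[i] - 1L)
      qgap <- substr(qry_strand[[runs$qscaf[cur]]], runs$qend[cur] + 1L,
                     runs$qstart[i] - 1L)
      if (identical(rgap, qgap) && !grepl("N", rgap, fixed = TRUE)) {
        runs$rend[cur] <- runs$rend[i]
        runs$qend[cur] <- runs$qend[i]
        next
      }
    }
    cur <- i
    keep[i] <- TRUE
  }
  runs[keep, , drop = FALSE]
}

# Highest-scoring strictly collinear chain (score = total anchor length)
# via sweep + Fenwick prefix-max over query end coordinates.
.chain_anchors <- function(rs, re, qs, qe, len) {
  n <- length(rs)
  if (n == 1L) return(1L)
  o <- order(rs, qs)
  rs <- rs[o]; re <- re[o]; qs <- qs[o]; qe <- qe[o]; len <- len[o]
  qlev <- sort(unique(qe))
  m <- length(qlev)
  fenv <- numeric(m)
  fena <- integer(m)
  upd <- function(i, val, arg) {
    while (i <= m) {
      if (val > fenv[i]) { fenv[i] <<- val; fena[i] <<- arg }
      i <- i + bitwAnd(i, -i)
    }
  }
  qry <- function(i) {
    best <- 0; arg <- 0L
    while (i > 0L) {
      if (fenv[i] > best) { best <- fenv[i]; arg <- fena[i] }
      i <- i - bitwAnd(i, -i)
    }
    list(best = best, arg = arg)
  }
  f <- numeric(n)
  parent <- integer(n)
  pend <- order(re)          # anchors in order of ref end, pending insertion
  pi <- 1L
  for (i in seq_len(n)) {
    while (pi <= n && re[pend[pi]] < rs[i]) {
      j <- pend[pi]
      upd(findInterval(qe[j], qlev), f[j], j)
      pi <- pi + 1L
    }
    pos <- findInterval(qs[i] - 1L, qlev)   # predecessors with qe < qs
    q <- if (pos >= 1L) qry(pos) else list(best = 0, arg = 0L)
    f[i] <- len[i] + q$best
    parent[i] <- q$arg
  }
  i <- which.max(f)
  chain <- integer(0)
  while (i != 0L) {
    chain <- c(i, chain)
    i <- parent[i]
  }
  o[chain]
}

# count matching characters between equal-length strings
.match_count <- function(a, b) {
  if (!nzchar(a)) return(0L)
  sum(utf8ToInt(a) == utf8ToInt(b))
}

# close a gap between consecutive chained anchors; returns c(matches, columns)
.close_gap <- function(rgap, qgap) {
  nr <- nchar(rgap); nq <- nchar(qgap)
  if (nr == 0L && nq == 0L) return(c(0L, 0L))
  if (nr == 0L || nq == 0L) return(c(0L, max(nr, nq)))
  if (nr == nq) return(c(.match_count(rgap, qgap), nr))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(rgap), Biostrings::DNAString(qgap),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  c(Biostrings::nmatch(al), Biostrings::nchar(al))
}

#' Align two genome assemblies
#'
#' Unique exact-match anchors are clustered by scaffold pair and strand;
#' within each cluster the highest-scoring strictly collinear chain (by
#' total anchor length) is kept, inter-anchor gaps of at most
#' `max_diag_gap` bp on both genomes are closed by global alignment
#' (match +1, mismatch -1, gap -2), and the resulting merged blocks are
#' reported when at least `min_report_len` columns long.  Per-block
#' identity is matched columns / total columns.
#'
#' @inheritParams find_anchors
#' @param max_diag_gap Largest inter-anchor gap (bp) closed by alignment.
#' @param min_report_len Minimum reported block length in columns
#'   (typically 100, 1000 or 10000).
#' @return An [alignment_set()].
#' @export
align_genomes <- function(ref, qry, min_anchor = 20L, max_diag_gap = 90L,
                          min_report_len = 100L, unique_only = TRUE) {
  ref_total <- sum(nchar(unclass(ref)))
  qry_total <- sum(nchar(unclass(qry)))
  anchors <- find_anchors(ref, qry, min_anchor = min_anchor,
                          unique_only = unique_only)
  blocks <- list()
  if (nrow(anchors)) {
    qlen <- setNames(nchar(unclass(qry)), names(qry))
    qrev_cache <- new.env(parent = emptyenv())
    qseq_strand <- function(scaf, strand) {
      if (strand == "+") return(qry[[scaf]])
      if (!exists(scaf, qrev_cache)) {
        assign(scaf, revcomp(as.character(qry[[scaf]])), qrev_cache)
      }
      get(scaf, qrev_cache)
    }
    # strand-space query coordinates (1-based inclusive)
    a <- anchors
    a$qs <- a$qry_start + 1L
    a$qe <- a$qry_end
    neg <- a$strand == "-"
    if (any(neg)) {
      L <- qlen[a$qry_scaffold[neg]]
      a$qs[neg] <- L - a$qry_end[neg] + 1L
      a$qe[neg] <- L - a$qry_start[neg]
    }
    a$rs <- a$ref_start + 1L
    a$re <- a$ref_end
    grp <- split(seq_len(nrow(a)),
                 paste(a$ref_scaffold, a$qry_scaffold, a$strand, sep = "\r"))
    walk_chain <- function(g) {
      rseq <- ref[[g$ref_scaffold[1]]]
      qseq <- qseq_strand(g$qry_scaffold[1], g$strand[1])
      cur <- list(rs = g$rs[1], re = g$re[1], qs = g$qs[1], qe = g$qe[1],
                  matches = g$length[1], columns = g$length[1])
      flush <- function(cur) {
        blocks[[length(blocks) + 1L]] <<- data.frame(
          ref_scaffold = g$ref_scaffold[1], qry_scaffold = g$qry_scaffold[1],
          strand = g$strand[1], rs = cur$rs, re = cur$re,
          qs = cur$qs, qe = cur$qe, matches = cur$matches,
          columns = cur$columns, stringsAsFactors = FALSE)
      }
      if (nrow(g) > 1L) {
        for (i in 2L:nrow(g)) {
          rgap <- g$rs[i] - cur$re - 1L
          qgap <- g$qs[i] - cur$qe - 1L
          if (rgap <= max_diag_gap && qgap <= max_diag_gap &&
              rgap >= 0L && qgap >= 0L) {
            mc <- .close_gap(substr(rseq, cur$re + 1L, g$rs[i] - 1L),
                             substr(qseq, cur$qe + 1L, g$qs[i] - 1L))
            cur$matches <- cur$matches + mc[1] + g$length[i]
            cur$columns <- cur$columns + mc[2] + g$length[i]
            cur$re <- g$re[i]
            cur$qe <- g$qe[i]
          } else {
            flush(cur)
            cur <- list(rs = g$rs[i], re = g$re[i], qs = g$qs[i],
                        qe = g$qe[i], matches = g$length[i],
                        columns = g$length[i])
          }
        }
      }
      flush(cur)
    }
    for (ix in grp) {
      g <- a[ix, , drop = FALSE]
      # extract chains greedily: best chain first, then rechain the
      # remaining anchors (secondary chains capture e.g. several
      # inversions on one strand)
      for (pass in seq_len(500L)) {
        if (nrow(g) == 0L) break
        chain <- .chain_anchors(g$rs, g$re, g$qs, g$qe, g$length)
        total <- sum(g$length[chain])
        # a chain whose anchors plus closable gaps cannot reach
        # min_report_len can never yield a reportable block
        if (total + (length(chain) - 1L) * max_diag_gap <
              max(min_report_len, min_anchor)) break
        walk_chain(g[chain, , drop = FALSE])
        g <- g[-chain, , drop = FALSE]
      }
    }
  }
  if (length(blocks)) {
    b <- do.call(rbind, blocks)
    b <- b[b$columns >= min_report_len, , drop = FALSE]
  } else {
    b <- data.frame(ref_scaffold = character(0), qry_scaffold = character(0),
                    strand = character(0), rs = integer(0), re = integer(0),
                    qs = integer(0), qe = integer(0), matches = integer(0),
                    columns = integer(0))
  }
  qlen <- setNames(nchar(unclass(qry)), names(qry))
  qs_fwd <- b$qs - 1L
  qe_fwd <- b$qe
  neg <- b$strand == "-"
  if (any(neg)) {
    L <- qlen[b$qry_scaffold[neg]]
    qs_fwd[neg] <- L - b$qe[neg]
    qe_fwd[neg] <- L - (b$qs[neg] - 1L)
  }
  out <- data.frame(
    ref_scaffold = b$ref_scaffold, qry_scaffold = b$qry_scaffold,
    ref_start = b$rs - 1L, ref_end = b$re,
    qry_start = as.integer(qs_fwd), qry_end = as.integer(qe_fwd),
    strand = b$strand, length = b$columns,
    identity = ifelse(b$columns > 0, 100 * b$matches / b$columns, 0),
    stringsAsFactors = FALSE)
  alignment_set(out, ref_total, qry_total, min_report_len)
}

#' Percentage of query bases aligned (Q)
#'
#' Distinct query positions covered by at least one block, as a
#' percentage of total query length; overlapping blocks count each
#' position once.
#'
#' @param alnset An [alignment_set()].
#' @return Q in percent.
#' @export
compute_Q <- function(alnset) {
  if (alnset$qry_total <= 0) stop("query total length must be positive")
  b <- alnset$blocks
  if (nrow(b) == 0L) return(0)
  gr <- GenomicRanges::GRanges(b$qry_scaffold,
                               IRanges::IRanges(b$qry_start + 1L, b$qry_end))
  covered <- sum(BiocGenerics::width(GenomicRanges::reduce(gr)))
  100 * covered / alnset$qry_total
}

#' Overall identity of aligned regions (ID)
#'
#' Column-length-weighted mean of per-block identities.
#'
#' @param alnset An [alignment_set()] with at least one block.
#' @return ID in percent.
#' @export
compute_ID <- function(alnset) {
  b <- alnset$blocks
  if (nrow(b) == 0L) stop("alignment set has no blocks")
  sum(b$identity * b$length) / sum(b$length)
}

#' Import an external alignment coordinate table
#'
#' Accepts the whitespace-separated show-coords style dialect with
#' columns `S1 E1 S2 E2 [LEN1 LEN2] %IDY ref_id qry_id` (1-based
#' inclusive; reversed query coordinates denote the minus strand).
#'
#' @param path Path to the table.
#' @param ref_total,qry_total Genome lengths in bp.
#' @param min_report_len Minimum block length retained (columns).
#' @return An [alignment_set()].
#' @export
read_coords_table <- function(path, ref_total, qry_total,
                              min_report_len = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (!length(f) %in% c(7L, 9L)) {
      stop("unparseable coords row at line ", i, " of ", path)
    }
    v <- suppressWarnings(as.numeric(f[1:4]))
    idy <- suppressWarnings(as.numeric(f[length(f) - 2L]))
    if (anyNA(v) || is.na(idy)) {
      stop("unparseable coords row at line ", i, " of ", path)
    }
    s1 <- v[1]; e1 <- v[2]; s2 <- v[3]; e2 <- v[4]
    strand <- if (e2 < s2) "-" else "+"
    qlo <- min(s2, e2); qhi <- max(s2, e2)
    len <- if (length(f) == 9L) {
      max(as.numeric(f[5]), as.numeric(f[6]))
    } else {
      max(e1 - s1 + 1, qhi - qlo + 1)
    }
    rows[[i]] <- data.frame(
      ref_scaffold = f[length(f) - 1L], qry_scaffold = f[length(f)],
      ref_start = s1 - 1, ref_end = e1, qry_start = qlo - 1, qry_end = qhi,
      strand = strand, length = as.integer(len), identity = idy,
      stringsAsFactors = FALSE)
  }
  b <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_scaffold = character(0), qry_scaffold = character(0),
               ref_start = integer(0), ref_end = integer(0),
               qry_start = integer(0), qry_end = integer(0),
               strand = character(0), length = integer(0),
               identity = numeric(0))
  b <- b[b$length >= min_report_len, , drop = FALSE]
  alignment_set(b, ref_total, qry_total, min_report_len)
}
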