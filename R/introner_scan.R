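# Introner-element signatures: intron extraction and scanning for
# terminal inverted / direct repeat motifs, plus matching against a
# user-supplied reference motif library.  Mismatch model is Hamming
# (no indels).

#' Extract intron sequences from gene models
#'
#' Introns are the inter-exon gaps of multi-exon genes, numbered in
#' transcription order; minus-strand introns are reverse-complemented so
#' every sequence reads 5' to 3'.
#'
#' @param annot A [gene_annotation()].
#' @param assembly The matching [genome_assembly()].
#' @return Data frame with columns `gene_id`, `intron_index` (1-based,
#'   transcription order), `sequence`.
#' @export
extract_introns <- function(annot, assembly) {
  out <- list()
  n_zero <- 0L
  for (i in seq_len(nrow(annot))) {
    ex <- annot$exons[[i]]
    if (nrow(ex) < 2L) next
    scaf <- annot$scaffold[i]
    if (!scaf %in% names(assembly)) {
      stop("scaffold ", scaf, " not in assembly")
    }
    starts <- ex[-nrow(ex), 2]      # intron = [exon_j end, exon_{j+1} start)
    ends <- ex[-1, 1]
    w <- ends > starts
    n_zero <- n_zero + sum(!w)
    if (!any(w)) next
    seqs <- substring(assembly[[scaf]], starts[w] + 1L, ends[w])
    idx <- which(w)
    if (annot$strand[i] == "-") {
      seqs <- rev(revcomp(seqs))
      idx <- rev((nrow(ex) - 1L) + 1L - idx)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = annot$gene_id[i], intron_index = seq_along(idx),
      sequence = seqs, stringsAsFactors = FALSE)
  }
  if (n_zero > 0L) warning(n_zero, " zero-length intron(s) skipped")
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      sequence = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_ie_hits <- function() {
  data.frame(repeat_type = character(0), a_start = integer(0),
             a_end = integer(0), b_start = integer(0), b_end = integer(0),
             arm_len = integer(0), mismatches = integer(0))
}

.complement_chr <- function(ch) {
  chartr("ACGTN", "TGCAN", ch)
}

# shared scanner core: for each candidate (a_start, anchor) pair, find the
# maximal arm extension within the mismatch budget; returns the single
# longest hit (ties: 5'-most), or an empty frame
.scan_repeat <- function(seq, type, min_arm, end_window, max_mismatch) {
  L <- nchar(seq)
  if (L < 2L * min_arm) return(.empty_ie_hits())
  x <- strsplit(seq, "")[[1]]
  xc <- strsplit(.complement_chr(seq), "")[[1]]
  arm_cap <- 2L * end_window
  best <- NULL
  a_range <- seq_len(min(end_window, L))
  if (type == "inverted") {
    for (a in a_range) {
      for (be in seq.int(max(L - end_window + 1L, a + 2L * min_arm - 1L), L)) {
        len_max <- (be - a + 1L) %/% 2L
        if (len_max < min_arm) next
        t <- seq_len(len_max)
        mm <- cumsum(x[a + t - 1L] != xc[be - t + 1L])
        ok <- which(mm <= max_mismatch)
        if (length(ok) == 0L || max(ok) < min_arm) next
        len <- max(ok)
        cand <- c(a, len, be - len + 1L, mm[len])
        if (is.null(best) || len > best[2]) best <- cand
      }
    }
  } else {
    bs_min <- max(1L, L - end_window + 2L - arm_cap)
    for (a in a_range) {
      for (bs in seq.int(max(bs_min, a + min_arm), L - min_arm + 1L)) {
        len_max <- min(bs - a, L - bs + 1L, arm_cap)
        if (len_max < min_arm) next
        t <- seq_len(len_max)
        mm <- cumsum(x[a + t - 1L] != x[bs + t - 1L])
        ok <- which(mm <= max_mismatch)
        if (length(ok) == 0L || max(ok) < min_arm) next
        len <- max(ok)
        if (bs + len - 1L <= L - end_window) next   # arm b must end in 3' window
        cand <- c(a, len, bs, mm[len])
        if (is.null(best) || len > best[2]) best <- cand
      }
    }
  }
  if (is.null(best)) return(.empty_ie_hits())
  a <- best[1]; len <- best[2]; bs <- best[3]
  data.frame(repeat_type = type, a_start = a - 1L, a_end = a - 1L + len,
             b_start = bs - 1L, b_end = bs - 1L + len, arm_len = len,
             mismatches = as.integer(best[4]))
}

#' Find a terminal inverted repeat in an intron
#'
#' Searches for arm pairs (a, b) with a starting within `end_window` of
#' the 5' end and b ending within `end_window` of the 3' end, where b
#' equals the reverse complement of a up to `max_mismatch` Hamming
#' mismatches.  Arms are extended maximally and the longest arm per
#' intron is reported (coordinates are 0-based half-open within the
#' intron).
#'
#' @param intron_seq Intron sequence (character string, 5' to 3').
#' @param min_arm Minimum arm length (default 6).
#' @param end_window Window at each intron end in which arms must lie.
#' @param max_mismatch Allowed Hamming mismatches between the arms.
#' @return Data frame with 0 or 1 row: `repeat_type`, `a_start`, `a_end`,
#'   `b_start`, `b_end`, `arm_len`, `mismatches`.
#' @export
find_inverted_repeats <- function(intron_seq, min_arm = 6L,
                                  end_window = 30L, max_mismatch = 0L) {
  .scan_repeat(intron_seq, "inverted", min_arm, end_window, max_mismatch)
}

#' Find a terminal direct repeat in an intron
#'
#' As [find_inverted_repeats()], but the 3' arm must equal the 5' arm
#' without reverse complementing.
#'
#' @inheritParams find_inverted_repeats
#' @param min_arm Minimum arm length (default 4).
#' @return Data frame with 0 or 1 row (see [find_inverted_repeats()]).
#' @export
find_direct_repeats <- function(intron_seq, min_arm = 4L,
                                end_window = 30L, max_mismatch = 0L) {
  .scan_repeat(intron_seq, "direct", min_arm, end_window, max_mismatch)
}

#' Scan introns of a genome for introner-element signatures
#'
#' Runs the de novo inverted- and direct-repeat scans on every intron
#' and, when a motif library is given, also reports Hamming matches to
#' each reference motif (`repeat_type = "reference_motif"`; the matched
#' interval is reported as arm a, with arm b unset).
#'
#' @param annot A [gene_annotation()].
#' @param assembly The matching [genome_assembly()].
#' @param min_arm_inverted,min_arm_direct,end_window,max_mismatch Scan
#'   parameters (see [find_inverted_repeats()]).
#' @param motifs Optional named character vector of reference motif
#'   sequences, or a path to a motif FASTA.
#' @return Data frame of hits with columns `gene_id`, `intron_index`,
#'   `repeat_type`, `a_start`, `a_end`, `b_start`, `b_end`, `arm_len`,
#'   `mismatches`, `motif`.
#' @export
scan_introners <- function(annot, assembly, min_arm_inverted = 6L,
                           min_arm_direct = 4L, end_window = 30L,
                           max_mismatch = 0L, motifs = NULL) {
  introns <- extract_introns(annot, assembly)
  if (!is.null(motifs) && is.character(motifs) && length(motifs) == 1L &&
      file.exists(motifs)) {
    ms <- Biostrings::readBStringSet(motifs)
    motifs <- setNames(toupper(as.character(ms)),
                       vapply(strsplit(names(ms), "[ \t]"), `[`, "", 1L))
  }
  rows <- list()
  for (i in seq_len(nrow(introns))) {
    sq <- introns$sequence[i]
    hit_i <- find_inverted_repeats(sq, min_arm_inverted, end_window,
                                   max_mismatch)
    hit_d <- find_direct_repeats(sq, min_arm_direct, end_window,
                                 max_mismatch)
    hits <- rbind(hit_i, hit_d)
    if (nrow(hits)) hits$motif <- NA_character_
    if (!is.null(motifs)) {
      for (mn in names(motifs)) {
        m <- Biostrings::matchPattern(motifs[[mn]],
                                      Biostrings::DNAString(sq),
                                      max.mismatch = max_mismatch)
        if (length(m) > 0L) {
          st <- BiocGenerics::start(m)[1L]
          en <- BiocGenerics::end(m)[1L]
          nmis <- sum(strsplit(substr(sq, st, en), "")[[1]] !=
                        strsplit(motifs[[mn]], "")[[1]])
          hits <- rbind(hits, data.frame(
            repeat_type = "reference_motif", a_start = st - 1L, a_end = en,
            b_start = NA_integer_, b_end = NA_integer_,
            arm_len = nchar(motifs[[mn]]), mismatches = as.integer(nmis),
            motif = mn))
        }
      }
    }
    if (nrow(hits)) {
      hits <- cbind(gene_id = introns$gene_id[i],
                    intron_index = introns$intron_index[i], hits)
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (length(rows) == 0L) {
    out <- cbind(data.frame(gene_id = character(0), intron_index = integer(0)),
                 .empty_ie_hits())
    out$motif <- character(0)
    return(out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Introner-element gene statistics
#'
#' Percentage of genes carrying at least one introner-element hit,
#' genome-wide and restricted to tandem-duplicated (TD) genes.
#'
#' @param hits A [scan_introners()] hit table.
#' @param annot A [gene_annotation()].
#' @param td_blocks List of `td_block` objects ([find_td_blocks()]).
#' @return One-row data frame with `n_ie_genes`, `pct_ie_genes`,
#'   `n_td_genes`, `pct_ie_td_genes`.
#' @export
ie_gene_stats <- function(hits, annot, td_blocks = list()) {
  ie_genes <- unique(hits$gene_id)
  td_genes <- unique(unlist(lapply(td_blocks, `[[`, "genes")))
  data.frame(
    n_ie_genes = length(ie_genes),
    pct_ie_genes = 100 * length(ie_genes) / nrow(annot),
    n_td_genes = length(td_genes),
    pct_ie_td_genes = if (length(td_genes)) {
      100 * length(intersect(ie_genes, td_genes)) / length(td_genes)
    } else NA_real_)
}
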