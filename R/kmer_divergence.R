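# Alignment-free divergence: exact k-mer counting, background-corrected
# D2S similarity and its -log distance d, core k-mers shared across
# isolates (fraction x), and core-k-mer/feature interval intersection.
#
# k-mers are 2-bit packed (A=0 C=1 G=2 T=3) into IEEE doubles, which hold
# integers exactly up to 2^53, i.e. any k <= 26; the default k = 23 uses
# 2^46 distinct codes.  Packed-code order equals lexicographic DNA order,
# so canonical (strand-collapsed) counting takes the numeric minimum of a
# window code and its reverse-complement code.

#' Encode all N-free k-mer windows of a sequence as packed numeric codes
#'
#' @param seq DNA string.
#' @param k Word length (1..26).
#' @param canonical Collapse each window with its reverse complement to the
#'   lexicographically smaller of the two?
#' @return Numeric vector of window codes, one per valid (N-free) window,
#'   in sequence order.
#' @keywords internal
encode_kmers <- function(seq, k, canonical = TRUE) {
  if (k < 1L || k > 26L) stop("k must be in 1..26")
  b <- dna_to_int(seq)
  n <- length(b) - k + 1L
  if (n < 1L) return(numeric(0))
  code <- numeric(n)
  if (canonical) rc <- numeric(n)
  for (j in 0:(k - 1L)) {
    bj <- b[(1L + j):(n + j)]
    code <- code + bj * 4^(k - 1L - j)
    if (canonical) rc <- rc + (3L - bj) * 4^j
  }
  if (canonical) code <- pmin(code, rc)
  code[!is.na(code)]
}

#' Decode packed k-mer codes back to strings
#' @param codes Numeric codes from [encode_kmers()].
#' @param k Word length.
#' @return Character vector of k-mers.
#' @keywords internal
decode_kmers <- function(codes, k) {
  if (length(codes) == 0L) return(character(0))
  cols <- vector("list", k)
  x <- codes
  for (j in k:1) {
    d <- x %% 4
    cols[[j]] <- DNA_BASES[d + 1L]
    x <- (x - d) / 4
  }
  do.call(paste0, cols)
}

#' Count k-mers of a genome assembly
#'
#' Windows containing N are skipped.  Background nucleotide frequencies
#' are estimated from the N-free bases of the same assembly and feed the
#' expected-count centering of [d2s_similarity()].
#'
#' @param assembly A [genome_assembly()] (or named character vector of
#'   sequences).
#' @param k Word length, default 23.
#' @param canonical Strand-collapsed counting (default TRUE).
#' @return Object of class `kmer_profile`: list with `k`, `canonical`,
#'   `codes` (sorted distinct packed codes), `counts`, `n_positions`,
#'   and `bg_freq` (A,C,G,T).
#' @export
count_kmers <- function(assembly, k = 23L, canonical = TRUE) {
  k <- as.integer(k)
  seqs <- as.character(assembly)
  all_codes <- unlist(lapply(seqs, encode_kmers, k = k, canonical = canonical))
  base_tab <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seqs) {
    b <- dna_to_int(s)
    b <- b[!is.na(b)]
    if (length(b)) base_tab <- base_tab + tabulate(b + 1L, nbins = 4L)
  }
  bg <- if (sum(base_tab) > 0) base_tab / sum(base_tab) else rep(0.25, 4)
  names(bg) <- DNA_BASES
  if (length(all_codes) == 0L) {
    warning("no valid k-mer window (k exceeds every scaffold?); empty profile")
    return(structure(list(k = k, canonical = canonical, codes = numeric(0),
                          counts = integer(0), n_positions = 0L, bg_freq = bg),
                     class = "kmer_profile"))
  }
  o <- order(all_codes)
  r <- rle(all_codes[o])
  structure(list(k = k, canonical = canonical, codes = r$values,
                 counts = as.integer(r$lengths),
                 n_positions = length(all_codes), bg_freq = bg),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("kmer_profile: k =", x$k, if (x$canonical) "(canonical)" else "",
      "|", length(x$codes), "distinct k-mers,", x$n_positions, "windows\n")
  invisible(x)
}

# letter composition (A,C,G,T counts) of each packed code
.kmer_base_counts <- function(codes, k) {
  nA <- nC <- nG <- nT <- numeric(length(codes))
  x <- codes
  for (j in seq_len(k)) {
    d <- x %% 4
    nA <- nA + (d == 0)
    nC <- nC + (d == 1)
    nG <- nG + (d == 2)
    nT <- nT + (d == 3)
    x <- (x - d) / 4
  }
  cbind(A = nA, C = nC, G = nG, T = nT)
}

# expected word probability under a zero-order background model
.kmer_bg_prob <- function(codes, k, bg) {
  bc <- .kmer_base_counts(codes, k)
  bg[1]^bc[, 1] * bg[2]^bc[, 2] * bg[3]^bc[, 3] * bg[4]^bc[, 4]
}

#' Background-corrected D2S k-mer similarity
#'
#' Counts are centered by their expectation under each genome's own
#' zero-order (single-nucleotide) background model:
#' \eqn{\tilde X_w = X_w - n_1 p_w}, \eqn{\tilde Y_w = Y_w - n_2 q_w},
#' where \eqn{p_w} is the product of background frequencies of the letters
#' of \eqn{w} and \eqn{n} the number of valid windows.  The statistic is
#' \deqn{D2S = \sum_w \tilde X_w \tilde Y_w / \sqrt{\tilde X_w^2 + \tilde Y_w^2}}
#' summed over the union of observed words; terms with zero denominator
#' are skipped (never-observed words contribute nothing).
#'
#' @param p1,p2 [count_kmers()] profiles with matching `k` and `canonical`.
#' @return The D2S similarity (numeric scalar).
#' @export
d2s_similarity <- function(p1, p2) {
  if (p1$k != p2$k) stop("k-mer profiles have different k")
  if (!identical(p1$canonical, p2$canonical)) {
    stop("k-mer profiles have different canonical flags")
  }
  u <- sort(unique(c(p1$codes, p2$codes)))
  if (length(u) == 0L) return(0)
  X <- numeric(length(u)); X[match(p1$codes, u)] <- p1$counts
  Y <- numeric(length(u)); Y[match(p2$codes, u)] <- p2$counts
  Xc <- X - p1$n_positions * .kmer_bg_prob(u, p1$k, p1$bg_freq)
  Yc <- Y - p2$n_positions * .kmer_bg_prob(u, p2$k, p2$bg_freq)
  den <- sqrt(Xc^2 + Yc^2)
  ok <- den > 0
  sum(Xc[ok] * Yc[ok] / den[ok])
}

#' D2S distance d between two k-mer profiles
#'
#' The self-normalised similarity
#' \eqn{r = D2S(X,Y)/\sqrt{D2S(X,X)\,D2S(Y,Y)}} is mapped to the distance
#' \eqn{d = -\ln r}: 0 for identical genomes, unbounded for unrelated
#' ones.  Non-positive \eqn{r} (fully unrelated profiles) gives +Inf with
#' a warning.
#'
#' @inheritParams d2s_similarity
#' @return The distance d (numeric scalar, >= 0 up to rounding).
#' @export
d2s_distance <- function(p1, p2) {
  s11 <- d2s_similarity(p1, p1)
  s22 <- d2s_similarity(p2, p2)
  if (s11 <= 0 || s22 <= 0) stop("self-similarity must be positive")
  r <- d2s_similarity(p1, p2) / sqrt(s11 * s22)
  if (r <= 0) {
    warning("non-positive normalised similarity; returning Inf")
    return(Inf)
  }
  -log(r)
}

#' Pairwise D2S distance matrix
#'
#' @param profiles Named list of [count_kmers()] profiles.
#' @return Full symmetric matrix of distances with zero diagonal.
#' @export
d2s_distance_matrix <- function(profiles) {
  n <- length(profiles)
  nm <- names(profiles) %||% paste0("isolate", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- d2s_distance(profiles[[i]], profiles[[j]])
    }
  }
  m
}

#' Core k-mers shared by every isolate
#'
#' @param profiles Named list (>= 2) of [count_kmers()] profiles with
#'   matching `k` and `canonical`.
#' @return Object of class `core_kmer_report`: list with `k`, `canonical`,
#'   `core` (packed codes of k-mers present in every isolate) and `x`, the
#'   per-isolate percentage of core k-mers relative to that isolate's
#'   distinct k-mers.
#' @export
core_kmers <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least two k-mer profiles")
  ks <- vapply(profiles, `[[`, 1L, "k")
  can <- vapply(profiles, `[[`, TRUE, "canonical")
  if (length(unique(ks)) != 1L || length(unique(can)) != 1L) {
    stop("profiles must share k and canonical flag")
  }
  core <- Reduce(intersect, lapply(profiles, `[[`, "codes"))
  x <- vapply(profiles, function(p) {
    if (length(p$codes) == 0L) return(NA_real_)
    100 * length(core) / length(p$codes)
  }, 1.0)
  names(x) <- names(profiles) %||% paste0("isolate", seq_along(profiles))
  structure(list(k = ks[[1]], canonical = can[[1]],
                 core = sort(core), x = x),
            class = "core_kmer_report")
}

#' @export
print.core_kmer_report <- function(x, ...) {
  cat("core_kmer_report: k =", x$k, "|", length(x$core), "core k-mers\n")
  print(round(x$x, 2))
  invisible(x)
}

#' Locate core k-mer occurrences on an assembly as BED intervals
#'
#' Emits one 0-based half-open interval `[i, i+k)` per occurrence of a
#' core k-mer.  Under canonical matching a window matches when either its
#' forward or reverse-complement word is in the core set.
#'
#' @param assembly A [genome_assembly()].
#' @param core A [core_kmers()] report, or a character vector of k-mers
#'   (all the same length).
#' @param canonical Matching mode when `core` is a character vector.
#' @return A [feature_intervals()] table; the interval name is the core
#'   k-mer (in canonical form when applicable).
#' @export
map_core_kmers_to_bed <- function(assembly, core, canonical = TRUE) {
  if (inherits(core, "core_kmer_report")) {
    k <- core$k
    canonical <- core$canonical
    codes <- core$core
  } else {
    if (length(core) == 0L) return(feature_intervals())
    k <- unique(nchar(core))
    if (length(k) != 1L) stop("core k-mers must all have the same length")
    codes <- encode_kmers(paste(core, collapse = paste(rep("N", k), collapse = "")),
                          k = k, canonical = canonical)
    codes <- sort(unique(codes))
  }
  out <- list()
  for (sc in names(assembly)) {
    w <- encode_kmers_keep_pos(as.character(assembly[[sc]]), k, canonical)
    hit <- !is.na(match(w$codes, codes))
    if (any(hit)) {
      out[[sc]] <- data.frame(scaffold = sc, start = w$pos[hit] - 1L,
                              end = w$pos[hit] - 1L + k,
                              name = decode_kmers(w$codes[hit], k),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(feature_intervals())
  df <- do.call(rbind, out)
  feature_intervals(df$scaffold, df$start, df$end, df$name)
}

# as encode_kmers but keeps 1-based window start positions
encode_kmers_keep_pos <- function(seq, k, canonical) {
  b <- dna_to_int(seq)
  n <- length(b) - k + 1L
  if (n < 1L) return(list(codes = numeric(0), pos = integer(0)))
  code <- numeric(n)
  if (canonical) rc <- numeric(n)
  for (j in 0:(k - 1L)) {
    bj <- b[(1L + j):(n + j)]
    code <- code + bj * 4^(k - 1L - j)
    if (canonical) rc <- rc + (3L - bj) * 4^j
  }
  if (canonical) code <- pmin(code, rc)
  ok <- !is.na(code)
  list(codes = code[ok], pos = which(ok))
}

#' Intersect two sets of feature intervals
#'
#' Reports, per scaffold, the overlap of every overlapping pair of
#' intervals (overlap length >= 1; half-open abutment does not overlap),
#' mirroring `bedtools intersect` semantics.  Interval names are taken
#' from `a`.
#'
#' @param a,b [feature_intervals()] tables in the same coordinate
#'   convention.
#' @return A [feature_intervals()] table of overlaps.
#' @export
intersect_features <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(feature_intervals())
  ga <- GenomicRanges::GRanges(a$scaffold,
                               IRanges::IRanges(a$start + 1L, a$end))
  gb <- GenomicRanges::GRanges(b$scaffold,
                               IRanges::IRanges(b$start + 1L, b$end))
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  if (length(ov) == 0L) return(feature_intervals())
  pi <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(ov)],
                                  gb[S4Vectors::subjectHits(ov)])
  feature_intervals(as.character(GenomicRanges::seqnames(pi)),
                    BiocGenerics::start(pi) - 1L, BiocGenerics::end(pi),
                    a$name[S4Vectors::queryHits(ov)])
}
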