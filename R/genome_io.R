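# Input/output for the standard formats the pipeline touches: FASTA
# assemblies, GFF3 gene models, BLAST-style homology tables and BED
# feature intervals, plus the homology-hit filters applied before any
# downstream synteny or clustering step.

#' Construct a genome assembly object
#'
#' A genome assembly is a named character vector of upper-case scaffold
#' sequences over the alphabet \{A,C,G,T,N\}, with unique non-empty
#' scaffold ids.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all scaffolds must have non-empty ids")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(seqs))
  if (any(nchar(seqs) == 0L)) stop("empty scaffold sequence(s)")
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("scaffold sequences must be over {A,C,G,T,N}")
  }
  structure(setNames(seqs, ids), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x), "scaffold(s),",
      sum(nchar(unclass(x))), "bp total\n")
  invisible(x)
}

#' Read a genome assembly from FASTA
#'
#' Scaffold ids are the first whitespace-delimited token of each header.
#' Lower-case bases are upper-cased and any character outside
#' \{A,C,G,T,N\} (e.g. IUPAC ambiguity codes) is mapped to N; the number
#' of replaced characters is reported as a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_assembly()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  seqs <- toupper(as.character(ss))
  n_bad <- sum(nchar(seqs)) - sum(nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " non-ACGTN character(s) replaced by N in ", path)
  }
  genome_assembly(setNames(seqs, ids))
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(unclass(assembly))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' Coordinates are 0-based half-open.  `exons` is a list of two-column
#' matrices (start, end), one row per exon, in genomic order.  Per-scaffold
#' gene ranks (0-based order of gene start, ties broken by gene id) are
#' assigned here and are the coordinate system used by the synteny and
#' duplication modules.
#'
#' @param df Data frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` and a list column `exons`.
#' @return A `gene_annotation` data frame with an additional `rank` column.
#' @export
gene_annotation <- function(df) {
  needed <- c("gene_id", "scaffold", "start", "end", "strand", "exons")
  if (!all(needed %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene id(s)")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$start >= df$end)) stop("gene span must satisfy start < end")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L) {
      stop("gene ", df$gene_id[i], ": exons must be a matrix with >= 1 row")
    }
    if (any(ex[, 1] >= ex[, 2])) {
      stop("gene ", df$gene_id[i], ": zero- or negative-width exon")
    }
    if (is.unsorted(ex[, 1], strictly = TRUE) ||
        any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("gene ", df$gene_id[i], ": exons must be sorted and non-overlapping")
    }
    if (ex[1, 1] < df$start[i] || ex[nrow(ex), 2] > df$end[i]) {
      stop("exon outside gene span for gene ", df$gene_id[i])
    }
  }
  df <- df[order(df$scaffold, df$start, df$gene_id), , drop = FALSE]
  df$rank <- as.integer(stats::ave(df$start, df$scaffold,
                                   FUN = function(x) seq_along(x) - 1L))
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Number of exons per gene
#' @param annot A [gene_annotation()].
#' @return Integer vector named by gene id.
#' @export
n_exons <- function(annot) {
  setNames(vapply(annot$exons, nrow, 1L), annot$gene_id)
}

#' Read gene models from GFF3
#'
#' Parses gene and exon (or CDS, when no exons are present) features,
#' following ID/Parent links through intermediate mRNA records.  GFF3
#' 1-based inclusive coordinates are converted to 0-based half-open.
#' Genes without any exon/CDS child are treated as single-exon genes
#' spanning the whole gene interval.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_annotation()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, "")
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  gene_ids <- ids[is_gene]
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in ", path)

  # resolve the gene ancestor of every feature (one level of mRNA allowed)
  parent_of <- setNames(parents, ids)
  to_gene <- function(id) {
    seen <- 0L
    while (!is.na(id) && !(id %in% gene_ids) && seen < 5L) {
      id <- parent_of[[id]] %||% NA_character_
      seen <- seen + 1L
    }
    if (is.na(id) || !(id %in% gene_ids)) NA_character_ else id
  }

  child_type <- if (any(type == "exon")) "exon" else "CDS"
  is_child <- type == child_type
  child_gene <- vapply(parents[is_child], to_gene, "")
  cs <- BiocGenerics::start(gr)[is_child] - 1L
  ce <- BiocGenerics::end(gr)[is_child]

  gs <- BiocGenerics::start(gr)[is_gene] - 1L
  ge <- BiocGenerics::end(gr)[is_gene]
  gscaf <- as.character(GenomicRanges::seqnames(gr))[is_gene]
  gstrand <- as.character(BiocGenerics::strand(gr))[is_gene]
  gstrand[!gstrand %in% c("+", "-")] <- "+"

  exons <- lapply(seq_along(gene_ids), function(i) {
    sel <- which(child_gene == gene_ids[i])
    if (length(sel) == 0L) {
      return(matrix(c(gs[i], ge[i]), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    m <- cbind(start = cs[sel], end = ce[sel])
    m <- m[order(m[, 1]), , drop = FALSE]
    if (m[1, 1] < gs[i] || m[nrow(m), 2] > ge[i]) {
      stop("exon outside gene span for gene ", gene_ids[i])
    }
    m
  })

  gene_annotation(data.frame(
    gene_id = gene_ids, scaffold = gscaf, start = gs, end = ge,
    strand = gstrand, exons = I(exons), stringsAsFactors = FALSE))
}

#' Read and filter a protein homology table
#'
#' Reads the 12-column BLAST tabular dialect, optionally extended with two
#' coverage columns (`qcovs`, `scovs`).  Self hits (query == subject) are
#' dropped, then hits are kept when `evalue < max_evalue` and query
#' \emph{or} subject coverage exceeds `min_cov`; per query the best `top_n`
#' hits are retained, ranked by ascending e-value and then descending bit
#' score.
#'
#' @param path Path to the tab-separated table (no header).
#' @param max_evalue E-value cut-off (strict `<`).
#' @param min_cov Coverage cut-off in percent (strict `>`, either side).
#' @param top_n Hits retained per query.
#' @param lengths Optional named numeric vector of sequence lengths (or a
#'   path to a two-column id/length TSV), used to compute coverage when the
#'   table has only 12 columns.
#' @return Data frame of class `homology_hits` with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_len`, `evalue`, `bitscore`,
#'   `query_cov`, `subject_cov`.
#' @export
read_homology_table <- function(path, max_evalue = 1e-5, min_cov = 50,
                                top_n = 5L, lengths = NULL) {
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) && any(!nf %in% c(12L, 14L))) {
    stop("malformed homology table row at line ",
         which(!nf %in% c(12L, 14L))[1L], " of ", path)
  }
  df <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("cannot parse homology table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) {
    return(homology_hits(data.frame(
      query_id = character(), subject_id = character(),
      pct_identity = numeric(), aln_len = integer(), evalue = numeric(),
      bitscore = numeric(), query_cov = numeric(), subject_cov = numeric())))
  }
  if (ncol(df) == 12L) {
    if (is.null(lengths)) {
      stop("table has no coverage columns and no `lengths` supplied")
    }
    if (is.character(lengths) && length(lengths) == 1L) {
      lt <- read.delim(lengths, header = FALSE, stringsAsFactors = FALSE)
      lengths <- setNames(as.numeric(lt[[2]]), lt[[1]])
    }
    missing_ids <- setdiff(unique(c(df[[1]], df[[2]])), names(lengths))
    if (length(missing_ids)) {
      stop("no sequence length for: ", paste(head(missing_ids, 5), collapse = ", "))
    }
    df$qcov <- 100 * df[[4]] / lengths[df[[1]]]
    df$scov <- 100 * df[[4]] / lengths[df[[2]]]
  } else {
    df$qcov <- as.numeric(df[[13]])
    df$scov <- as.numeric(df[[14]])
  }
  hits <- data.frame(
    query_id = as.character(df[[1]]), subject_id = as.character(df[[2]]),
    pct_identity = as.numeric(df[[3]]), aln_len = as.integer(df[[4]]),
    evalue = as.numeric(df[[11]]), bitscore = as.numeric(df[[12]]),
    query_cov = df$qcov, subject_cov = df$scov,
    stringsAsFactors = FALSE)
  if (anyNA(hits$evalue) || anyNA(hits$bitscore)) {
    stop("malformed numeric field(s) in homology table ", path)
  }
  filter_homology_hits(homology_hits(hits), max_evalue = max_evalue,
                       min_cov = min_cov, top_n = top_n)
}

#' Construct a homology hit table
#' @param df Data frame with the `homology_hits` columns.
#' @return The validated data frame with class `homology_hits`.
#' @export
homology_hits <- function(df) {
  needed <- c("query_id", "subject_id", "pct_identity", "aln_len",
              "evalue", "bitscore", "query_cov", "subject_cov")
  if (!all(needed %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(needed, names(df)), collapse = ", "))
  }
  bad <- df$evalue < 0 |
    df$pct_identity < 0 | df$pct_identity > 100 |
    df$query_cov < 0 | df$query_cov > 100 |
    df$subject_cov < 0 | df$subject_cov > 100
  if (any(bad)) stop("hit(s) violate percentage/e-value bounds")
  rownames(df) <- NULL
  class(df) <- c("homology_hits", "data.frame")
  df
}

#' Apply the standard homology-hit filters
#'
#' @inheritParams read_homology_table
#' @param hits A [homology_hits()] table.
#' @return Filtered [homology_hits()].
#' @export
filter_homology_hits <- function(hits, max_evalue = 1e-5, min_cov = 50,
                                 top_n = 5L) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  keep <- hits$evalue < max_evalue &
    (hits$query_cov > min_cov | hits$subject_cov > min_cov)
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(hits$query_id, hits$evalue, -hits$bitscore), ,
                 drop = FALSE]
    idx <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                      FUN = seq_along)
    hits <- hits[idx <= top_n, , drop = FALSE]
  }
  rownames(hits) <- NULL
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' Construct a feature interval table
#'
#' 0-based half-open intervals on named scaffolds, the package's internal
#' equivalent of BED4.
#'
#' @param scaffold,start,end,name Vectors of equal length.
#' @return Data frame of class `feature_intervals`.
#' @export
feature_intervals <- function(scaffold = character(), start = integer(),
                              end = integer(), name = character()) {
  if (length(name) == 0L && length(scaffold) > 0L) {
    name <- rep(".", length(scaffold))
  }
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (any(!nzchar(df$scaffold))) stop("empty scaffold id in intervals")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  class(df) <- c("feature_intervals", "data.frame")
  df
}

#' Read feature intervals from BED
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A [feature_intervals()] table (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) && any(BiocGenerics::width(gr) < 1L)) {
    stop("BED record with start >= end in ", path)
  }
  nm <- gr$name
  if (is.null(nm)) nm <- rep(".", length(gr))
  nm[is.na(nm)] <- "."
  feature_intervals(as.character(GenomicRanges::seqnames(gr)),
                    BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr), nm)
}

#' Write feature intervals as BED4
#'
#' @param records A [feature_intervals()] table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(records, path) {
  write.table(records[, c("scaffold", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
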