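# End-to-end orchestration: simulate fixtures, run the divergence stage
# (Q/ID, d, core k-mers), run the duplication stage (labels, collinear
# blocks, TD blocks with Ka/Ks, orthogroup inflation profile, introner
# stats), and write every product as a deterministic TSV stamped with the
# config hash.  Tables are written atomically (write-then-rename).

#' Write a homology table in the extended BLAST tabular dialect
#'
#' 14 tab-separated columns: the standard 12 plus query and subject
#' coverage.  Unknown alignment bookkeeping columns are written as 0.
#'
#' @param hits A [homology_hits()] table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  df <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_len, 0L, 0L, 0L, 0L, 0L, 0L, hits$evalue,
                   hits$bitscore, hits$query_cov, hits$subject_cov)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene and exon records with ID/Parent links, converting the
#' internal 0-based half-open coordinates back to GFF3 1-based
#' inclusive.  The output is deterministic (no date stamps).
#'
#' @param annot A [gene_annotation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(annot, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(annot))) {
    g <- annot[i, ]
    lines <- c(lines, paste(g$scaffold, "intradiv", "gene", g$start + 1L,
                            g$end, ".", g$strand, ".",
                            paste0("ID=", g$gene_id), sep = "\t"))
    ex <- annot$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(g$scaffold, "intradiv", "exon", ex[j, 1] + 1L,
                              ex[j, 2], ".", g$strand, ".",
                              paste0("ID=", g$gene_id, ".exon", j,
                                     ";Parent=", g$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Accepts a YAML file or a list.  Defaults: `k = 23`,
#' `min_report_len = c(100, 1000, 10000)`,
#' `inflations = c(1.5, 2, 4, 6, 8, 10)`, `seed = 1`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$k <- as.integer(config$k %||% 23L)
  config$min_report_len <- as.numeric(config$min_report_len %||%
                                        c(100, 1000, 10000))
  config$inflations <- as.numeric(config$inflations %||%
                                    c(1.5, 2, 4, 6, 8, 10))
  config$seed <- as.integer(config$seed %||% 1L)
  if (config$k < 1L) stop("k must be >= 1")
  if (any(config$inflations <= 1)) stop("inflation values must be > 1")
  for (iso in names(config$isolates %||% list())) {
    for (f in unlist(config$isolates[[iso]])) {
      if (!file.exists(f)) stop("missing input file for ", iso, ": ", f)
    }
  }
  class(config) <- c("run_config", "list")
  config
}

# Hash the configuration with paths reduced to basenames and the output
# directory dropped, so reruns of the same parameters in different
# directories produce byte-identical tables.
.config_key <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  strip <- function(x) {
    if (is.list(x)) return(lapply(x, strip))
    if (is.character(x)) return(basename(x))
    x
  }
  config_hash(strip(cfg))
}

.stamp <- function(config) {
  paste0("config=", .config_key(config), " seed=", config$seed)
}

#' Simulate a two-isolate fixture set
#'
#' Writes, under `out_dir`: a diverged genome pair for the divergence
#' stage (`iso1.fasta`, `iso2.fasta`, from [make_genome_pair()]), a gene
#' landscape with planted duplications for isolate 1
#' ([plant_gene_landscape()]) and a clone of it (genes and scaffolds
#' prefixed `b_`) as isolate 2, with per-isolate homology tables, CDS
#' FASTA, GFF3, a cross-isolate homology table (each gene paired with its
#' clone), and a truth JSON.
#'
#' @param config See [read_run_config()]; uses `seed`, `out_dir` and
#'   optional `sim` sub-list (`L`, `p_sub`, landscape sizes).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim %||% list()
  gp <- make_genome_pair(L = sim$L %||% 100000L, gc = sim$gc %||% 0.5,
                         p_sub = sim$p_sub %||% 0.01,
                         seed = config$seed)
  write_fasta(gp$genome1, file.path(out, "iso1.fasta"))
  write_fasta(gp$genome2, file.path(out, "iso2.fasta"))

  ls1 <- plant_gene_landscape(
    n_scaffolds = sim$n_scaffolds %||% 3L,
    genes_per_scaffold = sim$genes_per_scaffold %||% 60L,
    n_tandem = sim$n_tandem %||% 8L, n_proximal = sim$n_proximal %||% 8L,
    n_dispersed = sim$n_dispersed %||% 8L, wgd = sim$wgd %||% TRUE,
    single_exon_fraction = sim$single_exon_fraction %||% 0.3,
    seed = config$seed)
  ls2 <- clone_landscape(ls1, prefix = "b_")
  for (tag in c("a", "b")) {
    ls <- if (tag == "a") ls1 else ls2
    write_fasta(ls$assembly, file.path(out, paste0("land_", tag, ".fasta")))
    write_gff3(ls$annot, file.path(out, paste0("land_", tag, ".gff3")))
    write_homology_table(ls$hits, file.path(out, paste0("land_", tag,
                                                        "_hits.tsv")))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ls$cds),
                                file.path(out, paste0("land_", tag,
                                                      "_cds.fasta")))
  }
  cross <- homology_hits(data.frame(
    query_id = ls1$annot$gene_id,
    subject_id = paste0("b_", ls1$annot$gene_id),
    pct_identity = 100,
    aln_len = as.integer(nchar(ls1$cds[ls1$annot$gene_id]) / 3L),
    evalue = 0,
    bitscore = 2 * nchar(ls1$cds[ls1$annot$gene_id]) / 3L,
    query_cov = 100, subject_cov = 100, stringsAsFactors = FALSE))
  write_homology_table(cross, file.path(out, "cross_hits.tsv"))
  truth <- list(genome_pair = gp$truth, landscape = ls1$truth)
  jsonlite::write_json(truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Clone a planted landscape under new gene and scaffold ids
#'
#' @param landscape A [plant_gene_landscape()] result.
#' @param prefix Prefix applied to scaffold and gene ids.
#' @return A landscape list with renamed ids (same sequences and truth
#'   classes).
#' @export
clone_landscape <- function(landscape, prefix = "b_") {
  ann <- as.data.frame(landscape$annot)
  ann$gene_id <- paste0(prefix, ann$gene_id)
  ann$scaffold <- paste0(prefix, ann$scaffold)
  ann$rank <- NULL
  hits <- landscape$hits
  hits$query_id <- paste0(prefix, hits$query_id)
  hits$subject_id <- paste0(prefix, hits$subject_id)
  truth <- landscape$truth
  names(truth$labels) <- paste0(prefix, names(truth$labels))
  list(assembly = genome_assembly(
         setNames(as.character(landscape$assembly),
                  paste0(prefix, names(landscape$assembly)))),
       annot = gene_annotation(ann),
       hits = homology_hits(as.data.frame(hits)),
       cds = setNames(landscape$cds, paste0(prefix, names(landscape$cds))),
       truth = truth)
}

# restrict an alignment set to blocks of at least min_len columns
filter_alignment_set <- function(alnset, min_len) {
  alignment_set(alnset$blocks[alnset$blocks$length >= min_len, ,
                              drop = FALSE],
                alnset$ref_total, alnset$qry_total, min_len)
}

#' Run the divergence stage
#'
#' Aligns every ordered pair of isolate assemblies and reports Q and ID
#' at each `min_report_len`; computes the D2S distance d for every
#' unordered pair and the core k-mer fraction x across all isolates.
#' Writes `qid.tsv`, `d_matrix.tsv`, `core_x.tsv` and `manifest.json`
#' under `out_dir`.
#'
#' @param config See [read_run_config()]; needs `isolates` (named list
#'   with at least a `fasta` entry each, or named character vector of
#'   FASTA paths) and `out_dir`.
#' @return List with `qid` (data frame), `d` (matrix), `core`
#'   ([core_kmers()] report), invisibly written to disk.
#' @export
run_divergence <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  isolates <- config$isolates %||% stop("config needs >= 2 isolates")
  if (length(isolates) < 2L) stop("config needs >= 2 isolates")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fasta_of <- function(x) if (is.list(x)) x$fasta else x
  asm <- lapply(isolates, function(x) read_fasta(fasta_of(x)))
  nm <- names(asm)
  rows <- list()
  base_len <- min(config$min_report_len)
  for (r in nm) {
    for (q in setdiff(nm, r)) {
      aln <- align_genomes(asm[[r]], asm[[q]], min_report_len = base_len)
      for (t in sort(config$min_report_len)) {
        sub <- filter_alignment_set(aln, t)
        rows[[length(rows) + 1L]] <- data.frame(
          ref = r, qry = q, min_report_len = t, Q = compute_Q(sub),
          ID = if (nrow(sub$blocks)) compute_ID(sub) else NA_real_)
      }
    }
  }
  qid <- do.call(rbind, rows)
  profiles <- lapply(asm, count_kmers, k = config$k)
  d <- d2s_distance_matrix(profiles)
  core <- core_kmers(profiles)
  stamp <- .stamp(config)
  write_tsv_atomic(qid, file.path(out, "qid.tsv"), stamp)
  write_tsv_atomic(as.data.frame(d), file.path(out, "d_matrix.tsv"), stamp)
  write_tsv_atomic(data.frame(isolate = names(core$x), x = core$x),
                   file.path(out, "core_x.tsv"), stamp)
  manifest <- list(stage = "divergence", config_hash = .config_key(config),
                   seed = config$seed, isolates = nm,
                   n_core_kmers = length(core$core))
  jsonlite::write_json(manifest, file.path(out, "manifest_divergence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qid = qid, d = d, core = core))
}

#' Run the duplication stage
#'
#' For each isolate (gff3 + homology + cds + fasta): duplication labels
#' and per-class counts, TD blocks with per-pair Ka/Ks and selection
#' classes, a Table-1-style TD summary, and introner-element statistics.
#' Across isolates: inter-isolate collinear blocks (with Ka+Ks anchor
#' deduplication) from the `cross_homology` table, and the orthogroup
#' isolate-specific fraction across the configured inflation parameters.
#' Writes one TSV per product plus `manifest_duplication.json`.
#'
#' @param config See [read_run_config()]; `isolates` entries need
#'   `fasta`, `gff3`, `cds`, `homology`; optional top-level
#'   `cross_homology`.
#' @return Invisible list of the main in-memory products.
#' @export
run_duplication <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir %||% stop("config needs out_dir")
  isolates <- config$isolates %||% stop("config needs isolates")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stamp <- .stamp(config)
  per <- list()
  label_rows <- list()
  td_rows <- list()
  block_rows <- list()
  ie_rows <- list()
  for (iso in names(isolates)) {
    entry <- isolates[[iso]]
    annot <- read_gff3(entry$gff3)
    asm <- read_fasta(entry$fasta)
    cds_ss <- Biostrings::readBStringSet(entry$cds)
    cds <- setNames(toupper(as.character(cds_ss)),
                    vapply(strsplit(names(cds_ss), "[ \t]"), `[`, "", 1L))
    hits <- read_homology_table(entry$homology)
    labels <- classify_duplicates(annot, hits)
    counts <- duplication_summary(labels)
    label_rows[[iso]] <- data.frame(isolate = iso, t(counts))
    tds <- find_td_blocks(annot, hits)
    tds <- lapply(tds, score_td_block, cds = cds)
    td_rows[[iso]] <- cbind(isolate = iso, td_summary_table(annot, tds))
    if (length(tds)) {
      block_rows[[iso]] <- data.frame(
        isolate = iso, block = seq_along(tds),
        scaffold = vapply(tds, `[[`, "", "scaffold"),
        size = vapply(tds, `[[`, 1L, "size"),
        mean_omega = vapply(tds, `[[`, 1.0, "mean_omega"),
        mean_ks = vapply(tds, `[[`, 1.0, "mean_ks"),
        selection_class = vapply(tds, `[[`, "", "selection_class"))
    }
    ie <- scan_introners(annot, asm)
    ie_rows[[iso]] <- cbind(isolate = iso, ie_gene_stats(ie, annot, tds))
    per[[iso]] <- list(annot = annot, hits = hits, cds = cds,
                       labels = labels, td = tds)
  }
  write_tsv_atomic(do.call(rbind, label_rows),
                   file.path(out, "duplication_labels.tsv"), stamp)
  write_tsv_atomic(do.call(rbind, td_rows),
                   file.path(out, "td_summary.tsv"), stamp)
  if (length(block_rows)) {
    write_tsv_atomic(do.call(rbind, block_rows),
                     file.path(out, "td_blocks.tsv"), stamp)
  }
  write_tsv_atomic(do.call(rbind, ie_rows),
                   file.path(out, "ie_stats.tsv"), stamp)

  inter <- list()
  if (!is.null(config$cross_homology) && length(per) >= 2L) {
    cross <- read_homology_table(config$cross_homology)
    nms <- names(per)
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        a <- per[[nms[i]]]; b <- per[[nms[j]]]
        blocks <- detect_collinear_blocks(a$annot, b$annot, cross,
                                          mode = "inter")
        if (length(blocks)) {
          cds_all <- c(a$cds, b$cds)
          anchors <- unique(do.call(rbind, lapply(blocks, function(bl) {
            bl$anchors[, c("gene_a", "gene_b")]
          })))
          kk <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(r) {
            res <- ng86(align_codons(cds_all[[anchors$gene_a[r]]],
                                     cds_all[[anchors$gene_b[r]]]))
            data.frame(gene_a = anchors$gene_a[r],
                       gene_b = anchors$gene_b[r],
                       ka_ks = res$ka + res$ks)
          }))
          kk$ka_ks[is.na(kk$ka_ks)] <- Inf
          blocks <- dedup_wgd_pairs(blocks, kk)
        }
        tab <- collinearity_table(blocks, a$annot, b$annot)$anchors
        if (nrow(tab)) {
          inter[[paste(nms[i], nms[j], sep = "~")]] <-
            cbind(pair = paste(nms[i], nms[j], sep = "~"), tab)
        }
      }
    }
  }
  if (length(inter)) {
    write_tsv_atomic(do.call(rbind, inter),
                     file.path(out, "collinear_blocks.tsv"), stamp)
  }

  all_hits <- do.call(rbind, c(lapply(per, function(p) as.data.frame(p$hits)),
                               if (!is.null(config$cross_homology)) {
                                 list(as.data.frame(
                                   read_homology_table(config$cross_homology)))
                               }))
  iso_tags <- unlist(lapply(names(per), function(iso) {
    setNames(rep(iso, nrow(per[[iso]]$annot)), per[[iso]]$annot$gene_id)
  }))
  graph <- build_graph(homology_hits(all_hits), iso_tags)
  prof <- inflation_profile(graph, config$inflations)
  write_tsv_atomic(prof, file.path(out, "orthogroup_fractions.tsv"), stamp)

  manifest <- list(stage = "duplication",
                   config_hash = .config_key(config),
                   seed = config$seed, isolates = names(per),
                   n_inter_block_tables = length(inter))
  jsonlite::write_json(manifest, file.path(out, "manifest_duplication.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_isolate = per, inflation_profile = prof))
}
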