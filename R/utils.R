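# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes A=0 C=1 G=2 T=3, NA elsewhere (N etc.).
dna_to_int <- function(seq) {
  x <- utf8ToInt(seq)
  out <- rep(NA_integer_, length(x))
  out[x == 65L] <- 0L
  out[x == 67L] <- 1L
  out[x == 71L] <- 2L
  out[x == 84L] <- 3L
  out
}

int_to_dna <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

# Vectorised reverse complement of character sequences (handles N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Random i.i.d. DNA string at a given GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# djb2 string hash, reported as fixed-width hex; used to stamp run outputs.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a table atomically (write to a temp file, then rename), so a failed
# run never leaves a truncated output behind.
write_tsv_atomic <- function(df, path, header_comment = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv_plain <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
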