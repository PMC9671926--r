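# Sequence, motif and table I/O: the shared data model of the pipeline.
#
# Coordinates are 0-based half-open everywhere internally (BED convention);
# 1-based coordinates appear only in human-readable messages.

#' Construct a promoter set
#'
#' A promoter set holds one record per gene: the promoter sequence (nominally
#' the 5 kb upstream of the transcription start site), its strand and length.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param sequence Character vector of sequences over `A`, `C`, `G`, `T`, `N`
#'   (lowercase accepted, uppercased on construction).
#' @param strand `"+"` or `"-"` per record (recycled).
#'
#' @return A `data.frame` of class `promoter_set` with columns `gene_id`,
#'   `sequence`, `strand`, `length`.
#' @export
promoter_set <- function(gene_id, sequence, strand = "+") {
  if (length(gene_id) != length(sequence)) {
    stop("'gene_id' and 'sequence' must have the same length", call. = FALSE)
  }
  sequence <- toupper(sequence)
  strand <- rep_len(strand, length(gene_id))
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in sequence '%s' at position %d",
                 substr(sequence[i], bad[i], bad[i]), gene_id[i], bad[i]),
         call. = FALSE)
  }
  out <- data.frame(gene_id = unname(as.character(gene_id)),
                    sequence = unname(sequence),
                    strand = unname(strand),
                    length = unname(nchar(sequence)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Read a FASTA file into a promoter set
#'
#' One record per FASTA entry, uppercased, order preserved. `N` is allowed;
#' any other non-`ACGT` character is an error naming the sequence and
#' position. With `type = "rna"`, `U` is accepted and normalized to `T`.
#' A `strand=-` token in the header sets the record strand.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (default) or `"rna"`.
#' @return A [promoter_set].
#' @export
read_fasta <- function(path, type = c("dna", "rna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  strand <- ifelse(grepl("(^| )strand=-( |$)", headers), "-", "+")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  if (type == "rna") {
    bad <- regexpr("[^ACGUTN]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop(sprintf("invalid character '%s' in sequence '%s' at position %d",
                   substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
           call. = FALSE)
    }
    seqs <- chartr("U", "T", seqs)
  }
  promoter_set(ids, seqs, strand)
}

#' Write a promoter set to FASTA
#'
#' Inverse of [read_fasta()]: `write_fasta` then `read_fasta` reproduces the
#' records exactly. Minus-strand records carry a `strand=-` header token.
#'
#' @param x A [promoter_set].
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "promoter_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- x$gene_id[i]
    if (x$strand[i] == "-") hdr <- paste0(hdr, " strand=-")
    writeLines(paste0(">", hdr), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read the first sequence of a FASTA file as a plain string
#'
#' Convenience for single-sequence inputs such as the lncRNA itself;
#' `U` is normalized to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A single character string.
#' @export
read_rna_sequence <- function(path) {
  ps <- read_fasta(path, type = "rna")
  ps$sequence[1L]
}

#' Construct a motif model
#'
#' A position probability matrix over `A,C,G,T` with background frequencies
#' and an additive pseudocount policy applied at scoring time (not stored in
#' the probabilities).
#'
#' @param motif_id Motif identifier.
#' @param probs 4 x width numeric matrix; each column must sum to 1 within
#'   `1e-6` and all entries must be non-negative. Rows are `A,C,G,T`.
#' @param background Length-4 background frequencies summing to 1 within
#'   `1e-6` (default uniform).
#' @param nsites Optional number of contributing sites (carried through I/O).
#' @param evalue Optional discovery E-value (carried through I/O so the
#'   E-value < 0.05 screen can be applied downstream).
#'
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(motif_id, probs, background = rep(0.25, 4),
                        nsites = NULL, evalue = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("'probs' must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(probs) < 2L) stop("motif width must be >= 2", call. = FALSE)
  if (any(probs < 0)) stop("motif probabilities must be non-negative", call. = FALSE)
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-6)) {
    j <- which(abs(cs - 1) > 1e-6)[1L]
    stop(sprintf("motif '%s': column %d sums to %.8f, not 1", motif_id, j, cs[j]),
         call. = FALSE)
  }
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive frequencies summing to 1", call. = FALSE)
  }
  dimnames(probs) <- list(.BASES, NULL)
  structure(list(motif_id = as.character(motif_id),
                 width = ncol(probs),
                 probs = probs,
                 background = as.numeric(background),
                 nsites = nsites,
                 evalue = evalue),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s  width=%d%s\n", x$motif_id, x$width,
              if (!is.null(x$evalue)) sprintf("  E=%.3g", x$evalue) else ""))
  invisible(x)
}

#' Reverse complement of a motif model
#'
#' @param motif A [motif_model].
#' @return A `motif_model` on the opposite strand.
#' @export
motif_rc <- function(motif) {
  p <- motif$probs[4:1, rev(seq_len(motif$width)), drop = FALSE]
  dimnames(p) <- list(.BASES, NULL)
  motif_model(motif$motif_id, p, motif$background,
              nsites = motif$nsites, evalue = motif$evalue)
}

#' Read motifs in MEME minimal format
#'
#' Parses the minimal (text) dialect: a `MEME version` line, optional
#' `ALPHABET`/`strands`/background lines, then `MOTIF` blocks with a
#' `letter-probability matrix:` header. The background defaults to uniform
#' when absent. Probability rows must sum to 1 within `1e-3` (then
#' renormalized exactly); a row count differing from the declared `w=` is an
#' error. `nsites=` and `E=` are carried onto the motif when present.
#'
#' @param path Path to a MEME minimal motif file.
#' @return A named list of [motif_model] objects.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal motif file (missing 'MEME version' line): ", path,
         call. = FALSE)
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    j <- bg_at[1L] + 1L
    while (j <= length(lines) && !nzchar(trimws(lines[j]))) j <- j + 1L
    toks <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2L, 8L, by = 2L)])
      keys <- toks[seq(1L, 7L, by = 2L)]
      background <- vals[match(.BASES, keys)]
      if (any(is.na(background))) {
        stop("malformed background line in ", path, call. = FALSE)
      }
      background <- background / sum(background)
    }
  }
  starts <- grep("^MOTIF( |\t)", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path, call. = FALSE)
  motifs <- list()
  for (s in starts) {
    toks <- strsplit(trimws(lines[s]), "[ \t]+")[[1]]
    id <- toks[2L]
    j <- s + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix:", lines[j])) {
      if (grepl("^MOTIF( |\t)", lines[j])) break
      j <- j + 1L
    }
    if (j > length(lines) || !grepl("^letter-probability matrix:", lines[j])) {
      stop(sprintf("motif '%s': missing letter-probability matrix", id),
           call. = FALSE)
    }
    get_field <- function(key) {
      m <- regmatches(lines[j], regexec(paste0(key, "=[ ]*([0-9.eE+-]+)"), lines[j]))[[1]]
      if (length(m) == 2L) as.numeric(m[2L]) else NULL
    }
    w <- get_field("w")
    nsites <- get_field("nsites")
    evalue <- get_field("E")
    if (is.null(w)) stop(sprintf("motif '%s': missing w= in matrix header", id),
                         call. = FALSE)
    rows <- list()
    k <- j + 1L
    while (k <= length(lines)) {
      tl <- trimws(lines[k])
      if (!nzchar(tl) || grepl("^MOTIF( |\t)", lines[k]) ||
          grepl("^URL", lines[k])) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "[ \t]+")[[1]]))
      if (any(is.na(vals))) break
      rows[[length(rows) + 1L]] <- vals
      k <- k + 1L
    }
    if (length(rows) != w) {
      stop(sprintf("motif '%s': %d probability rows but declared w=%d",
                   id, length(rows), as.integer(w)), call. = FALSE)
    }
    mat <- do.call(rbind, rows)
    if (ncol(mat) != 4L) {
      stop(sprintf("motif '%s': expected 4 letter probabilities per row", id),
           call. = FALSE)
    }
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-3)) {
      p <- which(abs(rs - 1) > 1e-3)[1L]
      stop(sprintf("motif '%s': position %d probabilities sum to %.6f, not 1",
                   id, p, rs[p]), call. = FALSE)
    }
    mat <- mat / rs  # renormalize exactly
    motifs[[id]] <- motif_model(id, t(mat), background,
                                nsites = nsites, evalue = evalue)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' Probabilities are written with enough digits that a read/write round-trip
#' is lossless to within `1e-9`.
#'
#' @param motifs A list of [motif_model] objects.
#' @param path Output path.
#' @param background Background written to the file header (defaults to the
#'   first motif's background).
#' @export
write_meme_motifs <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  stopifnot(length(motifs) > 0L)
  background <- background %||% motifs[[1L]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(rbind(.BASES, format(background, digits = 10)),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m$motif_id), con)
    hdr <- sprintf("letter-probability matrix: alength= 4 w= %d", m$width)
    if (!is.null(m$nsites)) hdr <- sprintf("%s nsites= %d", hdr, as.integer(m$nsites))
    if (!is.null(m$evalue)) hdr <- sprintf("%s E= %g", hdr, m$evalue)
    writeLines(hdr, con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.9f", m$probs[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a typed tab-separated table
#'
#' Header required; lines starting with `#` (provenance headers written by
#' [write_tsv_table()]) are skipped. Columns named in `schema` are coerced to
#' the declared type; a missing required column is an error naming it.
#'
#' @param path Path to a TSV file.
#' @param schema Named character vector mapping column name to one of
#'   `"character"`, `"double"`, `"integer"`, `"logical"`.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (col in names(schema)) {
      df[[col]] <- switch(schema[[col]],
        character = as.character(df[[col]]),
        double = {
          v <- suppressWarnings(as.numeric(df[[col]]))
          if (any(is.na(v) & !is.na(df[[col]]))) {
            stop(sprintf("column '%s' in %s is not numeric", col, path),
                 call. = FALSE)
          }
          v
        },
        integer = {
          v <- suppressWarnings(as.integer(df[[col]]))
          if (any(is.na(v) & !is.na(df[[col]]))) {
            stop(sprintf("column '%s' in %s is not integer", col, path),
                 call. = FALSE)
          }
          v
        },
        logical = {
          v <- df[[col]]
          if (!is.logical(v)) v <- toupper(as.character(v)) %in% c("TRUE", "T", "1")
          v
        },
        stop("unknown schema type for column ", col, call. = FALSE))
    }
  }
  df
}

#' Write a tab-separated table with optional provenance header
#'
#' Columns are written in the order of the data frame; `provenance` entries
#' become `# key: value` comment lines that [read_tsv_table()] skips.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param provenance Optional named list/vector of provenance fields.
#' @export
write_tsv_table <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
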