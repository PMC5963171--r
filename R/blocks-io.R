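# Readers and writers for the flat-file formats the toolkit touches:
# BLOCKS ungapped alignment blocks, SCOP/ASTRAL-style FASTA, and
# '#'-commented square substitution-matrix files.

#' Construct an alignment block
#'
#' A block is one ungapped, fixed-width segment of a multiple alignment:
#' every row has exactly `width` residues.  Blocks are the raw material for
#' substitution-matrix counting.
#'
#' @param block_id Identifier for the block.
#' @param rows Named character vector: names are sequence identifiers, values
#'   are residue strings of equal length.  Residues are uppercased; letters
#'   outside the 20-residue alphabet (B, Z, X, ...) are retained here and
#'   excluded later by the counting step.
#' @param description Optional free-text description.
#' @return An object of class `block` with fields `block_id`, `description`,
#'   `width`, `rows` (named character vector).
#' @export
#' @examples
#' new_block("BL001", c(s1 = "AAVK", s2 = "AAIK"))
new_block <- function(block_id, rows, description = "") {
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == "")) {
    stop("block rows must be a named character vector (names = sequence ids)")
  }
  if (anyDuplicated(names(rows))) {
    stop("duplicate sequence ids in block ", block_id)
  }
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(rows) < 1L) stop("block ", block_id, " has no rows")
  if (length(unique(widths)) != 1L) {
    stop("malformed block ", block_id, ": rows have unequal widths")
  }
  structure(
    list(block_id = as.character(block_id),
         description = as.character(description),
         width = unname(widths[1L]),
         rows = rows),
    class = "block")
}

#' @export
print.block <- function(x, ...) {
  cat("<block>", x$block_id, " width=", x$width, " depth=", length(x$rows),
      "\n", sep = "")
  shown <- head(x$rows, 6L)
  for (i in seq_along(shown)) {
    cat(sprintf("  %-20s %s\n", names(shown)[i], shown[i]))
  }
  if (length(x$rows) > 6L) cat("  ... ", length(x$rows) - 6L, " more rows\n")
  invisible(x)
}

#' Read a BLOCKS flat file
#'
#' Parses the BLOCKS database flat format: per-block header lines
#' (`ID`/`AC`/`DE`/`BL`), one line per sequence
#' `"<id>  (<start>) <RESIDUES> <weight>"`, and a `//` terminator per block.
#' Header dialects drift slightly across BLOCKS releases, so parsing is
#' lenient: any of the header lines may be absent, and the declared width
#' (`width=` on the `BL` line) is checked against the rows when present.
#'
#' The in-file weight column is ignored: clustering weights are always
#' recomputed from the raw rows by [cluster_block()].
#'
#' @param file Path to a BLOCKS flat file, or the file's text (a string with
#'   newlines, or a character vector of lines).
#' @return A list of [new_block()] objects, in file order.  An empty file
#'   yields an empty list.
#' @seealso [write_blocks()]
#' @export
read_blocks <- function(file) {
  lines <- .as_lines(file)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  term <- which(trimws(lines) == "//")
  if (length(term) == 0L) stop("no block terminator ('//') found")
  blocks <- vector("list", length(term))
  start <- 1L
  for (b in seq_along(term)) {
    chunk <- lines[start:(term[b] - 1L)]
    start <- term[b] + 1L
    blocks[[b]] <- .parse_block_chunk(chunk, index = b)
  }
  blocks
}

.parse_block_chunk <- function(chunk, index) {
  chunk <- chunk[nzchar(trimws(chunk))]
  id_line <- grep("^ID\\s", chunk, value = TRUE)
  ac_line <- grep("^AC\\s", chunk, value = TRUE)
  de_line <- grep("^DE\\s", chunk, value = TRUE)
  bl_line <- grep("^BL\\s", chunk, value = TRUE)
  block_id <-
    if (length(ac_line)) sub(";.*$", "", sub("^AC\\s+", "", ac_line[1L]))
    else if (length(id_line)) sub(";.*$", "", sub("^ID\\s+", "", id_line[1L]))
    else sprintf("BLOCK%05d", index)
  description <- if (length(de_line)) sub("^DE\\s+", "", de_line[1L]) else ""
  declared_width <- NA_integer_
  if (length(bl_line)) {
    m <- regmatches(bl_line[1L], regexec("width=([0-9]+)", bl_line[1L]))[[1L]]
    if (length(m) == 2L) declared_width <- as.integer(m[2L])
  }
  body <- chunk[!grepl("^(ID|AC|DE|BL)\\s", chunk)]
  rx <- "^\\s*(\\S+)\\s+\\(\\s*([0-9]+)\\s*\\)\\s+([A-Za-z]+)(\\s+\\S+)?\\s*$"
  hits <- regmatches(body, regexec(rx, body))
  ok <- lengths(hits) >= 4L
  if (!all(ok)) {
    stop("malformed block ", block_id, ": unparseable sequence line: ",
         body[!ok][1L])
  }
  ids <- vapply(hits, `[`, "", 2L)
  seqs <- toupper(vapply(hits, `[`, "", 4L))
  if (!is.na(declared_width) && any(nchar(seqs) != declared_width)) {
    stop("malformed block ", block_id, ": row length differs from declared width ",
         declared_width)
  }
  names(seqs) <- ids
  new_block(block_id, seqs, description)
}

#' Write blocks in BLOCKS flat format
#'
#' @param blocks A list of [new_block()] objects.
#' @param file Optional path; if omitted the formatted text is returned.
#' @return The text, invisibly when written to a file.
#' @export
write_blocks <- function(blocks, file = NULL) {
  fmt1 <- function(blk) {
    idw <- max(nchar(names(blk$rows)), 8L)
    c(sprintf("ID   %s; BLOCK", blk$block_id),
      sprintf("AC   %s; distance from previous block=(0,0)", blk$block_id),
      sprintf("DE   %s", blk$description),
      sprintf("BL   adapted; width=%d; seqs=%d", blk$width, length(blk$rows)),
      sprintf(paste0("%-", idw, "s (    1) %s  1.00"), names(blk$rows), blk$rows),
      "//")
  }
  text <- unlist(lapply(blocks, fmt1), use.names = FALSE)
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

#' Read SCOP/ASTRAL-style FASTA
#'
#' Reads a FASTA file whose headers follow the ASTRAL convention: the first
#' token is the domain sid (e.g. `d1dlwa_`) and the second is the SCOP
#' classification string `class.fold.superfamily.family` (e.g. `a.1.1.1`).
#' Trailing header fields are ignored; multi-line sequences are supported.
#'
#' @param file Path to a FASTA file.
#' @return A `data.frame` with one row per domain: `sid`, `sccs`,
#'   `class_id`, `fold_id`, `superfamily_id`, `family_id`, `sequence`
#'   (uppercased).  The hierarchy columns are nested prefixes of `sccs`, so
#'   `fold_id` is always a prefix of `superfamily_id`.
#' @export
read_scop_fasta <- function(file) {
  seqs <- Biostrings::readAAStringSet(file)
  headers <- names(seqs)
  toks <- strsplit(trimws(headers), "\\s+")
  sid <- vapply(toks, `[`, "", 1L)
  sccs <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_, "")
  if (anyNA(sccs)) {
    stop("malformed header (missing sccs field): ", headers[is.na(sccs)][1L])
  }
  parts <- strsplit(sccs, ".", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    bad <- sccs[lengths(parts) != 4L][1L]
    stop("malformed sccs '", bad, "': expected 4 dot-separated components")
  }
  lvl <- function(k) vapply(parts, function(p) paste(p[seq_len(k)], collapse = "."), "")
  data.frame(
    sid = sid,
    sccs = sccs,
    class_id = lvl(1L),
    fold_id = lvl(2L),
    superfamily_id = lvl(3L),
    family_id = lvl(4L),
    sequence = toupper(as.character(seqs)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write domains as SCOP-style FASTA
#'
#' @param domains Data frame as returned by [read_scop_fasta()] or
#'   [generate_benchmark()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scop_fasta <- function(domains, file) {
  x <- Biostrings::AAStringSet(domains$sequence)
  names(x) <- paste(domains$sid, domains$sccs)
  Biostrings::writeXStringSet(x, file, width = 60L)
  invisible(file)
}

#' Write a substitution matrix file
#'
#' Writes the standard '#'-commented square matrix layout used by classic
#' substitution-matrix distributions: comment lines recording provenance
#' (variant, clustering threshold, relative entropy, bit units, source),
#' a header row of residues, then one aligned score row per residue.
#'
#' @param x A finalized [build_matrix()] model, a `matrix_file`, or a bare
#'   symmetric integer matrix with residue dimnames.
#' @param file Optional path; if omitted the text is returned.
#' @param comments Extra comment lines (without the leading `#`).
#' @return The text, invisibly when written to a file.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(x, file = NULL, comments = character()) {
  meta <- character()
  if (inherits(x, "subst_model")) {
    if (is.null(x$scores)) stop("model not finalized: no integer scores")
    meta <- c(
      sprintf("variant: %s", x$provenance$variant %||% "unknown"),
      sprintf("threshold: %s", x$provenance$threshold %||% "NA"),
      sprintf("entropy_bits: %.4f", x$entropy),
      sprintf("bit_units: 1/%d", x$bit_denominator),
      sprintf("source: %s", x$provenance$source %||% "unspecified"))
    if (isTRUE(x$provenance$pseudocount)) meta <- c(meta, "pseudocount: 1")
  } else if (inherits(x, "matrix_file")) {
    meta <- x$comments
  }
  scores <- .score_matrix(x)
  ab <- rownames(scores)
  wid <- max(nchar(as.character(scores)), nchar(ab)) + 1L
  cell <- function(v) formatC(v, width = wid)
  lines <- c(
    paste0("# ", c("blosumkit substitution matrix", meta, comments)),
    paste0("  ", paste(cell(ab), collapse = "")),
    vapply(seq_along(ab), function(i) {
      paste0(formatC(ab[i], width = -2L), paste(cell(scores[i, ]), collapse = ""))
    }, ""))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a substitution matrix file
#'
#' @param file Path to (or text of) a '#'-commented square matrix file.
#' @return An object of class `matrix_file`: list with `alphabet`, `scores`
#'   (symmetric integer matrix with residue dimnames), `comments` (comment
#'   lines without the `#`), and `meta` (named list parsed from
#'   `key: value` comments, with `entropy_bits`, `threshold` and
#'   `bit_denominator` converted to numbers when present).
#' @export
read_matrix <- function(file) {
  lines <- .as_lines(file)
  is_comment <- grepl("^\\s*#", lines)
  comments <- sub("^\\s*#\\s?", "", lines[is_comment])
  body <- trimws(lines[!is_comment])
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("matrix file has no score table")
  alphabet <- strsplit(body[1L], "\\s+")[[1L]]
  n <- length(alphabet)
  if (length(body) - 1L != n) {
    stop("matrix file is not square: ", n, " columns but ",
         length(body) - 1L, " rows")
  }
  scores <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  for (i in seq_len(n)) {
    toks <- strsplit(body[i + 1L], "\\s+")[[1L]]
    if (toks[1L] != alphabet[i]) {
      stop("matrix row order mismatch: expected ", alphabet[i], ", got ", toks[1L])
    }
    vals <- suppressWarnings(as.numeric(toks[-1L]))
    if (length(vals) != n || anyNA(vals)) {
      stop("malformed score row for residue ", alphabet[i])
    }
    scores[i, ] <- as.integer(vals)
  }
  if (!isSymmetric(unname(scores))) stop("matrix file is not symmetric")
  meta <- list()
  kv <- regmatches(comments, regexec("^([A-Za-z_]+):\\s*(.*)$", comments))
  for (m in kv) {
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  if (!is.null(meta$entropy_bits)) meta$entropy_bits <- as.numeric(meta$entropy_bits)
  if (!is.null(meta$threshold)) meta$threshold <- suppressWarnings(as.numeric(meta$threshold))
  if (!is.null(meta$bit_units)) {
    meta$bit_denominator <- as.integer(sub("^1/", "", meta$bit_units))
  }
  structure(list(alphabet = alphabet, scores = scores,
                 comments = comments, meta = meta),
            class = "matrix_file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
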