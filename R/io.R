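#' Read RNA sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file and normalizes the residues to RNA:
#' `T`/`t` become `U`, everything is upper-cased. `N` is tolerated only when
#' `allow_n = TRUE` (scan targets from EST/GSS resources may contain it);
#' precursor sequences must be pure `A`/`C`/`G`/`U`.
#'
#' @param path path to a FASTA file.
#' @param allow_n logical; keep `N` residues instead of erroring.
#' @return named character vector of RNA sequences (5' to 3').
#' @export
read_rna_fasta <- function(path, allow_n = FALSE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs <- vapply(seqs, normalize_rna, character(1), allow_n = allow_n)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_rna_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Normalize a nucleotide string to RNA
#'
#' @param x character scalar.
#' @param allow_n tolerate `N`.
#' @return upper-case RNA string over `ACGU` (plus `N` if allowed).
#' @export
normalize_rna <- function(x, allow_n = FALSE) {
  x <- chartr("acgtun", "ACGUUN", toupper(x))
  x <- chartr("T", "U", x)
  alphabet <- if (allow_n) "ACGUN" else "ACGU"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nzchar(bad)) {
    stop("invalid residue(s) after RNA normalization: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  if (!nzchar(x)) stop("empty sequence")
  x
}

#' Reverse complement of an RNA string
#'
#' `N` complements to `N`.
#'
#' @param x RNA string.
#' @return reverse complement, 5' to 3'.
#' @export
rna_revcomp <- function(x) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Read Vienna-style records (sequence line + dot-bracket line)
#'
#' Each record is a `>` header line, one sequence line, and one dot-bracket
#' structure line of equal length, i.e. the native text output of RNA
#' folding programs.
#'
#' @param path input file.
#' @return named list of `hairpin_structure`-ready pairs:
#'   each element is `list(seq = <RNA string>, structure = <dot-bracket>)`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L || any(diff(heads) != 3L) ||
      length(lines) < heads[length(heads)] + 2L) {
    stop("malformed Vienna file: expected header + sequence + structure triples")
  }
  out <- lapply(heads, function(h) {
    seq <- normalize_rna(lines[h + 1L])
    db <- sub("\\s.*$", "", lines[h + 2L])
    if (nchar(db) != nchar(seq)) stop("structure length != sequence length")
    list(seq = seq, structure = db)
  })
  names(out) <- sub("^>", "", sub("\\s.*$", "", lines[heads]))
  out
}

#' Write Vienna-style records
#'
#' @param records named list with `seq` and `structure` elements.
#' @param path output file.
#' @export
write_vienna <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(c(paste0(">", nm), records[[nm]]$seq, records[[nm]]$structure),
               con)
  }
  invisible(path)
}

#' Read a Stockholm alignment
#'
#' Minimal single-block or interleaved Stockholm reader that keeps the
#' `#=GC SS_cons` consensus-structure line when present. Gap characters
#' `.`, `-` and `~` are normalized to `-` in sequence rows.
#'
#' @param path input file.
#' @return a `structural_alignment` object (see [structural_alignment()]),
#'   with attribute `ss_cons` holding the consensus structure string or
#'   `NULL`.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# STOCKHOLM", lines[1])) stop("not a Stockholm file")
  rows <- list()
  ss <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm row: ", ln)
    rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
  }
  if (length(rows) < 2L) stop("Stockholm alignment needs at least 2 rows")
  mat <- vapply(rows, function(s) {
    toupper(chartr(".~tT", "--UU", s))
  }, character(1))
  aln <- structural_alignment(mat)
  ss_line <- if (length(ss)) paste(ss, collapse = "") else NULL
  attr(aln, "ss_cons") <- ss_line
  aln
}

#' Write a Stockholm alignment with optional SS_cons
#'
#' @param aln a `structural_alignment`.
#' @param path output file.
#' @param ss_cons optional consensus-structure string (WUSS subset
#'   `<>`/`()`/`.`), same length as the alignment.
#' @export
write_stockholm <- function(aln, path, ss_cons = NULL) {
  rows <- as_aln_strings(aln)
  w <- max(nchar(names(rows)), nchar("#=GC SS_cons"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  for (nm in names(rows)) {
    writeLines(sprintf("%-*s %s", w, nm, rows[[nm]]), con)
  }
  if (!is.null(ss_cons)) {
    stopifnot(nchar(ss_cons) == ncol(aln))
    writeLines(sprintf("%-*s %s", w, "#=GC SS_cons", ss_cons), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a collapsed small-RNA/PARE count table
#'
#' Two input dialects are supported: a TSV with columns `sequence` and
#' `count` (header optional), or a collapsed FASTA whose headers end in
#' `_x<COUNT>`.
#'
#' @param path input file.
#' @return data.frame with character `sequence` and numeric `count`,
#'   collapsed to unique sequences.
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^>", first)) {
    seqs <- read_rna_fasta(path)
    counts <- as.numeric(sub("^.*_x", "", names(seqs)))
    if (anyNA(counts)) stop("collapsed FASTA headers must end in _x<COUNT>")
    df <- data.frame(sequence = unname(seqs), count = counts,
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = grepl("seq", first, ignore.case = TRUE),
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("count table needs sequence and count columns")
    names(df)[1:2] <- c("sequence", "count")
    df$sequence <- vapply(df$sequence, normalize_rna, character(1))
    df$count <- as.numeric(df$count)
  }
  df <- stats::aggregate(count ~ sequence, df, sum)
  if (any(df$count <= 0)) stop("counts must be positive")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
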