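#' Read candidate hairpin sequences from FASTA
#'
#' Reads a (multi-record) FASTA file and applies the standard cleaning rule
#' for pre-miRNA datasets: sequences are uppercased, DNA-coded records are
#' converted to RNA (`T` to `U`), and any record still containing characters
#' outside `A`, `U`, `C`, `G` — including IUPAC ambiguity codes such as `N`
#' — is removed (or, with `policy = "error"`, aborts the read).
#'
#' @param path FASTA file path.
#' @param policy `"drop_invalid"` (default) removes offending records and
#'   reports the count via a message; `"error"` stops on the first one.
#' @param dedupe drop later records whose residues exactly duplicate an
#'   earlier record's (off by default: curated collections legitimately
#'   contain identical hairpins from related species).
#' @return An [Biostrings::RNAStringSet] in file order; the number of
#'   dropped records is attached as `attr(, "dropped")`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ACGN"), f)
#' readHairpinFasta(f)          # 'a' becomes ACGU, 'b' is dropped
#' @export
readHairpinFasta <- function(path, policy = c("drop_invalid", "error"),
                             dedupe = FALSE) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw)))) {
    return(Biostrings::RNAStringSet())
  }
  body <- raw[nzchar(trimws(raw))]
  if (!startsWith(body[1], ">")) {
    stop("malformed FASTA: record body before first header")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e)))
  chars <- toupper(as.character(set))
  chars <- chartr("T", "U", chars)
  ok <- grepl("^[ACGU]+$", chars)
  if (any(!ok)) {
    if (policy == "error") {
      stop("non-AUCG characters in record(s): ",
           paste(head(names(set)[!ok], 5), collapse = ", "))
    }
    message(sum(!ok), " record(s) dropped for non-AUCG characters")
  }
  keep <- chars[ok]
  nms <- names(set)[ok]
  if (dedupe && anyDuplicated(keep)) {
    dup <- duplicated(keep)
    message(sum(dup), " exact duplicate record(s) dropped")
    keep <- keep[!dup]
    nms <- nms[!dup]
  }
  out <- Biostrings::RNAStringSet(keep)
  names(out) <- nms
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Write sequences to FASTA
#'
#' Standard 60-column-wrapped FASTA; a round trip through
#' [readHairpinFasta()] is the identity on valid records.
#'
#' @param records an [Biostrings::RNAStringSet] (or named character vector).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeHairpinFasta <- function(records, path) {
  if (is.character(records)) {
    records <- Biostrings::RNAStringSet(asRnaCharacter(records))
  }
  Biostrings::writeXStringSet(records, path, width = 60L)
  invisible(path)
}

#' Read Vienna dot-bracket files
#'
#' Parses the three-line-per-record interchange format written by
#' thermodynamic folding tools: a `>` header, the sequence, then the
#' dot-bracket structure optionally followed by the minimum free energy in
#' parentheses (kcal/mol). Structures are returned with
#' `structureSource() == "provided"` so they can be featurized bit-for-bit
#' without refolding.
#'
#' @param path file path.
#' @return A list with parallel elements `sequences`
#'   ([Biostrings::RNAStringSet]) and `structures` (list of
#'   [SecondaryStructure-class]; `mfe` is `NA` when absent in the file).
#' @export
readVienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  seqs <- character(0)
  ids <- character(0)
  structs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) {
      stop("malformed dot-bracket file: expected header at line ", i)
    }
    if (i + 2L > length(lines)) stop("truncated record at end of file")
    id <- sub("^>\\s*", "", lines[i])
    sq <- chartr("Tt", "Uu", toupper(trimws(lines[i + 1L])))
    m <- regmatches(lines[i + 2L],
                    regexec("^([().]+)(\\s*\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$",
                            trimws(lines[i + 2L])))[[1]]
    if (length(m) == 0) stop("malformed structure line for record ", id)
    db <- m[2]
    energy <- if (nzchar(m[4])) as.numeric(m[4]) else NA_real_
    if (nchar(db) != nchar(sq)) {
      stop("structure/sequence length mismatch for record ", id)
    }
    bp <- parseDotBracket(db)
    structs[[length(structs) + 1L]] <- methods::new("SecondaryStructure",
      dotbracket = db, basePairs = bp,
      mfe = if (is.na(energy)) NA_real_ else energy, source = "provided")
    seqs <- c(seqs, sq)
    ids <- c(ids, id)
    i <- i + 3L
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  names(structs) <- ids
  list(sequences = out, structures = structs)
}

#' Write sequences plus structures in Vienna dot-bracket format
#'
#' @param seqs [Biostrings::RNAStringSet] or named character vector.
#' @param structures list of [SecondaryStructure-class], parallel to `seqs`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeVienna <- function(seqs, structures, path) {
  ch <- asRnaCharacter(seqs)
  stopifnot(length(ch) == length(structures))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ch)) {
    ss <- structures[[i]]
    energy <- if (is.na(mfe(ss))) "" else sprintf(" (%.2f)", mfe(ss))
    writeLines(c(paste0(">", names(ch)[i]), ch[[i]],
                 paste0(dotbracket(ss), energy)), con)
  }
  invisible(path)
}
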