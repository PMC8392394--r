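#' Parse and render dot-bracket notation
#'
#' `parseDotBracket` stack-matches a dot-bracket string into a 1-based
#' base-pair matrix; `renderDotBracket` is its inverse.
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @param pairs integer matrix with columns `i`, `j`.
#' @param L sequence length for rendering.
#' @return `parseDotBracket`: integer matrix of pairs sorted by `(i, j)`;
#'   `renderDotBracket`: a dot-bracket string of length `L`.
#' @examples
#' parseDotBracket("((..))")   # pairs (1,6) and (2,5)
#' renderDotBracket(rbind(c(1, 6), c(2, 5)), 6)
#' @export
parseDotBracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("dot-bracket may contain only '(', ')' and '.'")
  }
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos)
    } else if (chars[pos] == ")") {
      if (!length(stack)) stop("unbalanced brackets: unmatched ')'")
      pi <- c(pi, stack[length(stack)])
      pj <- c(pj, pos)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced brackets: unmatched '('")
  m <- cbind(i = pi, j = pj)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname parseDotBracket
#' @export
renderDotBracket <- function(pairs, L) {
  chars <- rep(".", L)
  if (nrow(pairs)) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

viennaAvailable <- function() nzchar(Sys.which("RNAfold"))

# one RNAfold process for a whole batch; returns list of (db, mfe)
foldWithVienna <- function(chars) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(rbind(paste0(">", seq_along(chars)), unlist(chars)), fa)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE))
  # records: >id / seq / structure ( energy )
  hits <- grep("^>", out)
  if (length(hits) != length(chars)) stop("RNAfold output parse failure")
  lapply(seq_along(hits), function(r) {
    sline <- trimws(out[hits[r] + 2L])
    m <- regmatches(sline,
                    regexec("^([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)$",
                            sline))[[1]]
    if (length(m) == 0) stop("RNAfold output parse failure: ", sline)
    list(db = m[2], mfe = as.numeric(m[3]))
  })
}

foldWithFallback <- function(chars) {
  lapply(chars, function(s) {
    res <- .nussinov_fold(seqToCodes(s), 3L)
    pairs <- res$pairs
    list(db = renderDotBracket(pairs, nchar(s)), mfe = -res$score,
         pairs = pairs)
  })
}

resolveEngine <- function(engine) {
  if (is.function(engine)) return(engine)
  engine <- match.arg(engine, c("auto", "fallback", "vienna"))
  if (engine == "auto") {
    if (viennaAvailable()) {
      engine <- "vienna"
    } else {
      warning("thermodynamic engine unavailable; using fallback folder")
      engine <- "fallback"
    }
  }
  if (engine == "vienna" && !viennaAvailable()) {
    warning("RNAfold not found on PATH; using fallback folder")
    engine <- "fallback"
  }
  engine
}

#' Fold sequences into minimum-(pseudo-)energy secondary structures
#'
#' `foldHairpin` folds a single sequence; `foldHairpins` folds a set,
#' batching external-engine calls. Two engines are built in:
#' `"vienna"` shells out to `RNAfold` (thermodynamic MFE, kcal/mol) and
#' `"fallback"` is a self-contained Nussinov-style base-pair-maximization
#' dynamic program with pair weights GC = 3, AU = 2, GU = 1, minimum
#' hairpin loop of 3 nt, reporting the negated pair-weight score as a
#' pseudo-energy. `"auto"` prefers the thermodynamic engine and falls back
#' with a warning. Among co-optimal fallback structures the one whose pair
#' set is lexicographically smallest by `(i, j)` is returned, making the
#' fallback fully deterministic. An `engine` may also be a function taking
#' a sequence string and returning `list(db =, mfe =)`.
#'
#' @param seq,seqs a sequence (character/RNAString) or a set
#'   ([Biostrings::RNAStringSet] / named character vector); minimum length
#'   10 nt.
#' @param engine `"auto"`, `"fallback"`, `"vienna"`, or a function.
#' @return A [SecondaryStructure-class] (or a named list of them).
#' @examples
#' foldHairpin("GGGGAAAACCCC", engine = "fallback")
#' @export
foldHairpin <- function(seq, engine = "auto") {
  foldHairpins(stats::setNames(as.character(seq), "x"), engine)[[1]]
}

#' @rdname foldHairpin
#' @export
foldHairpins <- function(seqs, engine = "auto") {
  chars <- asRnaCharacter(seqs)
  short <- nchar(chars) < 10L
  if (any(short)) {
    stop("sequence(s) shorter than 10 nt cannot form a hairpin: ",
         paste(head(names(chars)[short], 5), collapse = ", "))
  }
  engine <- resolveEngine(engine)
  if (is.function(engine)) {
    raw <- lapply(chars, function(s) engine(s))
    src <- "engine"
  } else if (engine == "vienna") {
    raw <- foldWithVienna(chars)
    src <- "engine"
  } else {
    raw <- foldWithFallback(chars)
    src <- "fallback"
  }
  out <- lapply(raw, function(r) {
    bp <- if (!is.null(r$pairs)) {
      p <- r$pairs
      if (nrow(p)) p[order(p[, 1], p[, 2]), , drop = FALSE] else p
    } else {
      parseDotBracket(r$db)
    }
    methods::new("SecondaryStructure", dotbracket = r$db,
                 basePairs = bp, mfe = r$mfe, source = src)
  })
  names(out) <- names(chars)
  out
}
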