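## Hexamer-based exonic splicing enhancer/silencer scoring (DeltaHx).
##
## A hexamer table maps each of the 4096 DNA 6-mers to a score; the total
## score of a sequence is the sum over all overlapping 6-mer windows, and
## DeltaHx is the mutant total minus the wild-type total. The published
## hexamer tables are optional user-supplied files; packaged toy tables keep
## the pipeline self-sufficient.

#' Construct a hexamer score table
#'
#' @param scores named numeric vector keyed by 6-mers over ACGT. Missing
#'   hexamers default to 0 (with a warning when the table is non-empty but
#'   incomplete).
#' @param name table name.
#' @param provenance free-text provenance note.
#' @return object of class `pe_hexamer_table`.
#' @export
hexamer_table <- function(scores, name = "user", provenance = "user") {
  keys <- names(scores)
  if (is.null(keys) || any(!grepl("^[ACGT]{6}$", keys))) {
    stop("hexamer scores must be named by 6-mers over ACGT", call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("duplicated hexamer keys", call. = FALSE)
  if (length(scores) > 0L && length(scores) < 4096L) {
    warning("hexamer table specifies ", length(scores),
            " of 4096 hexamers; the rest score 0", call. = FALSE)
  }
  structure(list(scores = scores, name = name, provenance = provenance),
            class = "pe_hexamer_table")
}

#' @export
print.pe_hexamer_table <- function(x, ...) {
  cat(sprintf("<pe_hexamer_table> %s (%d hexamers)\n", x$name,
              length(x$scores)))
  invisible(x)
}

#' Read a hexamer table from a two-column file
#'
#' Tab-separated `HEXAMER<TAB>score`, one per line; `#` comments ignored.
#'
#' @param path table file.
#' @param name table name (defaults to the file name).
#' @return a `pe_hexamer_table`.
#' @export
read_hexamer_table <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("hexamer", "score"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  hexamer_table(stats::setNames(tab$score, toupper(tab$hexamer)),
                name = name, provenance = path)
}

#' Packaged toy hexamer tables
#'
#' `toy_hexamer_table()` scores each hexamer 0.1 x (count of A - count of T),
#' so adenine-gaining changes read as enhancer gains; `zero_hexamer_table()`
#' scores everything 0 (the classifier null). Both cover all 4096 hexamers.
#'
#' @return a `pe_hexamer_table`.
#' @export
toy_hexamer_table <- function() {
  kmers <- all_hexamers()
  a <- vapply(gregexpr("A", kmers, fixed = TRUE),
              function(x) sum(x > 0L), 0L)
  t <- vapply(gregexpr("T", kmers, fixed = TRUE),
              function(x) sum(x > 0L), 0L)
  hexamer_table(stats::setNames(0.1 * (a - t), kmers), name = "toy-AT",
                provenance = "packaged toy table")
}

#' @rdname toy_hexamer_table
#' @export
zero_hexamer_table <- function() {
  hexamer_table(stats::setNames(rep(0, 4096L), all_hexamers()),
                name = "zero", provenance = "packaged null")
}

all_hexamers <- function() {
  do.call(paste0, expand.grid(rep(list(DNA_BASES), 6L),
                              stringsAsFactors = FALSE)[, 6:1])
}

#' Total hexamer score of a sequence
#'
#' Sum of table scores over all overlapping 6-mers; sequences shorter than
#' 6 nt score 0.
#'
#' @param seq DNA string.
#' @param table a `pe_hexamer_table`.
#' @return numeric total.
#' @export
total_hexamer_score <- function(seq, table) {
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 6L) return(0)
  kmers <- substring(seq, 1:(n - 5L), 6:n)
  vals <- table$scores[kmers]
  vals[is.na(vals)] <- 0
  sum(vals)
}

#' DeltaHx: hexamer score change caused by a mutation
#'
#' The definition of record is whole-sequence subtraction: mutant total minus
#' wild-type total. For SNVs a windowed computation restricted to the <= 6
#' hexamers overlapping the changed base is also performed and asserted equal
#' to the full subtraction.
#'
#' @param wt_seq wild-type sequence (transcript strand).
#' @param mutation list with `at` (1-based position within `wt_seq`), `kind`,
#'   `ref`, `alt` and (for deletions) `size`; alleles in transcript
#'   orientation.
#' @param table a `pe_hexamer_table`.
#' @param tol directionality tolerance (default 0).
#' @return object of class `pe_delta_hx` with `wt_total`, `mut_total`,
#'   `delta` and `direction` (`gain`/`loss`/`neutral`).
#' @export
delta_hx <- function(wt_seq, mutation, table, tol = 0) {
  assert_dna(wt_seq)
  at <- as.integer(mutation$at)
  kind <- mutation$kind %||% "SNV"
  n <- nchar(wt_seq)
  if (is.na(at) || at < 1L || at > n) {
    stop("mutation position lies outside the sequence", call. = FALSE)
  }
  mut_seq <- if (kind == "SNV") {
    if (substr(wt_seq, at, at) != mutation$ref) {
      stop("reference allele mismatch at position ", at, call. = FALSE)
    }
    s <- wt_seq
    substr(s, at, at) <- mutation$alt
    s
  } else if (kind == "deletion") {
    size <- as.integer(mutation$size %||% nchar(mutation$ref %||% ""))
    if (at + size - 1L > n) stop("deletion runs off the sequence", call. = FALSE)
    paste0(substr(wt_seq, 1L, at - 1L), substr(wt_seq, at + size, n))
  } else if (kind == "insertion") {
    paste0(substr(wt_seq, 1L, at - 1L), mutation$alt, substr(wt_seq, at, n))
  } else if (kind == "delins") {
    size <- as.integer(mutation$size)
    paste0(substr(wt_seq, 1L, at - 1L), mutation$alt,
           substr(wt_seq, at + size, n))
  } else {
    stop("DeltaHx is undefined for mutations of kind '", kind, "'",
         call. = FALSE)
  }
  wt_total <- total_hexamer_score(wt_seq, table)
  mut_total <- total_hexamer_score(mut_seq, table)
  delta <- mut_total - wt_total
  if (kind == "SNV") {
    ## windowed recomputation over the <= 6 affected hexamers must agree
    lo <- max(1L, at - 5L)
    hi <- min(n, at + 5L)
    delta_win <- total_hexamer_score(substr(mut_seq, lo, hi), table) -
      total_hexamer_score(substr(wt_seq, lo, hi), table)
    stopifnot(isTRUE(all.equal(delta, delta_win)))
  }
  structure(
    list(wt_total = wt_total, mut_total = mut_total, delta = delta,
         direction = predict_directionality_value(delta, tol)),
    class = "pe_delta_hx"
  )
}

#' @export
print.pe_delta_hx <- function(x, ...) {
  cat(sprintf("<pe_delta_hx> %.3f -> %.3f (delta %+.3f, %s)\n",
              x$wt_total, x$mut_total, x$delta, x$direction))
  invisible(x)
}

predict_directionality_value <- function(delta, tol = 0) {
  if (tol < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (delta > tol) "gain" else if (delta < -tol) "loss" else "neutral"
}

#' Directionality of a DeltaHx result
#'
#' @param d a `pe_delta_hx` (or a bare delta value).
#' @param tol symmetric neutrality band around 0 (default 0: sign only).
#' @return `"gain"`, `"loss"` or `"neutral"`.
#' @export
predict_directionality <- function(d, tol = 0) {
  delta <- if (inherits(d, "pe_delta_hx")) d$delta else as.numeric(d)
  predict_directionality_value(delta, tol)
}

#' Scan a sequence for IUPAC motifs
#'
#' Reports every exact IUPAC match (overlaps allowed) with 0-based offsets.
#'
#' @param seq DNA string.
#' @param motifs character vector of IUPAC patterns.
#' @return data.frame with `motif` and `offset` (0-based).
#' @export
scan_motifs <- function(seq, motifs) {
  assert_dna(seq)
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  out <- lapply(motifs, function(m) {
    chars <- seq_chars(toupper(m))
    if (any(!chars %in% valid)) {
      stop("invalid IUPAC code in motif '", m, "'", call. = FALSE)
    }
    if (nchar(seq) < nchar(m)) {
      return(data.frame(motif = character(0), offset = integer(0)))
    }
    hits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(m)),
                                     Biostrings::DNAString(seq),
                                     fixed = FALSE)
    data.frame(motif = rep(m, length(hits)),
               offset = Biostrings::start(hits) - 1L)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
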