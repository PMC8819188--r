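## HGVS-style cDNA variant parsing. Only the variant forms occurring in
## published pseudoexon catalogues are supported: SNVs, deletions (range or
## legacy size-suffixed), insertions, deletion-insertions, duplications and
## inversions, with intronic +/- offsets on either bound. Protein-level and
## repeat syntax are out of scope.

#' Construct a cDNA position
#'
#' @param anchor coding-sequence position (1-based; negative for 5'UTR
#'   positions such as `c.-32`).
#' @param offset signed intronic offset (0 = exonic; `+n` lies n nt 3' of the
#'   anchor exon's donor site, `-n` lies n nt 5' of its acceptor site).
#' @return object of class `pe_cdna_position`.
#' @export
cdna_position <- function(anchor, offset = 0L) {
  anchor <- as.integer(anchor)
  offset <- as.integer(offset)
  if (is.na(anchor) || anchor == 0L) {
    stop("cDNA anchor must be a non-zero integer", call. = FALSE)
  }
  structure(list(anchor = anchor, offset = offset),
            class = "pe_cdna_position")
}

format_cdna_position <- function(pos) {
  off <- if (pos$offset > 0L) {
    paste0("+", pos$offset)
  } else if (pos$offset < 0L) {
    as.character(pos$offset)
  } else {
    ""
  }
  paste0(pos$anchor, off)
}

#' @export
print.pe_cdna_position <- function(x, ...) {
  cat("<pe_cdna_position> c.", format_cdna_position(x), "\n", sep = "")
  invisible(x)
}

.parse_cdna_pos <- function(tok, original) {
  m <- regexec("^(-?\\d+)(([+-])(\\d+))?$", tok)[[1L]]
  if (m[1L] == -1L) {
    stop("unparseable cDNA position '", tok, "' in '", original, "'",
         call. = FALSE)
  }
  parts <- regmatches(tok, list(regexec("^(-?\\d+)(([+-])(\\d+))?$", tok)[[1L]]))[[1L]]
  anchor <- as.integer(parts[2L])
  offset <- 0L
  if (nzchar(parts[3L])) {
    offset <- as.integer(parts[5L])
    if (parts[4L] == "-") offset <- -offset
  }
  cdna_position(anchor, offset)
}

## advance a cDNA position n steps along the transcript axis. Only valid when
## the walk stays on one side of one exon boundary (true for the legacy
## `del<N>` forms this is used to normalise).
.advance_cdna_pos <- function(pos, n) {
  if (pos$offset != 0L) {
    cdna_position(pos$anchor, pos$offset + n)
  } else {
    anchor <- pos$anchor + n
    if (pos$anchor < 0L && anchor >= 0L) anchor <- anchor + 1L
    cdna_position(anchor, 0L)
  }
}

#' Parse an HGVS-style cDNA variant string
#'
#' Accepts SNVs (`c.3994-159A>G`), range and legacy size-suffixed deletions
#' (`c.2113+461_2113+473del`, `c.163+696del55`), insertions (`c.100+5insTTA`),
#' deletion-insertions, duplications and inversions. Both ASCII hyphen and
#' Unicode minus are accepted in offsets; whitespace is ignored. Legacy
#' `del<N>` deletions are normalised to range form.
#'
#' @param s variant string beginning with `"c."`.
#' @return an object of class `pe_cdna_variant` with fields `hgvs`
#'   (normalised string), `start`, `end` ([cdna_position()]s; `end` may be
#'   `NULL`), `kind` (`SNV`, `deletion`, `insertion`, `delins`, `inversion`),
#'   `ref`, `alt` (transcript-strand alleles, `""` where inapplicable),
#'   `size` (nt; `NA` when it can only be determined by genomic mapping) and
#'   `is_duplication`.
#' @export
parse_cdna_variant <- function(s) {
  original <- s
  s <- gsub("−", "-", s)
  s <- gsub("[[:space:]]", "", s)
  if (!startsWith(s, "c.")) {
    stop("variant must begin with 'c.': '", original, "'", call. = FALSE)
  }
  body <- substring(s, 3L)
  m <- regmatches(body, regexec(
    "^(-?\\d+(?:[+-]\\d+)?)(?:_(-?\\d+(?:[+-]\\d+)?))?([A-Za-z>0-9]+)$", body
  ))[[1L]]
  if (length(m) == 0L) {
    stop("unparseable cDNA variant '", original, "'", call. = FALSE)
  }
  start <- .parse_cdna_pos(m[2L], original)
  end <- if (nzchar(m[3L])) .parse_cdna_pos(m[3L], original) else NULL
  change <- m[4L]

  same_axis_span <- function(start, end) {
    ## span length when both bounds are comparable without genomic mapping
    if (is.null(end)) return(1L)
    if (start$offset != 0L && end$offset != 0L &&
        start$anchor == end$anchor &&
        sign(start$offset) == sign(end$offset)) {
      return(abs(end$offset - start$offset) + 1L)
    }
    if (start$offset == 0L && end$offset == 0L &&
        sign(start$anchor) == sign(end$anchor)) {
      return(end$anchor - start$anchor + 1L)
    }
    NA_integer_
  }

  kind <- NULL; ref <- ""; alt <- ""; size <- NA_integer_; is_dup <- FALSE
  if (grepl("^[ACGT]>[ACGT]$", change)) {
    if (!is.null(end)) {
      stop("SNV cannot carry a position range: '", original, "'",
           call. = FALSE)
    }
    ref <- substr(change, 1L, 1L)
    alt <- substr(change, 3L, 3L)
    if (ref == alt) {
      stop("SNV reference and alternate alleles are identical: '", original,
           "'", call. = FALSE)
    }
    kind <- "SNV"; size <- 1L
  } else if (grepl("^del(\\d+)?([ACGT]+)?$", change)) {
    kind <- "deletion"
    n <- regmatches(change, regexec("^del(\\d+)?([ACGT]+)?$", change))[[1L]]
    if (nzchar(n[2L])) {
      if (!is.null(end)) {
        stop("size-suffixed deletion cannot also carry a range: '", original,
             "'", call. = FALSE)
      }
      size <- as.integer(n[2L])
      end <- .advance_cdna_pos(start, size - 1L)
    } else if (nzchar(n[3L])) {
      ref <- n[3L]
      size <- nchar(n[3L])
      if (is.null(end) && size > 1L) end <- .advance_cdna_pos(start, size - 1L)
    } else if (is.null(end)) {
      size <- 1L
    } else {
      size <- same_axis_span(start, end)
    }
  } else if (grepl("^delins[ACGT]+$", change)) {
    kind <- "delins"
    alt <- sub("^delins", "", change)
    size <- same_axis_span(start, end)
  } else if (grepl("^ins[ACGT]+$", change)) {
    kind <- "insertion"
    alt <- sub("^ins", "", change)
    size <- nchar(alt)
  } else if (change == "dup") {
    kind <- "insertion"; is_dup <- TRUE
    size <- same_axis_span(start, end)
  } else if (change == "inv") {
    kind <- "inversion"
    size <- same_axis_span(start, end)
  } else {
    stop("unsupported cDNA change '", change, "' in '", original, "'",
         call. = FALSE)
  }

  out <- structure(
    list(hgvs = NA_character_, start = start, end = end, kind = kind,
         ref = ref, alt = alt, size = size, is_duplication = is_dup),
    class = "pe_cdna_variant"
  )
  out$hgvs <- format_cdna_variant(out)
  out
}

#' Format a parsed cDNA variant back to HGVS-style text
#'
#' The formatter emits the normalised form: legacy `del<N>` deletions appear
#' as explicit ranges. [parse_cdna_variant()] of the output yields an equal
#' descriptor.
#'
#' @param v a `pe_cdna_variant`.
#' @return character scalar.
#' @export
format_cdna_variant <- function(v) {
  pos <- format_cdna_position(v$start)
  if (!is.null(v$end)) {
    pos <- paste0(pos, "_", format_cdna_position(v$end))
  }
  change <- switch(v$kind,
    SNV = paste0(v$ref, ">", v$alt),
    deletion = paste0("del", v$ref),
    delins = paste0("delins", v$alt),
    insertion = if (isTRUE(v$is_duplication)) "dup" else paste0("ins", v$alt),
    inversion = "inv",
    stop("cannot format variant of kind '", v$kind, "'", call. = FALSE)
  )
  paste0("c.", pos, change)
}

#' @export
print.pe_cdna_variant <- function(x, ...) {
  cat("<pe_cdna_variant> ", x$hgvs, " (", x$kind, ")\n", sep = "")
  invisible(x)
}
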