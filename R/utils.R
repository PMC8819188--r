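## Low-level sequence and coordinate helpers. All genomic coordinates in this
## package are 0-based, half-open, on the reference (+) strand; sequences are
## plain uppercase character strings keyed by chromosome name.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (ACGT, IUPAC codes tolerated).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## substring by 0-based half-open interval
seq_sub <- function(seq, start0, end0) {
  stopifnot(start0 >= 0, end0 >= start0)
  substr(seq, start0 + 1L, end0)
}

assert_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single non-missing string", call. = FALSE)
  }
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq)) {
    stop(what, " contains non-ACGT characters", call. = FALSE)
  }
  invisible(seq)
}

## split a DNA string into single characters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

is_purine <- function(base) base %in% c("A", "G")
is_pyrimidine <- function(base) base %in% c("C", "T")

## transition: purine<->purine or pyrimidine<->pyrimidine
is_transition <- function(ref, alt) {
  (is_purine(ref) & is_purine(alt)) | (is_pyrimidine(ref) & is_pyrimidine(alt))
}

#' Apply mutations to a reference sequence
#'
#' Applies one or more mutations to a chromosome-scale string and returns the
#' mutant sequence together with a coordinate-shift function mapping reference
#' positions to mutant positions (positions deleted by a mutation map to NA).
#'
#' @param seq reference sequence (plain string, + strand).
#' @param mutations a single mutation or list of mutations, each with fields
#'   `genomic_start`, `genomic_end` (0-based half-open) and `alt_allele`
#'   (reference-strand replacement; "" for pure deletions).
#' @param seq_offset genomic position of the first base of `seq` (default 0).
#' @return list with `seq` (mutant string) and `shift` (vectorised function
#'   from reference genomic positions to mutant genomic positions).
#' @export
mutate_sequence <- function(seq, mutations, seq_offset = 0L) {
  if (!is.null(mutations$genomic_start)) mutations <- list(mutations)
  starts <- vapply(mutations, function(m) as.integer(m$genomic_start), 1L)
  ends <- vapply(mutations, function(m) as.integer(m$genomic_end), 1L)
  alts <- vapply(mutations, function(m) as.character(m$alt_allele %||% ""), "")
  ord <- order(starts, decreasing = TRUE)
  out <- seq
  for (i in ord) {
    s <- starts[i] - seq_offset
    e <- ends[i] - seq_offset
    stopifnot(s >= 0, s <= e, e <= nchar(out))
    out <- paste0(substr(out, 1L, s), alts[i], substr(out, e + 1L, nchar(out)))
  }
  ord_fwd <- order(starts)
  s_f <- starts[ord_fwd]
  e_f <- ends[ord_fwd]
  len_f <- nchar(alts)[ord_fwd]
  delta_f <- len_f - (e_f - s_f)
  shift <- function(pos) {
    vapply(pos, function(p) {
      d <- 0L
      for (j in seq_along(s_f)) {
        if (p >= e_f[j]) {
          d <- d + delta_f[j]
        } else if (p >= s_f[j]) {
          ## equal-length replacements (SNVs, balanced delins) keep their
          ## positions; length-changing footprints erase them
          if (delta_f[j] != 0L) return(NA_integer_)
        }
      }
      as.integer(p + d)
    }, 1L)
  }
  list(seq = out, shift = shift)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random DNA with given GC content; if forbid_ag, never emits an AG dinucleotide
random_dna <- function(n, gc = 0.42, forbid_ag = FALSE) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (n <= 0L) return("")
  if (!forbid_ag) {
    return(paste(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]),
                 collapse = ""))
  }
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    if (prev == "A") {
      q <- p[c("A", "C", "T")]
      out[i] <- sample(c("A", "C", "T"), 1L, prob = q / sum(q))
    } else {
      out[i] <- sample(DNA_BASES, 1L, prob = p[DNA_BASES])
    }
    prev <- out[i]
  }
  paste(out, collapse = "")
}
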