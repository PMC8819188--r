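## AG-exclusion zone and branch-point analysis.
##
## Branch-point definition needs a functional branch adenosine motif and a
## continuous AG-free stretch (the AG-exclusion zone, AGEZ) connecting it to
## the downstream acceptor. Activating mutations tend to "close the circuit"
## between acceptor and branch point: they enlarge the AGEZ, improve an
## in-range branch motif, or move a branch point closer to the acceptor.

#' Compute the AG-exclusion zone upstream of an acceptor
#'
#' The AGEZ length counts nucleotides strictly between the 3'-most upstream
#' AG dinucleotide and the acceptor AG (neither dinucleotide included). If no
#' AG occurs within `scan_limit` nt, the zone is reported as the scanned span
#' with `upstream_ag = NA`.
#'
#' @param upstream_seq sense-strand sequence immediately 5' of the acceptor
#'   AG (the AG itself excluded), 3' end last.
#' @param scan_limit maximum number of nucleotides scanned back from the
#'   acceptor (default 500).
#' @return object of class `pe_agez` with fields `length`, `upstream_ag`
#'   (1-based index of the bounding AG's A within `upstream_seq`, or `NA`)
#'   and `scan_limit`.
#' @export
compute_agez <- function(upstream_seq, scan_limit = 500L) {
  assert_dna(upstream_seq, "upstream sequence")
  n <- nchar(upstream_seq)
  span <- min(n, scan_limit)
  region <- substr(upstream_seq, n - span + 1L, n)
  ## 3'-most AG within the scanned region
  hits <- gregexpr("(?=AG)", region, perl = TRUE)[[1L]]
  agez <- structure(list(length = span, upstream_ag = NA_integer_,
                         scan_limit = as.integer(scan_limit)),
                    class = "pe_agez")
  if (hits[1L] != -1L) {
    last <- max(hits)                      # index of A within region
    agez$length <- span - (last + 1L)      # bases strictly 3' of the AG
    agez$upstream_ag <- (n - span) + last  # 1-based index within upstream_seq
  }
  agez
}

#' @export
print.pe_agez <- function(x, ...) {
  cat(sprintf("<pe_agez> length %d nt (bounding AG %s, scan limit %d)\n",
              x$length,
              if (is.na(x$upstream_ag)) "none within scan" else
                paste0("at ", x$upstream_ag),
              x$scan_limit))
  invisible(x)
}

#' Scan an AGEZ for branch-point candidates
#'
#' One candidate per adenosine within `max_distance` nt of the acceptor,
#' scored with a pluggable branch model over a 7-mer window whose branch A
#' sits at position 6 of 7. The distance of an adenosine is counted so that
#' the 3'-most base of `agez_seq` (the base abutting the acceptor AG) has
#' distance 1.
#'
#' @param agez_seq the AGEZ sequence (3' end abutting the acceptor AG);
#'   optional extra padding 5' of the zone is allowed and used only to fill
#'   windows.
#' @param model a branch `pe_motif_model`.
#' @param max_distance search depth from the acceptor (default 100 nt).
#' @return data.frame of candidates (`position` 1-based within `agez_seq`,
#'   `distance_to_acceptor`, `window_seq`, `score`), sorted by score
#'   (descending) then distance (ascending).
#' @export
scan_branchpoints <- function(agez_seq, model, max_distance = 100L) {
  assert_dna(agez_seq, "AGEZ sequence")
  if (model$kind != "branch") stop("not a branch model", call. = FALSE)
  n <- nchar(agez_seq)
  empty <- data.frame(position = integer(0), distance_to_acceptor = integer(0),
                      window_seq = character(0), score = numeric(0))
  if (n == 0L) return(empty)
  chars <- seq_chars(agez_seq)
  a_pos <- which(chars == "A")
  a_pos <- a_pos[(n - a_pos + 1L) <= max_distance]
  ## a full window needs 5 nt 5' of the branch A and 1 nt 3'
  a_pos <- a_pos[a_pos >= 6L & a_pos <= n - 1L]
  if (length(a_pos) == 0L) return(empty)
  windows <- substring(agez_seq, a_pos - 5L, a_pos + 1L)
  scores <- vapply(windows, function(w) score_motif(model, w), 0,
                   USE.NAMES = FALSE)
  out <- data.frame(position = a_pos,
                    distance_to_acceptor = n - a_pos + 1L,
                    window_seq = windows, score = scores)
  out[order(-out$score, out$distance_to_acceptor), , drop = FALSE]
}

#' Before/after branch-point comparison for a mutation
#'
#' @param wt,mut lists with fields `agez` (a `pe_agez` or plain length),
#'   `bps` (best branch-point score) and `distance` (nt from the best branch
#'   A to the acceptor; `NA` when no candidate). Printed table values can be
#'   supplied directly.
#' @param mutation the [instigating_mutation()] (or list of them) under
#'   evaluation; used for the pyrimidine-gain flag.
#' @return object of class `pe_branchpoint_delta` with the AGEZ and score
#'   befores/afters and the flags `agez_increased`, `bps_increased`,
#'   `moved_closer` (distance decreased with the score not worsened) and
#'   `pyrimidine_gain` (any SNV whose alternate allele is C or T on the
#'   transcript strand).
#' @export
branchpoint_delta <- function(wt, mut, mutation = NULL) {
  get_len <- function(x) if (inherits(x$agez, "pe_agez")) x$agez$length else
    as.numeric(x$agez)
  agez_before <- get_len(wt)
  agez_after <- get_len(mut)
  bps_before <- as.numeric(wt$bps)
  bps_after <- as.numeric(mut$bps)
  d_before <- wt$distance %||% NA_integer_
  d_after <- mut$distance %||% NA_integer_
  moved_closer <- !is.na(d_before) && !is.na(d_after) &&
    d_after < d_before && bps_after >= bps_before
  pyr <- FALSE
  if (!is.null(mutation)) {
    muts <- if (inherits(mutation, "pe_mutation")) list(mutation) else mutation
    pyr <- any(vapply(muts, function(m) {
      m$kind == "SNV" && transcript_alt(m) %in% c("C", "T")
    }, TRUE))
  }
  structure(
    list(agez_before = agez_before, agez_after = agez_after,
         bps_before = bps_before, bps_after = bps_after,
         distance_before = d_before, distance_after = d_after,
         agez_increased = isTRUE(agez_after > agez_before),
         bps_increased = isTRUE(bps_after > bps_before),
         moved_closer = isTRUE(moved_closer),
         pyrimidine_gain = isTRUE(pyr)),
    class = "pe_branchpoint_delta"
  )
}

## alternate allele on the transcript strand; mutations constructed from HGVS
## store reference-strand alleles, so flip for minus-strand genes when the
## strand is recorded on the mutation
transcript_alt <- function(m) {
  alt <- m$alt_allele
  if (isTRUE(m$strand == "-")) alt <- revcomp(alt)
  alt
}

#' @export
print.pe_branchpoint_delta <- function(x, ...) {
  cat(sprintf(
    "<pe_branchpoint_delta> AGEZ %s -> %s, BPS %.2f -> %.2f%s%s\n",
    x$agez_before, x$agez_after, x$bps_before, x$bps_after,
    if (x$moved_closer) " (moved closer)" else "",
    if (x$pyrimidine_gain) " (pyrimidine gain)" else ""
  ))
  invisible(x)
}

#' The "close the circuit" rule
#'
#' TRUE when a mutation enlarges the AG-exclusion zone, improves the best
#' branch-point score, or moves the branch point closer to the acceptor.
#' The pyrimidine-gain flag deliberately does not participate: it extends
#' branch-point *category* membership downstream but is not part of the
#' circuit rule itself.
#'
#' @param d a `pe_branchpoint_delta`.
#' @return logical flag.
#' @export
circuit_rule <- function(d) {
  isTRUE(d$agez_increased) || isTRUE(d$bps_increased) || isTRUE(d$moved_closer)
}
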