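## Strand-aware mapping between cDNA, genomic, and splice-site-relative
## coordinates.

## transcript (spliced, 0-based) coordinate of a cDNA anchor
.anchor_to_transcript <- function(anchor, cds_start_offset) {
  if (anchor > 0L) cds_start_offset + anchor - 1L else cds_start_offset + anchor
}

.transcript_to_anchor <- function(t, cds_start_offset) {
  if (t >= cds_start_offset) t - cds_start_offset + 1L else t - cds_start_offset
}

## exon index and within-exon offset for a transcript coordinate
.locate_transcript_pos <- function(t, context) {
  lens <- context$exons$end - context$exons$start
  cum <- cumsum(lens)
  if (t < 0L || t >= cum[length(cum)]) {
    stop("cDNA anchor lies outside the transcript", call. = FALSE)
  }
  i <- which(t < cum)[1L]
  u <- t - (if (i == 1L) 0L else cum[i - 1L])
  list(exon = i, within = u, exon_len = lens[i])
}

#' Map a cDNA position to a genomic position
#'
#' Mapping is strand-aware: for minus-strand genes, positive intronic offsets
#' move towards lower genomic coordinates. Intronic offsets are only valid
#' from the terminal base of an exon.
#'
#' @param pos a [cdna_position()].
#' @param context a [gene_context()].
#' @return genomic position (0-based, reference strand).
#' @export
cdna_to_genomic <- function(pos, context) {
  t <- .anchor_to_transcript(pos$anchor, context$cds_start_offset)
  loc <- .locate_transcript_pos(t, context)
  ex <- context$exons[loc$exon, ]
  plus <- context$strand == "+"
  g <- if (plus) ex$start + loc$within else ex$end - 1L - loc$within
  if (pos$offset == 0L) return(as.integer(g))
  n_exons <- nrow(context$exons)
  if (pos$offset > 0L) {
    if (loc$within != loc$exon_len - 1L || loc$exon == n_exons) {
      stop("positive intronic offset from a non-donor-boundary anchor: c.",
           format_cdna_position(pos), call. = FALSE)
    }
    as.integer(if (plus) g + pos$offset else g - pos$offset)
  } else {
    if (loc$within != 0L || loc$exon == 1L) {
      stop("negative intronic offset from a non-acceptor-boundary anchor: c.",
           format_cdna_position(pos), call. = FALSE)
    }
    as.integer(if (plus) g + pos$offset else g - pos$offset)
  }
}

#' Map a genomic position to a cDNA position
#'
#' Exonic positions get offset 0; intronic positions are anchored at the
#' nearer exon boundary (HGVS convention: the 5' half of an intron is numbered
#' from the upstream donor with `+n`, the 3' half from the downstream acceptor
#' with `-n`; ties go to the donor side).
#'
#' @param g genomic position (0-based).
#' @param context a [gene_context()].
#' @return a [cdna_position()].
#' @export
genomic_to_cdna <- function(g, context) {
  ex <- context$exons
  plus <- context$strand == "+"
  lens <- ex$end - ex$start
  cumstart <- c(0L, cumsum(lens))[seq_len(nrow(ex))]
  hit <- which(g >= ex$start & g < ex$end)
  if (length(hit) == 1L) {
    u <- if (plus) g - ex$start[hit] else ex$end[hit] - 1L - g
    t <- cumstart[hit] + u
    return(cdna_position(.transcript_to_anchor(t, context$cds_start_offset), 0L))
  }
  ## intron between transcript-consecutive exons i and i+1
  for (i in seq_len(nrow(ex) - 1L)) {
    donor_g <- if (plus) ex$end[i] - 1L else ex$start[i]      # last base of exon i
    accep_g <- if (plus) ex$start[i + 1L] else ex$end[i + 1L] - 1L  # first base of exon i+1
    inside <- if (plus) g > donor_g && g < accep_g else g < donor_g && g > accep_g
    if (!inside) next
    d_donor <- abs(g - donor_g)
    d_accep <- abs(accep_g - g)
    if (d_donor <= d_accep) {
      t <- cumstart[i] + lens[i] - 1L
      return(cdna_position(.transcript_to_anchor(t, context$cds_start_offset),
                           d_donor))
    }
    t <- cumstart[i + 1L]
    return(cdna_position(.transcript_to_anchor(t, context$cds_start_offset),
                         -d_accep))
  }
  stop("genomic position ", g, " lies outside the transcribed span of ",
       context$gene_symbol, call. = FALSE)
}

#' Splice-site-relative position of a genomic coordinate
#'
#' Labels a position relative to a pseudoexon's splice sites, in transcript
#' orientation: `A+1` is the first pseudoexon base, `A-1` the last intronic
#' base 5' of the acceptor AG's exonic boundary, `D-1` the last pseudoexon
#' base, and `D+1` the first intronic base 3' of the pseudoexon. Positions
#' inside the pseudoexon are labelled from the nearer boundary; ties go to
#' the acceptor.
#'
#' @param g genomic position (0-based).
#' @param record a [pseudoexon_record()].
#' @param strand strand of the host gene (`"+"` or `"-"`); defaults to the
#'   strand stored on the record.
#' @return object of class `pe_site_position` with fields `site` ("A" or "D")
#'   and `offset` (non-zero integer).
#' @export
relative_to_pe <- function(g, record, strand = record$strand) {
  s <- record$pe_start
  e <- record$pe_end
  if (strand == "+") {
    if (g >= s && g < e) {
      a_off <- g - s + 1L
      d_off <- -(e - g)
    } else if (g < s) {
      return(site_position("A", -(s - g)))
    } else {
      return(site_position("D", g - e + 1L))
    }
  } else {
    if (g >= s && g < e) {
      a_off <- e - g
      d_off <- -(g - s + 1L)
    } else if (g >= e) {
      return(site_position("A", -(g - e + 1L)))
    } else {
      return(site_position("D", s - g))
    }
  }
  if (a_off <= abs(d_off)) site_position("A", a_off) else site_position("D", d_off)
}

#' @rdname relative_to_pe
#' @param site "A" (acceptor) or "D" (donor).
#' @param offset signed non-zero offset.
#' @export
site_position <- function(site = c("A", "D"), offset) {
  site <- match.arg(site)
  offset <- as.integer(offset)
  if (offset == 0L) stop("site-relative offset cannot be 0", call. = FALSE)
  structure(list(site = site, offset = offset), class = "pe_site_position")
}

#' Format a site-relative position as "A+32" / "D-5"
#' @param pos a `pe_site_position`.
#' @return character scalar.
#' @export
format_site_position <- function(pos) {
  sprintf("%s%s%d", pos$site, if (pos$offset > 0L) "+" else "-",
          abs(pos$offset))
}

#' @export
print.pe_site_position <- function(x, ...) {
  cat("<pe_site_position> ", format_site_position(x), "\n", sep = "")
  invisible(x)
}

#' Reconstruct the genomic position from a site-relative label
#'
#' Inverse of [relative_to_pe()] given the same record.
#'
#' @param pos a `pe_site_position`.
#' @param record a [pseudoexon_record()].
#' @param strand host gene strand.
#' @return genomic position (0-based).
#' @export
site_position_to_genomic <- function(pos, record, strand = record$strand) {
  s <- record$pe_start
  e <- record$pe_end
  o <- pos$offset
  if (strand == "+") {
    if (pos$site == "A") {
      if (o > 0L) s + o - 1L else s + o
    } else {
      if (o > 0L) e + o - 1L else e + o
    }
  } else {
    if (pos$site == "A") {
      if (o > 0L) e - o else e - o - 1L
    } else {
      if (o > 0L) s - o else s - o - 1L
    }
  }
}
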