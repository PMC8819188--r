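## Transcript-level consequences of pseudoexon inclusion: reading frame,
## premature termination, nonsense-mediated decay (NMD), and poison-exon /
## novel-exon / terminal-pseudoexon candidacy.

#' Reading frame and premature termination codon scan
#'
#' The incoming frame is set by `upstream_cds` (codons start at its first
#' base; phase = length mod 3). The pseudoexon preserves the frame when its
#' length is divisible by 3. The novel stop is the first in-frame stop codon
#' (TAA/TAG/TGA) whose codon overlaps the pseudoexon; when the frame is
#' shifted, scanning continues into `downstream_cds` until a stop or the end
#' of sequence.
#'
#' @param upstream_cds spliced coding sequence 5' of the pseudoexon, starting
#'   at the translation start.
#' @param pe_seq pseudoexon sequence (transcript strand).
#' @param downstream_cds spliced sequence 3' of the pseudoexon.
#' @return list with `frame_preserved`, `novel_stop` (0-based nt into the
#'   pseudoexon of the stop codon's first base; may be -1/-2 for a codon
#'   straddling the acceptor junction; `NA` when none), `stop_codon`, and
#'   `ptc_end` (1-based position of the stop codon's last base on the
#'   upstream + pseudoexon + downstream axis; `NA` when none).
#' @export
frame_and_ptc <- function(upstream_cds, pe_seq, downstream_cds) {
  assert_dna(upstream_cds, "upstream CDS")
  assert_dna(pe_seq, "pseudoexon sequence")
  assert_dna(downstream_cds, "downstream CDS")
  len_up <- nchar(upstream_cds)
  len_pe <- nchar(pe_seq)
  frame_preserved <- len_pe %% 3L == 0L
  full <- paste0(upstream_cds, pe_seq, downstream_cds)
  out <- list(frame_preserved = frame_preserved, novel_stop = NA_integer_,
              stop_codon = NA_character_, ptc_end = NA_integer_)
  ## first codon that extends past the upstream CDS
  k <- len_up %/% 3L + 1L
  while (3L * k <= nchar(full)) {
    codon <- substr(full, 3L * k - 2L, 3L * k)
    past_pe <- 3L * k - 2L > len_up + len_pe
    if (past_pe && frame_preserved) break  # back in the original frame
    if (codon %in% STOP_CODONS) {
      out$novel_stop <- 3L * k - 3L - len_up
      out$stop_codon <- codon
      out$ptc_end <- 3L * k
      break
    }
    k <- k + 1L
  }
  out
}

#' NMD prediction by the 55-nt rule
#'
#' A premature termination codon triggers NMD unless it lies less than 55 nt
#' upstream of the final exon-exon junction (a distance of exactly 55 nt
#' still triggers NMD). A PTC at or downstream of the final junction
#' (last-exon stop) never triggers NMD.
#'
#' @param ptc_pos position of the stop codon's last base on the spliced
#'   transcript.
#' @param final_junction_pos position of the final exon-exon junction on the
#'   same axis.
#' @return logical flag.
#' @export
nmd_predicted <- function(ptc_pos, final_junction_pos) {
  if (is.na(ptc_pos) || is.na(final_junction_pos)) return(NA)
  (final_junction_pos - ptc_pos) >= 55L
}

#' Annotate the transcript-level effect of a pseudoexon
#'
#' Builds the mutant spliced transcript (canonical exons with the pseudoexon
#' inserted into its host intron), locates any novel stop codon, applies the
#' 55-nt NMD rule, and derives candidacy flags:
#' * `poison_candidate`: splice evidence at >= 1 site AND a disrupted open
#'   reading frame (frameshift or novel stop);
#' * `novel_exon_candidate`: splice evidence AND frame preserved AND no
#'   novel stop;
#' * `terminal_pe`: flagged terminal AND confirmed polyadenylation site AND
#'   a validation-clean novel acceptor ([validate_pseudoexon()] reports no
#'   violations).
#'
#' @param record a [pseudoexon_record()].
#' @param context the host [gene_context()].
#' @param sequences named list/vector of chromosome sequences.
#' @return object of class `pe_transcript_effect`.
#' @export
annotate_effect <- function(record, context, sequences) {
  chrseq <- sequences[[record$chrom]]
  if (is.null(chrseq)) {
    stop("no sequence available for chromosome ", record$chrom, call. = FALSE)
  }
  ex <- context$exons
  n_ex <- nrow(ex)
  i <- record$intron_index
  if (i >= n_ex) {
    stop("intron_index ", i, " has no downstream canonical exon", call. = FALSE)
  }
  exon_seq <- vapply(seq_len(n_ex), function(j) {
    s <- seq_sub(chrseq, ex$start[j], ex$end[j])
    if (context$strand == "-") revcomp(s) else s
  }, "")
  pe_seq <- seq_sub(chrseq, record$pe_start, record$pe_end)
  if (record$strand == "-") pe_seq <- revcomp(pe_seq)

  evidence <- record$splice_evidence_acceptor || record$splice_evidence_donor
  frame_preserved <- pe_length(record) %% 3L == 0L
  novel_stop <- NA_integer_
  ptc_distance <- NA_integer_
  nmd <- NA

  upstream_tx <- paste(exon_seq[seq_len(i)], collapse = "")
  cds0 <- context$cds_start_offset
  if (is.na(cds0) || cds0 < 0L || cds0 >= nchar(upstream_tx)) {
    warning("CDS phase unavailable for ", context$gene_symbol,
            "; frame fields left unset", call. = FALSE)
  } else {
    downstream_tx <- paste(exon_seq[(i + 1L):n_ex], collapse = "")
    fp <- frame_and_ptc(substr(upstream_tx, cds0 + 1L, nchar(upstream_tx)),
                        pe_seq, downstream_tx)
    frame_preserved <- fp$frame_preserved
    novel_stop <- fp$novel_stop
    if (!is.na(fp$ptc_end)) {
      ## final exon-exon junction on the mutant spliced axis used by the scan
      lens <- nchar(exon_seq)
      final_junction <- sum(lens[seq_len(n_ex - 1L)]) + nchar(pe_seq) - cds0
      ptc_distance <- final_junction - fp$ptc_end
      nmd <- nmd_predicted(fp$ptc_end, final_junction)
    }
  }

  disrupted <- !frame_preserved || !is.na(novel_stop)
  terminal <- FALSE
  if (record$is_terminal && record$polya_confirmed) {
    violations <- withCallingHandlers(
      validate_pseudoexon(record, context,
                          sequences = stats::setNames(list(chrseq),
                                                      record$chrom)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    terminal <- length(violations) == 0L
  }
  structure(
    list(frame_preserved = frame_preserved, novel_stop = novel_stop,
         ptc_distance_to_final_junction = ptc_distance, nmd_predicted = nmd,
         poison_candidate = evidence && disrupted,
         novel_exon_candidate = evidence && !disrupted,
         terminal_pe = terminal),
    class = "pe_transcript_effect"
  )
}

#' @export
print.pe_transcript_effect <- function(x, ...) {
  flags <- c(if (isTRUE(x$poison_candidate)) "poison-exon candidate",
             if (isTRUE(x$novel_exon_candidate)) "novel-exon candidate",
             if (isTRUE(x$terminal_pe)) "terminal pseudoexon")
  cat(sprintf(
    "<pe_transcript_effect> frame %s, novel stop %s, NMD %s%s\n",
    if (x$frame_preserved) "preserved" else "shifted",
    if (is.na(x$novel_stop)) "none" else paste0("at PE+", x$novel_stop),
    if (is.na(x$nmd_predicted)) "n/a" else x$nmd_predicted,
    if (length(flags)) paste0(" [", paste(flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}
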