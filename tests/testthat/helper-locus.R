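# A tiny fully hand-written locus used across tests, so expectations can be
# computed by eye. Layout (0-based, + strand, 400 nt):
#   exon1 [20, 80)   intron [80, 340)   exon2 [340, 400)
#   pseudoexon [180, 240)
make_hand_locus <- function(strand = "+") {
  set.seed(424242)
  ch <- strsplit(paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                              prob = c(0.3, 0.2, 0.2, 0.3)),
                       collapse = ""), "")[[1L]]
  set_at <- function(pos0, str) {
    s <- strsplit(str, "")[[1L]]
    ch[(pos0 + 1L):(pos0 + length(s))] <<- s
    invisible(NULL)
  }
  # canonical intron boundaries
  set_at(77L, "CAG"); set_at(80L, "GTAAGT")
  set_at(320L, paste(rep("T", 17), collapse = "")); set_at(337L, "CAG")
  set_at(340L, "GTT")
  # latent pseudoexon [180, 240): bounding AG then a 50-nt AGEZ
  set_at(126L, "AG")
  set_at(128L, paste(rep("C", 32), collapse = ""))  # AG-free filler 128..159
  set_at(146L, "TACTAAC")                            # branch A at 151 (A-29)
  set_at(160L, paste(rep("T", 17), collapse = ""))
  set_at(177L, "G")                                  # degraded A-3 (cons C)
  set_at(178L, "AG")
  set_at(180L, "GTT")
  set_at(237L, "CAG")
  set_at(240L, "GTAAGA")                             # degraded donor (+6 A)
  sense <- paste(ch, collapse = "")
  L <- 400L
  if (strand == "+") {
    seq <- sense
    exons <- data.frame(start = c(20L, 340L), end = c(80L, 380L))
    pe <- c(180L, 240L)
    pa <- 390L  # in the 3' tail, outside exon 2
  } else {
    seq <- pseudex::revcomp(sense)
    exons <- data.frame(start = c(L - 380L, L - 80L), end = c(L - 340L, L - 20L))
    exons <- exons[2:1, ]  # transcript order for minus strand
    rownames(exons) <- NULL
    pe <- c(L - 240L, L - 180L)
    pa <- L - 1L - 390L
  }
  ctx <- gene_context("HANDG", "TX1", "chrH", strand, exons,
                      cds_start_offset = 0L, polyadenylation_sites = pa)
  rec <- pseudoexon_record(pe_id = "HANDG-1-1", gene = "HANDG",
                           chrom = "chrH", strand = strand,
                           intron_index = 1L, pe_start = pe[1L],
                           pe_end = pe[2L])
  list(sense = sense, seq = seq, seqs = stats::setNames(list(seq), "chrH"),
       ctx = ctx, rec = rec, L = L)
}

# sense-axis position -> reference-strand position for a hand locus
hand_g <- function(loc, p) {
  if (loc$ctx$strand == "+") p else loc$L - 1L - p
}
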