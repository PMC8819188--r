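## Synthetic locus, pseudoexon, and catalogue generator.
##
## Each locus is a toy 2-exon gene whose intron carries a latent pseudoexon:
## a strong (toy-model) acceptor with a planted AG-exclusion zone and branch
## motif, and a sub-threshold donor. Implanted mutations are constructed so
## that the classifier rule for the requested category -- and no earlier
## rule in the decision order -- fires under the packaged toy models.

#' Simulation parameters
#'
#' Defaults encode the statistical structure of the curated pathogenic
#' pseudoexon landscape: the five-way mechanism mix in proportion
#' 210:53:14:37:35 (donor, acceptor, branch point, internal, flanking),
#' transition:transversion odds 165:92, and a normal-cell splice-evidence
#' rate of 15.7%.
#'
#' @param seed RNG seed (non-negative, below 2^31).
#' @param n_entries number of catalogue entries to generate.
#' @param category_mix positive weights over classifier categories.
#' @param ti_tv_ratio two positive weights (transitions, transversions).
#' @param evidence_rate per-entry probability of normal-cell splice evidence.
#' @param pe_length_range,intron_length_range,exon_length_range inclusive
#'   integer ranges (nt).
#' @param gc_content background GC fraction.
#' @param agez_range inclusive range of planted AG-exclusion-zone lengths.
#' @return object of class `pe_sim_params`.
#' @export
sim_params <- function(seed = 1L, n_entries = 100L,
                       category_mix = c(DONOR_MOTIF = 210,
                                        ACCEPTOR_MOTIF = 53,
                                        BRANCHPOINT = 14,
                                        INTERNAL_ESE_ESS = 37,
                                        FLANKING_EXON_DEFINITION_LOSS = 35),
                       ti_tv_ratio = c(165, 92), evidence_rate = 0.157,
                       pe_length_range = c(50L, 250L),
                       intron_length_range = c(1500L, 3000L),
                       exon_length_range = c(120L, 200L),
                       gc_content = 0.42, agez_range = c(40L, 80L)) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) {
    stop("seed must be a non-negative integer below 2^31", call. = FALSE)
  }
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% MUTATION_CATEGORIES)) {
    stop("category_mix must be named by classifier categories", call. = FALSE)
  }
  if (any(category_mix <= 0) || any(ti_tv_ratio <= 0)) {
    stop("mix weights must be positive", call. = FALSE)
  }
  if (evidence_rate < 0 || evidence_rate > 1) {
    stop("evidence_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = seed, n_entries = as.integer(n_entries),
         category_mix = category_mix / sum(category_mix),
         p_transition = ti_tv_ratio[1L] / sum(ti_tv_ratio),
         evidence_rate = evidence_rate,
         pe_length_range = as.integer(pe_length_range),
         intron_length_range = as.integer(intron_length_range),
         exon_length_range = as.integer(exon_length_range),
         gc_content = gc_content, agez_range = as.integer(agez_range)),
    class = "pe_sim_params"
  )
}

#' @export
print.pe_sim_params <- function(x, ...) {
  cat(sprintf("<pe_sim_params> seed %d, n %d, ti fraction %.3f, evidence %.3f\n",
              x$seed, x$n_entries, x$p_transition, x$evidence_rate))
  invisible(x)
}

## sample one element of a vector (safe for length-1 vectors)
samp1 <- function(v) v[sample.int(length(v), 1L)]

## overwrite a character-vector sequence at 0-based position
.set_at <- function(ch, pos0, str) {
  s <- seq_chars(str)
  ch[(pos0 + 1L):(pos0 + length(s))] <- s
  ch
}

## proximity margin each side of a latent pseudoexon (proximal window + slack)
PE_MARGIN <- 620L

## plant a latent pseudoexon at sense position pe_s; returns the modified
## character vector plus the implant layout
.plant_pe <- function(ch, pe_s, pe_len, ti, agez_len, gc) {
  pe_e <- pe_s + pe_len
  d_b <- samp1(26:34)  # branch adenosine distance from the acceptor
  ## bounding AG, then an AG-free zone of exactly agez_len nt down to A-3
  ch <- .set_at(ch, pe_s - agez_len - 4L, "AG")
  free_len <- agez_len - 18L  # zone 5' of the 17-nt T-run and A-3
  ch <- .set_at(ch, pe_s - agez_len - 2L,
                random_dna(free_len, gc, forbid_ag = TRUE))
  ch <- .set_at(ch, pe_s - d_b - 5L, "TACTAAC")
  ch <- .set_at(ch, pe_s - 20L, strrep("T", 17L))
  acc3_ref <- if (ti) "T" else "G"  # degraded A-3 (consensus C)
  ch <- .set_at(ch, pe_s - 3L, acc3_ref)
  ch <- .set_at(ch, pe_s - 2L, "AG")
  ch <- .set_at(ch, pe_s, "GTT")
  p_int <- pe_s + pe_len %/% 2L
  ch <- .set_at(ch, p_int, if (ti) "G" else "C")
  ch <- .set_at(ch, pe_e - 3L, "CAG")
  ch <- .set_at(ch, pe_e, if (ti) "GTAAAT" else "GTAAGA")  # degraded donor
  layout <- list(
    pe_s = pe_s, pe_e = pe_e, agez_len = agez_len, branch_distance = d_b,
    bounding_a = pe_s - agez_len - 4L, bounding_g = pe_s - agez_len - 3L,
    acc3 = pe_s - 3L, acc3_ref = acc3_ref, p_int = p_int,
    donor_deg_pos = if (ti) pe_e + 4L else pe_e + 5L,
    donor_deg_alt = if (ti) "G" else "T"
  )
  list(ch = ch, layout = layout)
}

#' Generate one synthetic locus
#'
#' A toy 2-exon gene with one intron carrying a latent pseudoexon (strong
#' toy-model acceptor, planted AG-exclusion zone and branch motif,
#' sub-threshold donor) plus one polyadenylation site 3' of the gene.
#'
#' @param params a [sim_params()].
#' @param seed optional seed for standalone use; leave `NULL` when the
#'   caller manages the RNG stream.
#' @param gene,chrom identifiers for the generated gene and chromosome.
#' @param strand `"+"`, `"-"`, or `NULL` to draw one at random.
#' @param with_sibling also plant a second latent pseudoexon in the same
#'   intron (needed for sibling-activation implants).
#' @param pe_offset optional fixed pseudoexon offset into the intron
#'   (default: drawn uniformly); e.g. place the pseudoexon early in a long
#'   intron to leave room for a juxtaposing deletion implant.
#' @return object of class `pe_locus`: `context`, `record`, `sequence`
#'   (reference strand), `sense_seq`, `sibling_record`, per-feature sense
#'   coordinates in `layout`, and the drawn transition flag `ti`.
#' @export
generate_locus <- function(params = sim_params(), seed = NULL,
                           gene = "SYNGENE", chrom = "chr_sim",
                           strand = NULL, with_sibling = FALSE,
                           pe_offset = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  strand <- strand %||% samp1(c("+", "-"))
  ti <- stats::runif(1L) < params$p_transition
  gc <- params$gc_content
  exr <- params$exon_length_range
  inr <- params$intron_length_range
  per <- params$pe_length_range
  exon1_len <- samp1(exr[1L]:exr[2L])
  exon2_len <- samp1(exr[1L]:exr[2L])
  if (with_sibling) {
    pe_len <- samp1(50:120)
    sib_len <- samp1(50:120)
    need <- 2L * PE_MARGIN + pe_len + 350L + sib_len
    if (inr[2L] < need) {
      stop("intron_length_range too short for a sibling pseudoexon",
           call. = FALSE)
    }
    intron_len <- samp1(max(inr[1L], need):inr[2L])
    pe_off <- PE_MARGIN
  } else {
    pe_cap <- min(per[2L], inr[2L] - 2L * PE_MARGIN)
    if (pe_cap < per[1L]) {
      stop("infeasible length constraints: intron too short for the ",
           "pseudoexon and its margins", call. = FALSE)
    }
    pe_len <- samp1(per[1L]:pe_cap)
    intron_len <- samp1(max(inr[1L], pe_len + 2L * PE_MARGIN):inr[2L])
    pe_off <- samp1(PE_MARGIN:(intron_len - pe_len - PE_MARGIN))
  }
  if (!is.null(pe_offset)) {
    pe_off <- as.integer(pe_offset)
    if (pe_off < PE_MARGIN || pe_off > intron_len - pe_len - PE_MARGIN) {
      stop("pe_offset leaves less than ", PE_MARGIN,
           " nt of margin on one side of the pseudoexon", call. = FALSE)
    }
  }
  pad <- 60L
  L <- pad + exon1_len + intron_len + exon2_len + pad
  i0 <- pad + exon1_len        # first intron base (sense)
  i1 <- i0 + intron_len        # first exon-2 base (sense)
  ch <- seq_chars(random_dna(L, gc))
  ## canonical splice sites of the real intron
  ch <- .set_at(ch, i0 - 3L, "CAG")
  ch <- .set_at(ch, i0, "GTAAGT")
  ch <- .set_at(ch, i1 - 20L, strrep("T", 17L))
  ch <- .set_at(ch, i1 - 3L, "CAG")
  ch <- .set_at(ch, i1, "GTT")
  ## latent pseudoexon(s)
  agez_len <- samp1(params$agez_range[1L]:params$agez_range[2L])
  pe_s <- i0 + pe_off
  planted <- .plant_pe(ch, pe_s, pe_len, ti, agez_len, gc)
  ch <- planted$ch
  layout <- planted$layout
  sib_layout <- NULL
  if (with_sibling) {
    sib_s <- layout$pe_e + 350L
    sp <- .plant_pe(ch, sib_s, sib_len, ti, samp1(40:60), gc)
    ch <- sp$ch
    sib_layout <- sp$layout
  }
  sense_seq <- paste(ch, collapse = "")
  pa_sense <- L - pad + 20L  # polyadenylation site in the 3' pad

  plus <- strand == "+"
  map_pos <- function(p) if (plus) p else L - 1L - p
  map_iv <- function(a, b) if (plus) c(a, b) else c(L - b, L - a)
  ref_seq <- if (plus) sense_seq else revcomp(sense_seq)
  ex1 <- map_iv(pad, i0)
  ex2 <- map_iv(i1, i1 + exon2_len)
  context <- gene_context(
    gene_symbol = gene, chrom = chrom, strand = strand,
    exons = data.frame(start = c(ex1[1L], ex2[1L]),
                       end = c(ex1[2L], ex2[2L])),
    cds_start_offset = 0L,
    polyadenylation_sites = map_pos(pa_sense)
  )
  pe_iv <- map_iv(layout$pe_s, layout$pe_e)
  record <- pseudoexon_record(
    pe_id = paste0(gene, "-1-1"), gene = gene, chrom = chrom,
    strand = strand, intron_index = 1L,
    pe_start = pe_iv[1L], pe_end = pe_iv[2L]
  )
  sibling_record <- NULL
  if (with_sibling) {
    sib_iv <- map_iv(sib_layout$pe_s, sib_layout$pe_e)
    sibling_record <- pseudoexon_record(
      pe_id = paste0(gene, "-1-2"), gene = gene, chrom = chrom,
      strand = strand, intron_index = 1L,
      pe_start = sib_iv[1L], pe_end = sib_iv[2L]
    )
  }
  structure(
    list(gene = gene, chrom = chrom, strand = strand, length = L,
         sequence = ref_seq, sense_seq = sense_seq, context = context,
         record = record, sibling_record = sibling_record,
         layout = c(layout, list(i0 = i0, i1 = i1, pa = pa_sense,
                                 sibling = sib_layout)),
         ti = ti),
    class = "pe_locus"
  )
}

#' @export
print.pe_locus <- function(x, ...) {
  cat(sprintf("<pe_locus> %s %s(%s) %d nt, latent PE %d nt\n", x$gene,
              x$chrom, x$strand, x$length, x$layout$pe_e - x$layout$pe_s))
  invisible(x)
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_PARTNER <- c(A = "C", G = "T", C = "A", T = "G")

## SNV at a sense-axis position, returned as a resolved pe_mutation
.sense_snv <- function(locus, pos, alt) {
  ref <- substr(locus$sense_seq, pos + 1L, pos + 1L)
  stopifnot(ref != alt)
  plus <- locus$strand == "+"
  g <- if (plus) pos else locus$length - 1L - pos
  hgvs <- paste0("c.",
                 format_cdna_position(genomic_to_cdna(g, locus$context)),
                 ref, ">", alt)
  instigating_mutation(hgvs, "SNV", g, g + 1L,
                       ref_allele = if (plus) ref else revcomp(ref),
                       alt_allele = if (plus) alt else revcomp(alt),
                       size = 1L)
}

## deletion of sense-axis half-open interval [a, b)
.sense_del <- function(locus, a, b, in_transcript = TRUE) {
  plus <- locus$strand == "+"
  iv <- if (plus) c(a, b) else c(locus$length - b, locus$length - a)
  hgvs <- NA_character_
  if (in_transcript) {
    g1 <- if (plus) a else locus$length - 1L - a
    g2 <- if (plus) b - 1L else locus$length - b
    hgvs <- paste0(
      "c.", format_cdna_position(genomic_to_cdna(g1, locus$context)), "_",
      format_cdna_position(genomic_to_cdna(g2, locus$context)), "del")
  }
  instigating_mutation(hgvs, "deletion", iv[1L], iv[2L], size = b - a)
}

#' Implant an instigating mutation of a requested category
#'
#' Constructs a mutation in `locus` such that the classifier rule for
#' `category` -- and no earlier rule in the decision order -- fires under
#' the packaged toy models. The transition/transversion character of SNV
#' implants follows the flag drawn when the locus was generated.
#'
#' @param locus a [generate_locus()] result.
#' @param category the target classifier category.
#' @param config a [classify_config()] (sets the juxtaposition deletion
#'   size).
#' @return list with `mutation` (a resolved [instigating_mutation()]),
#'   `category` (the truth label) and `transition`.
#' @export
implant_mutation <- function(locus, category, config = classify_config()) {
  stopifnot(inherits(locus, "pe_locus"))
  lay <- locus$layout
  ti <- locus$ti
  mutation <- switch(category,
    DONOR_MOTIF = .sense_snv(locus, lay$donor_deg_pos, lay$donor_deg_alt),
    ACCEPTOR_MOTIF = .sense_snv(locus, lay$acc3, "C"),
    BRANCHPOINT = if (ti) .sense_snv(locus, lay$bounding_a, "G") else
      .sense_snv(locus, lay$bounding_g, "T"),
    INTERNAL_ESE_ESS = .sense_snv(locus, lay$p_int, "A"),
    FLANKING_EXON_DEFINITION_LOSS =
      .sense_snv(locus, lay$i0, if (ti) "A" else "T"),
    PROXIMAL_INTRONIC_MOTIF = {
      pos <- lay$pe_s - samp1(120:595)
      ref <- substr(locus$sense_seq, pos + 1L, pos + 1L)
      alt <- if (ti) TRANSITION_PARTNER[[ref]] else
        TRANSVERSION_PARTNER[[ref]]
      .sense_snv(locus, pos, alt)
    },
    INTERNAL_DELETION_JUXTAPOSITION = {
      size <- config$large_deletion_threshold + 500L
      a <- lay$p_int
      if (a + size > lay$i1 - 25L) {
        stop("category INTERNAL_DELETION_JUXTAPOSITION is not implantable: ",
             "the intron is too short for a juxtaposing deletion",
             call. = FALSE)
      }
      .sense_del(locus, a, a + size)
    },
    POLYA_LOSS_READTHROUGH =
      .sense_del(locus, lay$pa - 8L, lay$pa + 8L, in_transcript = FALSE),
    SIBLING_PE_ACTIVATION = {
      if (is.null(lay$sibling)) {
        stop("category SIBLING_PE_ACTIVATION is not implantable: the locus ",
             "was generated without a sibling pseudoexon", call. = FALSE)
      }
      .sense_snv(locus, lay$sibling$donor_deg_pos, lay$sibling$donor_deg_alt)
    },
    stop("no implant construction for category '", category, "'",
         call. = FALSE)
  )
  list(mutation = mutation, category = category, transition = ti)
}

#' Generate a whole synthetic catalogue
#'
#' Draws `n_entries` loci, implants one mutation per entry according to the
#' category mix, flips the splice-evidence flag at the evidence rate, and
#' returns entries, gene contexts, chromosome sequences and the implant
#' truth table. Output is fully determined by `params$seed`.
#'
#' @param params a [sim_params()].
#' @param dir optional directory; when given, `catalogue.tsv`, `truth.tsv`,
#'   `contexts.json` and `sequences.fa` are written there.
#' @return list with `entries`, `contexts` (named by gene), `sequences`
#'   (named by chromosome), `truth` (data.frame `pe_id`, `gene`, `chrom`,
#'   `strand`, `true_category`, `transition`, `hgvs`) and `params`.
#' @export
generate_catalogue <- function(params = sim_params(), dir = NULL) {
  set.seed(params$seed)
  n <- params$n_entries
  mix <- params$category_mix
  entries <- vector("list", n)
  contexts <- vector("list", n)
  sequences <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    category <- names(mix)[samp1_weighted(mix)]
    gene <- sprintf("SYN%04d", k)
    chrom <- sprintf("chr_s%04d", k)
    locus <- generate_locus(params, seed = NULL, gene = gene, chrom = chrom)
    imp <- implant_mutation(locus, category)
    record <- locus$record
    record$splice_evidence_acceptor <- stats::runif(1L) < params$evidence_rate
    entries[[k]] <- catalogue_entry(record, list(imp$mutation))
    contexts[[k]] <- locus$context
    sequences[[k]] <- locus$sequence
    truth[[k]] <- data.frame(
      pe_id = record$pe_id, gene = gene, chrom = chrom,
      strand = locus$strand, true_category = category,
      transition = imp$transition, hgvs = imp$mutation$hgvs_cdna
    )
  }
  names(contexts) <- vapply(contexts, function(x) x$gene_symbol, "")
  names(sequences) <- vapply(entries, function(e) e$record$chrom, "")
  truth <- if (n > 0L) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame(pe_id = character(0), gene = character(0),
               chrom = character(0), strand = character(0),
               true_category = character(0), transition = logical(0),
               hgvs = character(0))
  }
  out <- list(entries = entries, contexts = contexts,
              sequences = sequences, truth = truth, params = params)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_catalogue(entries, file.path(dir, "catalogue.tsv"))
    writeLines(c(
      paste0("#", paste(names(truth), collapse = "\t")),
      if (n > 0L) do.call(paste, c(truth, list(sep = "\t")))
    ), file.path(dir, "truth.tsv"))
    write_gene_contexts(contexts, file.path(dir, "contexts.json"))
    .write_fasta(sequences, file.path(dir, "sequences.fa"))
  }
  invisible(out)
}

## weighted index draw from a normalized probability vector
samp1_weighted <- function(p) {
  sample.int(length(p), 1L, prob = p)
}

.write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = 70L)
      writeLines(substring(s, starts, pmin(starts + 69L, n)), con)
    }
  }
  invisible(path)
}
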