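#' Pseudoexon record
#'
#' One catalogued pseudoexon: identity, genomic coordinates, splice-site
#' dinucleotides, normal-cell splice-evidence flags, and provenance.
#'
#' @param pe_id unique ID in the form `GENE-intron-number[letter]` (may be
#'   `NA` before [assign_pe_ids()] has run).
#' @param gene gene symbol.
#' @param transcript transcript identifier (informational).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param intron_index 1-based index of the encompassing intron.
#' @param pe_start,pe_end genomic interval (0-based half-open, + strand).
#' @param acceptor_dinuc,donor_dinuc terminal intronic dinucleotides
#'   (canonically `"AG"` and `"GT"`).
#' @param is_terminal is this a terminal pseudoexon candidate?
#' @param polya_confirmed was a de novo polyadenylation site confirmed?
#' @param splice_evidence_acceptor,splice_evidence_donor normal-cell splicing
#'   evidence at each site.
#' @param cell_types,citations character vectors of provenance.
#' @return object of class `pe_record`.
#' @export
pseudoexon_record <- function(pe_id = NA_character_, gene, transcript = NA_character_,
                              chrom, strand = c("+", "-"), intron_index,
                              pe_start, pe_end, acceptor_dinuc = "AG",
                              donor_dinuc = "GT", is_terminal = FALSE,
                              polya_confirmed = FALSE,
                              splice_evidence_acceptor = FALSE,
                              splice_evidence_donor = FALSE,
                              cell_types = character(0),
                              citations = character(0)) {
  strand <- match.arg(strand)
  pe_start <- as.integer(pe_start)
  pe_end <- as.integer(pe_end)
  intron_index <- as.integer(intron_index)
  if (is.na(pe_start) || is.na(pe_end) || pe_start >= pe_end) {
    stop("pseudoexon interval is empty or inverted (pe_start must be < pe_end)",
         call. = FALSE)
  }
  if (intron_index < 1L) stop("intron_index must be >= 1", call. = FALSE)
  if (!is.na(pe_id) &&
      !grepl("^[A-Z0-9]+(-[A-Z0-9]+)*-\\d+-\\d+[a-z]?$", pe_id)) {
    stop("malformed pe_id '", pe_id, "'", call. = FALSE)
  }
  structure(
    list(pe_id = pe_id, gene = gene, transcript = transcript, chrom = chrom,
         strand = strand, intron_index = intron_index, pe_start = pe_start,
         pe_end = pe_end, acceptor_dinuc = toupper(acceptor_dinuc),
         donor_dinuc = toupper(donor_dinuc), is_terminal = isTRUE(is_terminal),
         polya_confirmed = isTRUE(polya_confirmed),
         splice_evidence_acceptor = isTRUE(splice_evidence_acceptor),
         splice_evidence_donor = isTRUE(splice_evidence_donor),
         cell_types = cell_types, citations = citations),
    class = "pe_record"
  )
}

#' @export
print.pe_record <- function(x, ...) {
  cat(sprintf("<pe_record> %s %s:%d-%d(%s) %dnt %s..%s\n",
              x$pe_id, x$chrom, x$pe_start, x$pe_end, x$strand,
              x$pe_end - x$pe_start, x$acceptor_dinuc, x$donor_dinuc))
  invisible(x)
}

## pseudoexon length in nt
pe_length <- function(record) record$pe_end - record$pe_start

## genomic positions (0-based base coordinates) of the two splice boundaries
pe_boundaries <- function(record) {
  if (record$strand == "+") {
    c(acceptor = record$pe_start, donor = record$pe_end - 1L)
  } else {
    c(acceptor = record$pe_end - 1L, donor = record$pe_start)
  }
}

#' Instigating mutation with resolved genomic coordinates
#'
#' Usually produced by [resolve_mutation()]; direct construction is useful
#' for mutations (large rearrangements) that have no parsable cDNA form.
#'
#' @param hgvs_cdna HGVS-style cDNA string (may be `NA`).
#' @param kind one of `SNV`, `deletion`, `insertion`, `delins`, `inversion`,
#'   `rearrangement`.
#' @param genomic_start,genomic_end 0-based half-open reference interval
#'   (`end = start + 1` for an SNV); `NA` when unresolved.
#' @param ref_allele,alt_allele reference-strand alleles (empty string where
#'   inapplicable).
#' @param size affected length in nt.
#' @return object of class `pe_mutation`.
#' @export
instigating_mutation <- function(hgvs_cdna = NA_character_,
                                 kind = c("SNV", "deletion", "insertion",
                                          "delins", "inversion",
                                          "rearrangement"),
                                 genomic_start = NA_integer_,
                                 genomic_end = NA_integer_,
                                 ref_allele = "", alt_allele = "",
                                 size = NA_integer_) {
  kind <- match.arg(kind)
  if (kind == "SNV") {
    if (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L ||
        ref_allele == alt_allele) {
      stop("an SNV needs single, distinct ref and alt alleles", call. = FALSE)
    }
  }
  gs <- as.integer(genomic_start)
  ge <- as.integer(genomic_end)
  if (!is.na(gs) && !is.na(ge)) {
    if (gs > ge) stop("genomic_start must be <= genomic_end", call. = FALSE)
    if (kind == "deletion") size <- ge - gs
    if (kind == "SNV" && ge - gs != 1L) {
      stop("an SNV spans exactly one base", call. = FALSE)
    }
  }
  structure(
    list(hgvs_cdna = hgvs_cdna, kind = kind, genomic_start = gs,
         genomic_end = ge, ref_allele = toupper(ref_allele),
         alt_allele = toupper(alt_allele), size = as.integer(size)),
    class = "pe_mutation"
  )
}

#' Resolve a parsed cDNA variant against a gene context
#'
#' Maps both bounds to the genome and converts transcript-strand alleles to
#' reference-strand alleles (reverse-complemented for minus-strand genes).
#'
#' @param variant a [parse_cdna_variant()] result or HGVS string.
#' @param context a [gene_context()].
#' @return a [instigating_mutation()].
#' @export
resolve_mutation <- function(variant, context) {
  if (is.character(variant)) variant <- parse_cdna_variant(variant)
  g1 <- cdna_to_genomic(variant$start, context)
  g2 <- if (is.null(variant$end)) g1 else cdna_to_genomic(variant$end, context)
  lo <- min(g1, g2)
  hi <- max(g1, g2)
  plus <- context$strand == "+"
  ref <- variant$ref
  alt <- variant$alt
  if (!plus) {
    if (nzchar(ref)) ref <- revcomp(ref)
    if (nzchar(alt)) alt <- revcomp(alt)
  }
  kind <- variant$kind
  if (kind == "SNV") {
    return(instigating_mutation(variant$hgvs, "SNV", lo, lo + 1L, ref, alt, 1L))
  }
  if (kind == "deletion") {
    return(instigating_mutation(variant$hgvs, "deletion", lo, hi + 1L,
                                ref_allele = ref, alt_allele = "",
                                size = hi + 1L - lo))
  }
  if (kind == "insertion") {
    ## HGVS insertions sit between the two flanking positions; duplications
    ## insert a copy of the duplicated tract after it (reference-strand
    ## insertion point chosen accordingly)
    if (isTRUE(variant$is_duplication)) {
      return(instigating_mutation(variant$hgvs, "insertion", hi + 1L, hi + 1L,
                                  alt_allele = "", size = hi + 1L - lo))
    }
    ins_at <- if (plus) g1 + 1L else g1
    return(instigating_mutation(variant$hgvs, "insertion", ins_at, ins_at,
                                alt_allele = alt, size = nchar(alt)))
  }
  if (kind == "delins") {
    return(instigating_mutation(variant$hgvs, "delins", lo, hi + 1L,
                                alt_allele = alt, size = hi + 1L - lo))
  }
  instigating_mutation(variant$hgvs, kind, lo, hi + 1L, size = hi + 1L - lo)
}

#' Catalogue entry: one pseudoexon variant plus its instigating mutations
#'
#' @param record a [pseudoexon_record()].
#' @param mutations list of [instigating_mutation()] (may be empty, e.g. for
#'   deletion-created pseudoexons described only at the DNA level).
#' @param category optional classification result (output column).
#' @return object of class `pe_catalogue_entry`.
#' @export
catalogue_entry <- function(record, mutations = list(), category = NULL) {
  stopifnot(inherits(record, "pe_record"))
  structure(list(record = record, mutations = mutations, category = category),
            class = "pe_catalogue_entry")
}

#' @export
print.pe_catalogue_entry <- function(x, ...) {
  cat(sprintf("<pe_catalogue_entry> %s, %d mutation(s)%s\n",
              x$record$pe_id, length(x$mutations),
              if (is.null(x$category)) "" else
                paste0(", category ", x$category$category)))
  invisible(x)
}

CATALOGUE_COLUMNS <- c(
  "pe_id", "gene", "transcript", "chrom", "strand", "intron_index",
  "pe_start", "pe_end", "acceptor_dinuc", "donor_dinuc", "mutations",
  "splice_evidence_acceptor", "splice_evidence_donor", "is_terminal",
  "polya_confirmed", "frame_preserving", "category", "cell_types", "citations"
)

#' Read a pseudoexon catalogue from TSV
#'
#' The file is tab-separated with a `#`-prefixed header naming the columns
#' (see [write_catalogue()]); booleans are 0/1, multiple mutations, cell
#' types and citations are `;`-joined. When `contexts` are supplied,
#' mutations are resolved to genomic coordinates via each entry's gene.
#'
#' @param path TSV file path.
#' @param contexts optional named list of [gene_context()] objects keyed by
#'   gene symbol.
#' @return list of [catalogue_entry()] objects.
#' @export
read_catalogue <- function(path, contexts = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty catalogue file: ", path, call. = FALSE)
  header <- sub("^#", "", lines[1L])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  entries <- vector("list", length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    length(fields) <- length(cols)
    fields[is.na(fields)] <- ""
    row <- stats::setNames(as.list(fields), cols)
    entries[[i]] <- tryCatch(
      .entry_from_row(row, contexts),
      error = function(e) {
        stop("catalogue row ", i, " (", path, "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  entries
}

.split_multi <- function(x) {
  if (is.null(x) || !nzchar(x)) character(0) else
    strsplit(x, ";", fixed = TRUE)[[1L]]
}

.entry_from_row <- function(row, contexts) {
  intron_index <- if (nzchar(row$intron_index %||% "")) {
    as.integer(row$intron_index)
  } else if (nzchar(row$pe_id)) {
    ## recoverable from the GENE-intron-number[letter] scheme
    as.integer(regmatches(row$pe_id,
                          regexec("-(\\d+)-\\d+[a-z]?$", row$pe_id))[[1L]][2L])
  } else {
    stop("neither intron_index nor a parseable pe_id present", call. = FALSE)
  }
  record <- pseudoexon_record(
    pe_id = if (nzchar(row$pe_id)) row$pe_id else NA_character_,
    gene = row$gene,
    transcript = if (nzchar(row$transcript %||% "")) row$transcript else NA_character_,
    chrom = row$chrom, strand = row$strand,
    intron_index = intron_index,
    pe_start = as.integer(row$pe_start), pe_end = as.integer(row$pe_end),
    acceptor_dinuc = row$acceptor_dinuc, donor_dinuc = row$donor_dinuc,
    is_terminal = row$is_terminal == "1",
    polya_confirmed = row$polya_confirmed == "1",
    splice_evidence_acceptor = row$splice_evidence_acceptor == "1",
    splice_evidence_donor = row$splice_evidence_donor == "1",
    cell_types = .split_multi(row$cell_types),
    citations = .split_multi(row$citations)
  )
  ctx <- if (!is.null(contexts)) contexts[[row$gene]] else NULL
  mutations <- lapply(.split_multi(row$mutations), function(m) {
    v <- parse_cdna_variant(m)
    if (!is.null(ctx)) resolve_mutation(v, ctx) else
      instigating_mutation(v$hgvs, v$kind,
                           ref_allele = if (v$kind == "SNV") v$ref else "",
                           alt_allele = if (v$kind == "SNV") v$alt else "",
                           size = v$size)
  })
  category <- if (nzchar(row$category %||% "")) {
    structure(list(category = row$category, subcategory = NA_character_,
                   evidence = list(), negligible_motif_effect = FALSE),
              class = "pe_classification")
  } else NULL
  catalogue_entry(record, mutations, category)
}

#' Write a pseudoexon catalogue to TSV
#'
#' Inverse of [read_catalogue()]: `read_catalogue(write_catalogue(x, p))`
#' reproduces the entries field-for-field.
#'
#' @param entries list of [catalogue_entry()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(entries, path) {
  rows <- vapply(entries, function(e) {
    r <- e$record
    paste(c(
      r$pe_id %|na|% "", r$gene, r$transcript %|na|% "", r$chrom, r$strand,
      r$intron_index, r$pe_start, r$pe_end, r$acceptor_dinuc, r$donor_dinuc,
      paste(Filter(nzchar, vapply(e$mutations,
                                  function(m) m$hgvs_cdna %|na|% "", "")),
            collapse = ";"),
      as.integer(r$splice_evidence_acceptor),
      as.integer(r$splice_evidence_donor),
      as.integer(r$is_terminal), as.integer(r$polya_confirmed),
      as.integer(pe_length(r) %% 3L == 0L),
      if (is.null(e$category)) "" else e$category$category,
      paste(r$cell_types, collapse = ";"),
      paste(r$citations, collapse = ";")
    ), collapse = "\t")
  }, "")
  writeLines(c(paste0("#", paste(CATALOGUE_COLUMNS, collapse = "\t")), rows),
             path)
  invisible(path)
}

`%|na|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

#' Assign unique pseudoexon IDs
#'
#' IDs follow `GENE-intron-number[letter]`: pseudoexons in the same gene and
#' intron that share an acceptor or donor genomic position share a number and
#' are distinguished by letters (`a`, `b`, ...; a previously unlettered
#' sharer gains `a`); otherwise the next free number is used with no letter.
#' Deterministic given insertion order, and idempotent: records whose IDs
#' already follow the scheme are left unchanged.
#'
#' @param records list of [pseudoexon_record()] in insertion order, all from
#'   the same gene and intron for [assign_pe_id()]; [assign_pe_ids()] groups
#'   by gene and intron itself.
#' @return for `assign_pe_ids`, the list of records with `pe_id` set; for
#'   `assign_pe_id`, the new record's ID (with an attribute `renames` naming
#'   any existing record whose ID must gain a letter).
#' @export
assign_pe_ids <- function(records) {
  key <- vapply(records, function(r) {
    if (r$intron_index < 1L) stop("intron_index must be >= 1", call. = FALSE)
    paste(r$gene, r$intron_index, sep = "\r")
  }, "")
  for (k in unique(key)) {
    idx <- which(key == k)
    groups <- list()  # per number: integer vector of record indices
    for (i in idx) {
      r <- records[[i]]
      b <- pe_boundaries(r)
      placed <- FALSE
      for (gi in seq_along(groups)) {
        shared <- any(vapply(groups[[gi]], function(j) {
          any(pe_boundaries(records[[j]]) %in% b)
        }, TRUE))
        if (shared) {
          groups[[gi]] <- c(groups[[gi]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- i
    }
    for (gi in seq_along(groups)) {
      members <- groups[[gi]]
      for (m in seq_along(members)) {
        r <- records[[members[m]]]
        letter <- if (length(members) == 1L) "" else letters[m]
        records[[members[m]]]$pe_id <-
          paste0(r$gene, "-", r$intron_index, "-", gi, letter)
      }
    }
  }
  records
}

#' @rdname assign_pe_ids
#' @param gene gene symbol.
#' @param intron_index 1-based intron number.
#' @param new_record the record to be IDed.
#' @param existing previously IDed records in the same gene and intron.
#' @export
assign_pe_id <- function(gene, intron_index, new_record, existing = list()) {
  if (as.integer(intron_index) < 1L) {
    stop("intron_index must be >= 1", call. = FALSE)
  }
  b <- pe_boundaries(new_record)
  parse_num <- function(id) {
    m <- regmatches(id, regexec("-(\\d+)([a-z]?)$", id))[[1L]]
    list(num = as.integer(m[2L]), letter = m[3L])
  }
  renames <- character(0)
  sharer <- NULL
  for (r in existing) {
    if (any(pe_boundaries(r) %in% b)) {
      sharer <- r
      break
    }
  }
  if (!is.null(sharer)) {
    info <- parse_num(sharer$pe_id)
    group <- Filter(function(r) parse_num(r$pe_id)$num == info$num, existing)
    used <- vapply(group, function(r) parse_num(r$pe_id)$letter, "")
    if (all(used == "")) {
      renames <- stats::setNames(paste0(sharer$pe_id, "a"), sharer$pe_id)
      next_letter <- "b"
    } else {
      next_letter <- letters[max(match(used[used != ""], letters)) + 1L]
    }
    id <- paste0(gene, "-", intron_index, "-", info$num, next_letter)
  } else {
    nums <- vapply(existing, function(r) parse_num(r$pe_id)$num, 1L)
    id <- paste0(gene, "-", intron_index, "-",
                 if (length(nums)) max(nums) + 1L else 1L)
  }
  attr(id, "renames") <- renames
  id
}

#' Validate a pseudoexon against its gene's canonical exons
#'
#' A pseudoexon must not overlap, adjoin, or duplicate any sense-strand
#' canonical exon sequence. "Adjoin" means sharing a boundary coordinate with
#' a canonical exon; antisense overlap is permitted. The duplication check
#' compares the full pseudoexon sequence with each full exon sequence and is
#' skipped (with a warning) when no sequence is available.
#'
#' @param record a [pseudoexon_record()].
#' @param context the host [gene_context()].
#' @param sequences optional named character vector of chromosome sequences.
#' @return character vector of violations (empty = valid).
#' @export
validate_pseudoexon <- function(record, context, sequences = NULL) {
  if (record$chrom != context$chrom) {
    stop("record and context are on different chromosomes", call. = FALSE)
  }
  violations <- character(0)
  if (record$strand == context$strand) {
    pe <- IRanges::IRanges(start = record$pe_start + 1L, end = record$pe_end)
    ex <- IRanges::IRanges(start = context$exons$start + 1L,
                           end = context$exons$end)
    hits <- IRanges::findOverlaps(pe, ex, maxgap = 0L)
    for (h in S4Vectors_subjectHits(hits)) {
      ov <- IRanges::width(IRanges::pintersect(pe, ex[h])) > 0L
      violations <- c(violations, sprintf(
        "%s sense-strand canonical exon %d [%d,%d)",
        if (ov) "overlaps" else "adjoins",
        h, context$exons$start[h], context$exons$end[h]
      ))
    }
  }
  if (is.null(sequences) || is.null(sequences[[record$chrom]])) {
    warning("no sequence available; exon-duplication check skipped for ",
            record$pe_id %|na|% "unnamed record", call. = FALSE)
  } else {
    chrseq <- sequences[[record$chrom]]
    pe_seq <- seq_sub(chrseq, record$pe_start, record$pe_end)
    if (record$strand == "-") pe_seq <- revcomp(pe_seq)
    for (i in seq_len(nrow(context$exons))) {
      exon_seq <- seq_sub(chrseq, context$exons$start[i], context$exons$end[i])
      if (context$strand == "-") exon_seq <- revcomp(exon_seq)
      if (identical(pe_seq, exon_seq)) {
        violations <- c(violations,
                        sprintf("duplicates canonical exon %d sequence", i))
      }
    }
  }
  violations
}

## minimal accessor so we do not need to Import S4Vectors for one generic
S4Vectors_subjectHits <- function(hits) {
  as.data.frame(hits)$subjectHits
}
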