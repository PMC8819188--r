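#' Gene context: transcript structure for coordinate mapping
#'
#' A gene context carries the minimal transcript anatomy needed to map HGVS
#' cDNA positions to the genome and to reason about flanking canonical exons:
#' exon intervals in 0-based half-open reference coordinates, the strand, and
#' the offset of the CDS start within the spliced transcript.
#'
#' @param gene_symbol gene symbol, e.g. `"ATM"`.
#' @param transcript_id informational transcript identifier (RefSeq-style).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of exon `start`/`end`
#'   (0-based half-open, reference strand), ordered 5'->3' in *transcript*
#'   order (descending genomic coordinates for `-` strand genes).
#' @param cds_start_offset 0-based offset of the first CDS base within the
#'   spliced transcript.
#' @param polyadenylation_sites integer vector of genomic positions (may be
#'   empty).
#' @return an object of class `pe_gene_context`.
#' @export
gene_context <- function(gene_symbol, transcript_id = NA_character_, chrom,
                         strand = c("+", "-"), exons, cds_start_offset = 0L,
                         polyadenylation_sites = integer(0)) {
  strand <- match.arg(strand)
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) {
    stop("every exon interval must have start < end", call. = FALSE)
  }
  ## transcript order: ascending genomic for +, descending for -
  g <- if (strand == "+") exons$start else -exons$start
  if (is.unsorted(g, strictly = TRUE)) {
    stop("exons must be sorted 5'->3' in transcript order", call. = FALSE)
  }
  o <- order(exons$start)
  if (any(exons$end[o][-nrow(exons)] > exons$start[o][-1L])) {
    stop("exons must be non-overlapping", call. = FALSE)
  }
  structure(
    list(
      gene_symbol = gene_symbol,
      transcript_id = transcript_id,
      chrom = chrom,
      strand = strand,
      exons = exons,
      cds_start_offset = as.integer(cds_start_offset),
      polyadenylation_sites = as.integer(polyadenylation_sites)
    ),
    class = "pe_gene_context"
  )
}

#' @export
print.pe_gene_context <- function(x, ...) {
  cat(sprintf(
    "<pe_gene_context> %s (%s) %s%s, %d exon(s), CDS offset %d\n",
    x$gene_symbol, x$transcript_id, x$chrom, x$strand, nrow(x$exons),
    x$cds_start_offset
  ))
  invisible(x)
}

## total spliced transcript length
transcript_length <- function(context) {
  sum(context$exons$end - context$exons$start)
}

#' Write gene contexts to a JSON file
#'
#' @param contexts a list of [gene_context()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_contexts <- function(contexts, path) {
  payload <- lapply(contexts, function(ctx) {
    list(
      gene_symbol = ctx$gene_symbol,
      transcript_id = ctx$transcript_id,
      chrom = ctx$chrom,
      strand = ctx$strand,
      exons = ctx$exons,
      cds_start_offset = ctx$cds_start_offset,
      polyadenylation_sites = ctx$polyadenylation_sites
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read gene contexts from a JSON file
#'
#' @param path file written by [write_gene_contexts()].
#' @return named list of [gene_context()] objects (names are gene symbols).
#' @export
read_gene_contexts <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  contexts <- lapply(payload, function(p) {
    exons <- do.call(rbind, lapply(p$exons, function(e) {
      data.frame(start = e$start, end = e$end)
    }))
    gene_context(
      gene_symbol = p$gene_symbol,
      transcript_id = p$transcript_id %||% NA_character_,
      chrom = p$chrom, strand = p$strand, exons = exons,
      cds_start_offset = p$cds_start_offset,
      polyadenylation_sites = unlist(p$polyadenylation_sites) %||% integer(0)
    )
  })
  names(contexts) <- vapply(contexts, function(x) x$gene_symbol, "")
  contexts
}
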