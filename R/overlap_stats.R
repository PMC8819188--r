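## Recursive-splice-site (RSS) overlap and catalogue summary statistics.

#' Recursive splice site
#'
#' @param chrom chromosome name.
#' @param position genomic 0-based coordinate of the exon-intron boundary the
#'   recursive event cleaves.
#' @param kind `"acceptor"`, `"donor"` or `"either"`.
#' @param source dataset label.
#' @return object of class `pe_rss_site`.
#' @export
rss_site <- function(chrom, position, kind = c("either", "acceptor", "donor"),
                     source = "") {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (is.na(position) || position < 0L) {
    stop("RSS position must be a non-negative integer", call. = FALSE)
  }
  structure(list(chrom = chrom, position = position, kind = kind,
                 source = source),
            class = "pe_rss_site")
}

#' Read recursive splice sites from BED-like text
#'
#' Accepts standard BED (chrom, start, end, ...; 0-based half-open; the site
#' position is the interval start) and a 2-column `chrom<TAB>pos` variant.
#' `#`/`track`/`browser` lines are ignored.
#'
#' @param path file path.
#' @param kind site kind applied to every record.
#' @param source dataset label (defaults to the file name).
#' @return list of [rss_site()] objects.
#' @export
read_rss_bed <- function(path, kind = "either", source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) {
      stop("malformed RSS line in ", path, ": '", ln, "'", call. = FALSE)
    }
    rss_site(f[1L], as.integer(f[2L]), kind, source)
  })
}

#' Match pseudoexon splice-site boundaries against recursive splice sites
#'
#' A pseudoexon matches an RSS when one of its boundary coordinates (the
#' genomic base of the acceptor or donor splice boundary) lies within
#' `tolerance` nt of the RSS position and the RSS kind is compatible with
#' that side. Each (pseudoexon, side, source) combination is reported once.
#'
#' @param entries list of [catalogue_entry()] or [pseudoexon_record()]
#'   objects.
#' @param rss list of [rss_site()] objects.
#' @param tolerance maximum |distance| in nt (default 0: exact hits).
#' @return data.frame with `pe_id`, `side`, `rss_source`, `rss_position`,
#'   `distance`, ordered by `pe_id` then `side`.
#' @export
match_rss <- function(entries, rss, tolerance = 0L) {
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L) {
    stop("tolerance must be a non-negative integer", call. = FALSE)
  }
  rows <- list()
  for (entry in entries) {
    rec <- if (inherits(entry, "pe_catalogue_entry")) entry$record else entry
    b <- pe_boundaries(rec)
    for (side in c("acceptor", "donor")) {
      for (site in rss) {
        if (site$chrom != rec$chrom) next
        if (site$kind != "either" && site$kind != side) next
        d <- abs(b[[side]] - site$position)
        if (d <= tolerance) {
          key <- paste(rec$pe_id, side, site$source, sep = "\r")
          if (is.null(rows[[key]])) {
            rows[[key]] <- data.frame(
              pe_id = rec$pe_id, side = side, rss_source = site$source,
              rss_position = site$position, distance = d
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pe_id = character(0), side = character(0),
                      rss_source = character(0), rss_position = integer(0),
                      distance = integer(0)))
  }
  out <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  out[order(out$pe_id, out$side, out$rss_source), , drop = FALSE]
}

## modal consensus base at a window offset, NA when undefined
.consensus_at <- function(site, offset) {
  if (site == "D") {
    cons <- seq_chars("CAGGTAAGT")  # -3..-1 | +1..+6; +7 has no single base
    idx <- if (offset < 0L) offset + 4L else offset + 3L
    if (idx >= 1L && idx <= 9L) cons[idx] else NA_character_
  } else {
    cons <- seq_chars(paste0(strrep("T", 17), "CAG", "GTT"))  # -20..-1 | +1..+3
    idx <- if (offset < 0L) offset + 21L else offset + 20L
    if (idx >= 1L && idx <= 23L) cons[idx] else NA_character_
  }
}

## signed offset of genomic position g from one named site of a record
.offset_from_site <- function(g, rec, site) {
  s <- rec$pe_start
  e <- rec$pe_end
  if (rec$strand == "+") {
    if (site == "D") {
      if (g >= e) g - e + 1L else -(e - g)
    } else {
      if (g >= s) g - s + 1L else -(s - g)
    }
  } else {
    if (site == "D") {
      if (g < s) s - g else -(g - s + 1L)
    } else {
      if (g < e) e - g else -(g - e + 1L)
    }
  }
}

#' Positional histogram of splice-motif SNVs
#'
#' Tallies donor- and acceptor-motif SNVs by motif position (donor -3..+7,
#' acceptor -20..+3) and transcript-strand reference base. SNVs whose
#' alternate allele is not the modal consensus base at their position are
#' additionally counted as "Other" (positions without a single consensus
#' base, e.g. D+7, are never counted there).
#'
#' @param entries list of [catalogue_entry()] objects with categories set
#'   (directly or via `classifications`).
#' @param classifications optional list of [classification()] results
#'   parallel to `entries`.
#' @return list with `histogram` (data.frame `site`, `offset`, `label`,
#'   `ref`, `n`), `other` (count), `total` (motif SNVs tallied).
#' @export
positional_snv_histogram <- function(entries, classifications = NULL) {
  counts <- list()
  other <- 0L
  total <- 0L
  for (k in seq_along(entries)) {
    entry <- entries[[k]]
    cls <- if (!is.null(classifications)) classifications[[k]] else
      entry$category
    if (is.null(cls)) next
    site <- switch(cls$category, DONOR_MOTIF = "D", ACCEPTOR_MOTIF = "A",
                   NULL)
    if (is.null(site)) next
    lims <- if (site == "D") c(-3L, 7L) else c(-20L, 3L)
    rec <- entry$record
    for (m in entry$mutations) {
      if (m$kind != "SNV" || is.na(m$genomic_start)) next
      off <- .offset_from_site(m$genomic_start, rec, site)
      if (off < lims[1L] || off > lims[2L] || off == 0L) next
      ref_t <- if (rec$strand == "-") revcomp(m$ref_allele) else m$ref_allele
      alt_t <- if (rec$strand == "-") revcomp(m$alt_allele) else m$alt_allele
      key <- paste(site, off, ref_t, sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      total <- total + 1L
      cons <- .consensus_at(site, off)
      if (!is.na(cons) && alt_t != cons) other <- other + 1L
    }
  }
  if (length(counts) == 0L) {
    hist <- data.frame(site = character(0), offset = integer(0),
                       label = character(0), ref = character(0),
                       n = integer(0))
  } else {
    parts <- strsplit(names(counts), "\r", fixed = TRUE)
    hist <- data.frame(
      site = vapply(parts, `[`, "", 1L),
      offset = as.integer(vapply(parts, `[`, "", 2L)),
      ref = vapply(parts, `[`, "", 3L),
      n = unlist(counts, use.names = FALSE)
    )
    hist$label <- sprintf("%s%+d", hist$site, hist$offset)
    hist <- hist[order(hist$site, hist$offset, hist$ref),
                 c("site", "offset", "label", "ref", "n")]
    rownames(hist) <- NULL
  }
  list(histogram = hist, other = other, total = total)
}

#' Summarize a pseudoexon catalogue
#'
#' @param entries list of [catalogue_entry()] objects.
#' @param classifications optional list of [classification()] results
#'   parallel to `entries` (otherwise categories stored on the entries are
#'   used; entries without one count as `UNKNOWN`).
#' @return object of class `pe_summary_report` with entry count, category
#'   tally, transition/transversion counts over all SNV mutations, evidence
#'   count/fraction, and pseudoexon length summary.
#' @export
summarize_catalogue <- function(entries, classifications = NULL) {
  cats <- vapply(seq_along(entries), function(k) {
    cls <- if (!is.null(classifications)) classifications[[k]] else
      entries[[k]]$category
    if (is.null(cls)) "UNKNOWN" else cls$category
  }, "")
  tally <- table(factor(cats, levels = MUTATION_CATEGORIES))
  ti <- 0L
  tv <- 0L
  for (entry in entries) {
    for (m in entry$mutations) {
      if (m$kind != "SNV") next
      if (is_transition(m$ref_allele, m$alt_allele)) ti <- ti + 1L else
        tv <- tv + 1L
    }
  }
  evidence <- vapply(entries, function(e) {
    e$record$splice_evidence_acceptor || e$record$splice_evidence_donor
  }, TRUE)
  lens <- vapply(entries, function(e) pe_length(e$record), 1L)
  structure(
    list(n_entries = length(entries),
         tally = stats::setNames(as.integer(tally), MUTATION_CATEGORIES),
         transitions = ti, transversions = tv,
         evidence_count = sum(evidence),
         evidence_fraction = if (length(entries)) mean(evidence) else
           NA_real_,
         size_min = if (length(lens)) min(lens) else NA_integer_,
         size_median = if (length(lens)) stats::median(lens) else NA_real_,
         size_max = if (length(lens)) max(lens) else NA_integer_),
    class = "pe_summary_report"
  )
}

#' @export
print.pe_summary_report <- function(x, ...) {
  cat(sprintf("<pe_summary_report> %d entries, ti:tv %d:%d, evidence %.1f%%\n",
              x$n_entries, x$transitions, x$transversions,
              100 * (x$evidence_fraction %||% NA_real_)))
  nz <- x$tally[x$tally > 0L]
  if (length(nz)) {
    cat(paste0("  ", names(nz), ": ", nz, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

## five headline mechanism groups used for published-count comparison
.category_group <- function(category) {
  switch(category,
    DONOR_MOTIF = "donor",
    ACCEPTOR_MOTIF = "acceptor",
    BRANCHPOINT = "branch_point",
    INTERNAL_ESE_ESS = ,
    INTERNAL_DELETION_JUXTAPOSITION = "internal",
    FLANKING_EXON_DEFINITION_LOSS = ,
    SIBLING_PE_ACTIVATION = ,
    POLYA_LOSS_READTHROUGH = ,
    PROXIMAL_INTRONIC_MOTIF = "distal",
    "unclassified"
  )
}

#' Reproduce the headline statistics of a curated catalogue
#'
#' Runner for reproducing a published catalogue's summary numbers from its
#' TSV export plus optional recursive-splice-site datasets. The inputs
#' (curated catalogue, genome-derived classifications, RSS coordinate lists)
#' are external data supplied by the user; this function only aggregates.
#'
#' @param catalogue_path catalogue TSV (see [read_catalogue()]), with the
#'   `category` column filled.
#' @param rss_paths character vector of RSS BED files.
#' @param contexts optional named list of [gene_context()] objects.
#' @param tolerance RSS match tolerance in nt.
#' @return named list: `n_entries`, `group_tally` (five mechanism groups),
#'   `donor_snvs`, `transitions`, `transversions`, `donor_minus3_snvs`,
#'   `evidence_fraction`, `rss_matches`, `rss_distinct_sites`.
#' @export
reproduce_catalogue_statistics <- function(catalogue_path,
                                           rss_paths = character(0),
                                           contexts = NULL, tolerance = 0L) {
  entries <- read_catalogue(catalogue_path, contexts)
  report <- summarize_catalogue(entries)
  groups <- vapply(seq_along(entries), function(k) {
    cls <- entries[[k]]$category
    .category_group(if (is.null(cls)) "UNKNOWN" else cls$category)
  }, "")
  group_tally <- table(factor(groups, levels = c(
    "donor", "acceptor", "branch_point", "internal", "distal", "unclassified"
  )))
  donor_snvs <- 0L
  donor_minus3 <- 0L
  for (k in seq_along(entries)) {
    entry <- entries[[k]]
    if (is.null(entry$category) ||
        entry$category$category != "DONOR_MOTIF") next
    for (m in entry$mutations) {
      if (m$kind != "SNV") next
      donor_snvs <- donor_snvs + 1L
      if (!is.na(m$genomic_start) &&
          .offset_from_site(m$genomic_start, entry$record, "D") == -3L) {
        donor_minus3 <- donor_minus3 + 1L
      }
    }
  }
  matches <- NULL
  if (length(rss_paths) > 0L) {
    rss <- unlist(lapply(rss_paths, read_rss_bed), recursive = FALSE)
    matches <- match_rss(entries, rss, tolerance)
  }
  list(
    n_entries = report$n_entries,
    group_tally = stats::setNames(as.integer(group_tally),
                                  names(group_tally)),
    donor_snvs = donor_snvs,
    transitions = report$transitions,
    transversions = report$transversions,
    donor_minus3_snvs = donor_minus3,
    evidence_fraction = report$evidence_fraction,
    rss_matches = if (is.null(matches)) NA_integer_ else nrow(matches),
    rss_distinct_sites = if (is.null(matches)) NA_integer_ else
      length(unique(matches$rss_position))
  )
}
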