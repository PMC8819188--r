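## Packaged curated fixtures: the branch-point mutation table ("table1") and
## the recursive-splice-site comparison table ("table2").

#' Path to a packaged fixture file
#'
#' @param filename file name under the package's `extdata` directory, e.g.
#'   `"table2_rss.bed"`; omit to list available files.
#' @return absolute path (or a character vector of file names).
#' @export
fixture_path <- function(filename = NULL) {
  if (is.null(filename)) {
    return(list.files(system.file("extdata", package = "pseudex")))
  }
  p <- system.file("extdata", filename, package = "pseudex")
  if (!nzchar(p)) stop("no packaged fixture named ", filename, call. = FALSE)
  p
}

.read_fixture_tsv <- function(filename) {
  lines <- readLines(fixture_path(filename))
  keep <- !startsWith(lines, "#") | startsWith(lines, "#pe_id")
  lines <- lines[keep & nzchar(lines)]
  cols <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  utils::read.delim(text = paste(lines[-1L], collapse = "\n"),
                    header = FALSE, col.names = cols, sep = "\t",
                    na.strings = c("NA", ""), fill = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load a packaged curated fixture
#'
#' * `"table1"`: the 14 branch-point-category mutations with AG-exclusion
#'   zone lengths and best branch-point scores before/after the mutation,
#'   the moved-closer flag, and the pyrimidine-gain flag (`NA` for
#'   deletions).
#' * `"table2"`: the 8 pseudoexons with normal-tissue splice evidence,
#'   their coordinates (0-based half-open), sizes, instigating mutations,
#'   MaxEnt-style acceptor/donor scores before/after, and which boundary
#'   coincides with a catalogued recursive splice site.
#'
#' @param name `"table1"` or `"table2"`.
#' @return a data.frame (one row per curated record).
#' @export
load_fixtures <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  .read_fixture_tsv(switch(name,
                           table1 = "table1_branchpoint.tsv",
                           table2 = "table2_rss.tsv"))
}

#' Branch-point deltas for the curated table1 mutations
#'
#' Rebuilds one [branchpoint_delta()] per curated branch-point mutation from
#' the printed before/after values. The curated table records the
#' moved-closer outcome rather than raw branch distances, so flagged rows
#' are given a synthetic decreasing distance pair and unflagged rows `NA`
#' distances; the pyrimidine-gain flag is taken from the table directly.
#'
#' @return named list of `pe_branchpoint_delta` objects keyed by `pe_id`.
#' @export
table1_deltas <- function() {
  tab <- load_fixtures("table1")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    mc <- isTRUE(r$moved_closer == 1L)
    d <- branchpoint_delta(
      wt = list(agez = r$agez_before, bps = r$bps_before,
                distance = if (mc) 2L else NA_integer_),
      mut = list(agez = r$agez_after, bps = r$bps_after,
                 distance = if (mc) 1L else NA_integer_)
    )
    d$pyrimidine_gain <- isTRUE(r$pyrimidine_gain == 1L)
    d
  })
  stats::setNames(out, tab$pe_id)
}

#' Pseudoexon records for the curated table2 pseudoexons
#'
#' @return named list of [pseudoexon_record()] objects keyed by `pe_id`.
#' @export
table2_records <- function() {
  tab <- load_fixtures("table2")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    intron <- as.integer(regmatches(
      r$pe_id, regexec("-(\\d+)-\\d+[a-z]?$", r$pe_id))[[1L]][2L])
    pseudoexon_record(
      pe_id = r$pe_id, gene = r$gene, chrom = r$chrom, strand = r$strand,
      intron_index = intron, pe_start = r$pe_start, pe_end = r$pe_end,
      splice_evidence_acceptor = TRUE
    )
  })
  stats::setNames(out, tab$pe_id)
}
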