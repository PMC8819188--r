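test_that("read_rss_bed accepts BED and 2-column forms and skips headers", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "# comment", "browser position chr1",
               "chr1\t100\t101\tsiteA", "chr2\t200"), path)
  rss <- read_rss_bed(path)
  expect_length(rss, 2L)
  expect_equal(rss[[1L]]$chrom, "chr1")
  expect_equal(rss[[1L]]$position, 100L)
  expect_equal(rss[[2L]]$position, 200L)
  expect_equal(rss[[1L]]$source, basename(path))
  bad <- tempfile()
  writeLines("chr1", bad)
  expect_error(read_rss_bed(bad), "malformed")
})

test_that("match_rss hits exact boundary bases with side compatibility", {
  rec <- pseudoexon_record(pe_id = "G1-2-1", gene = "G1", chrom = "chr1",
                           strand = "+", intron_index = 2L,
                           pe_start = 1000L, pe_end = 1100L)
  # + strand: acceptor base 1000, donor base 1099
  hits <- match_rss(list(rec), list(rss_site("chr1", 1000L),
                                    rss_site("chr1", 1099L),
                                    rss_site("chr1", 1050L),
                                    rss_site("chr2", 1000L)))
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$side, c("acceptor", "donor"))
  # kind-restricted sites only match their own side
  only_d <- match_rss(list(rec), list(rss_site("chr1", 1000L,
                                               kind = "donor")))
  expect_equal(nrow(only_d), 0L)
  # minus strand swaps the boundary bases
  mrec <- pseudoexon_record(pe_id = "G1-2-2", gene = "G1", chrom = "chr1",
                            strand = "-", intron_index = 2L,
                            pe_start = 1000L, pe_end = 1100L)
  mhits <- match_rss(list(mrec), list(rss_site("chr1", 1099L)))
  expect_equal(mhits$side, "acceptor")
  expect_error(match_rss(list(rec), list(), tolerance = -1), "non-negative")
})

test_that("raising the tolerance can only add matches (superset property)", {
  recs <- table2_records()
  rss <- read_rss_bed(fixture_path("table2_rss.bed"))
  exact <- match_rss(recs, rss, tolerance = 0L)
  for (tol in c(1L, 5L, 50L)) {
    wider <- match_rss(recs, rss, tolerance = tol)
    key <- function(d) paste(d$pe_id, d$side, d$rss_position)
    expect_true(all(key(exact) %in% key(wider)), info = tol)
    expect_gte(nrow(wider), nrow(exact))
  }
})

test_that("positional SNV histogram tallies motif positions and 'Other'", {
  loc <- make_hand_locus("+")
  mk <- function(p, alt, category) {
    ref <- substr(loc$sense, p + 1L, p + 1L)
    m <- instigating_mutation(NA_character_, "SNV", p, p + 1L, ref, alt)
    catalogue_entry(loc$rec, list(m),
                    category = classification(category,
                                              evidence = list(rule = "x")))
  }
  entries <- list(
    mk(245L, "T", "DONOR_MOTIF"),    # D+6 A>T, alt = consensus
    mk(243L, "C", "DONOR_MOTIF"),    # D+4 A>C, alt != consensus -> Other
    mk(177L, "C", "ACCEPTOR_MOTIF"), # A-3 G>C, consensus
    mk(150L, "C", "BRANCHPOINT")     # not a motif category: ignored
  )
  h <- positional_snv_histogram(entries)
  expect_equal(h$total, 3L)
  expect_equal(h$other, 1L)
  expect_setequal(h$histogram$label, c("D+6", "D+4", "A-3"))
  expect_equal(h$histogram$n, c(1L, 1L, 1L))
  # the reference base is reported on the transcript strand
  mloc <- make_hand_locus("-")
  p <- 245L
  g <- hand_g(mloc, p)
  m <- instigating_mutation(NA_character_, "SNV", g, g + 1L,
                            revcomp(substr(mloc$sense, p + 1L, p + 1L)),
                            revcomp("T"))
  e <- catalogue_entry(mloc$rec, list(m),
                       category = classification("DONOR_MOTIF",
                                                 evidence = list(rule = "x")))
  mh <- positional_snv_histogram(list(e))
  expect_equal(mh$histogram$label, "D+6")
  expect_equal(mh$histogram$ref, "A")
})

test_that("summarize_catalogue reports tallies, ti:tv and evidence", {
  res <- generate_catalogue(sim_params(seed = 21L, n_entries = 40L))
  bc <- batch_classify(res$entries, res$contexts, res$sequences)
  rep <- summarize_catalogue(res$entries, bc$results)
  expect_equal(rep$n_entries, 40L)
  expect_equal(sum(rep$tally), 40L)
  expect_equal(rep$transitions + rep$transversions,
               sum(vapply(res$entries, function(e) {
                 sum(vapply(e$mutations, function(m) m$kind == "SNV", TRUE))
               }, 1L)))
  expect_equal(rep$transitions, sum(res$truth$transition))
  expect_equal(rep$evidence_count,
               sum(vapply(res$entries, function(e) {
                 e$record$splice_evidence_acceptor ||
                   e$record$splice_evidence_donor
               }, TRUE)))
  expect_true(rep$size_min >= 50L && rep$size_max <= 250L)
})

test_that("transition counting is strand-invariant", {
  # reference-strand G>A on a minus-strand gene is transcript C>T: both are
  # transitions, so tallies must not depend on the stored strand
  expect_true(pseudex:::is_transition("G", "A"))
  expect_true(pseudex:::is_transition("C", "T"))
  expect_false(pseudex:::is_transition("G", "T"))
  expect_false(pseudex:::is_transition("A", "C"))
})

test_that("reproduce_catalogue_statistics aggregates a catalogue TSV", {
  stats <- reproduce_catalogue_statistics(
    fixture_path("table2_catalogue.tsv"),
    fixture_path("table2_rss.bed")
  )
  expect_equal(stats$n_entries, 8L)
  expect_equal(stats$rss_matches, 7L)
  expect_equal(stats$rss_distinct_sites, 7L)
  expect_equal(stats$evidence_fraction, 1)
  expect_equal(stats$transitions + stats$transversions, 8L)
  # without RSS files the RSS fields are NA
  no_rss <- reproduce_catalogue_statistics(
    fixture_path("table2_catalogue.tsv"))
  expect_true(is.na(no_rss$rss_matches))
})
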