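test_that("pseudoexon_record validates its inputs", {
  r <- pseudoexon_record(pe_id = "ATM-27-1b", gene = "ATM", chrom = "chr11",
                         strand = "+", intron_index = 27L,
                         pe_start = 108287409L, pe_end = 108287521L)
  expect_s3_class(r, "pe_record")
  expect_equal(r$pe_end - r$pe_start, 112L)
  expect_error(pseudoexon_record(gene = "X", chrom = "1", strand = "+",
                                 intron_index = 1L, pe_start = 10L,
                                 pe_end = 10L),
               "empty or inverted")
  expect_error(pseudoexon_record(pe_id = "bad id", gene = "X", chrom = "1",
                                 strand = "+", intron_index = 1L,
                                 pe_start = 1L, pe_end = 5L),
               "malformed pe_id")
  expect_error(pseudoexon_record(pe_id = "X-0-1", gene = "X", chrom = "1",
                                 strand = "+", intron_index = 0L,
                                 pe_start = 1L, pe_end = 5L),
               "intron_index")
})

test_that("pe_id scheme accepts published-style identifiers", {
  ok <- c("ATM-27-1b", "COL4A5-29-1", "F8-13-2a", "RPGRIP1-12-1a",
          "DMD-26-2", "PTS-2-1b")
  for (id in ok) {
    expect_silent(pseudoexon_record(pe_id = id, gene = "G", chrom = "1",
                                    strand = "+", intron_index = 1L,
                                    pe_start = 0L, pe_end = 10L))
  }
})

test_that("assign_pe_ids shares numbers between boundary-sharing records", {
  mk <- function(s, e) {
    pseudoexon_record(gene = "GENE1", chrom = "chr1", strand = "+",
                      intron_index = 4L, pe_start = s, pe_end = e)
  }
  recs <- assign_pe_ids(list(mk(100L, 160L), mk(100L, 130L), mk(500L, 590L)))
  ids <- vapply(recs, function(r) r$pe_id, "")
  expect_equal(ids, c("GENE1-4-1a", "GENE1-4-1b", "GENE1-4-2"))
})

test_that("assign_pe_id renames a previously unlettered sharer", {
  a <- pseudoexon_record(pe_id = "GENE1-2-1", gene = "GENE1", chrom = "chr1",
                         strand = "+", intron_index = 2L,
                         pe_start = 50L, pe_end = 90L)
  newr <- pseudoexon_record(gene = "GENE1", chrom = "chr1", strand = "+",
                            intron_index = 2L, pe_start = 50L, pe_end = 75L)
  id <- assign_pe_id("GENE1", 2L, newr, list(a))
  expect_equal(as.character(id), "GENE1-2-1b")
  expect_equal(attr(id, "renames"), c("GENE1-2-1" = "GENE1-2-1a"))
  lone <- pseudoexon_record(gene = "GENE1", chrom = "chr1", strand = "+",
                            intron_index = 2L, pe_start = 300L, pe_end = 390L)
  id2 <- assign_pe_id("GENE1", 2L, lone, list(a))
  expect_equal(as.character(id2), "GENE1-2-2")
})

test_that("validate_pseudoexon flags overlap, adjacency and duplication", {
  loc <- make_hand_locus("+")
  expect_length(validate_pseudoexon(loc$rec, loc$ctx, loc$seqs), 0L)
  overlapping <- pseudoexon_record(gene = "HANDG", chrom = "chrH",
                                   strand = "+", intron_index = 1L,
                                   pe_start = 70L, pe_end = 120L)
  expect_gt(length(validate_pseudoexon(overlapping, loc$ctx, loc$seqs)), 0L)
  adjoining <- pseudoexon_record(gene = "HANDG", chrom = "chrH",
                                 strand = "+", intron_index = 1L,
                                 pe_start = 80L, pe_end = 140L)
  expect_gt(length(validate_pseudoexon(adjoining, loc$ctx, loc$seqs)), 0L)
  expect_warning(validate_pseudoexon(loc$rec, loc$ctx),
                 "sequence")
})

test_that("catalogue TSV writing and reading round-trips", {
  loc <- make_hand_locus("+")
  m <- resolve_mutation("c.60+166A>G", loc$ctx)
  rec <- loc$rec
  rec$splice_evidence_acceptor <- TRUE
  rec$cell_types <- c("fibroblast", "blood")
  rec$citations <- "PMID:1"
  entry <- catalogue_entry(rec, list(m))
  path <- tempfile(fileext = ".tsv")
  write_catalogue(list(entry), path)
  back <- read_catalogue(path, contexts = list(HANDG = loc$ctx))
  expect_length(back, 1L)
  b <- back[[1L]]
  expect_equal(b$record$pe_id, rec$pe_id)
  expect_equal(b$record$pe_start, rec$pe_start)
  expect_equal(b$record$cell_types, rec$cell_types)
  expect_true(b$record$splice_evidence_acceptor)
  expect_equal(b$mutations[[1L]]$hgvs_cdna, m$hgvs_cdna)
  expect_equal(b$mutations[[1L]]$genomic_start, m$genomic_start)
})

test_that("mutations without a cDNA form are written as empty, not 'NA'", {
  loc <- make_hand_locus("+")
  m <- instigating_mutation(NA_character_, "deletion", 380L, 395L, size = 15L)
  path <- tempfile(fileext = ".tsv")
  write_catalogue(list(catalogue_entry(loc$rec, list(m))), path)
  line <- readLines(path)[2L]
  expect_false(grepl("NA", strsplit(line, "\t")[[1L]][11L]))
  back <- read_catalogue(path)
  expect_length(back[[1L]]$mutations, 0L)
})

test_that("gene_context validates exon geometry and round-trips JSON", {
  expect_error(gene_context("G", chrom = "1", strand = "+",
                            exons = data.frame(start = 10, end = 5)),
               "start < end")
  expect_error(gene_context("G", chrom = "1", strand = "-",
                            exons = data.frame(start = c(10, 100),
                                               end = c(50, 200))),
               "transcript order")
  loc <- make_hand_locus("-")
  path <- tempfile(fileext = ".json")
  write_gene_contexts(list(loc$ctx), path)
  back <- read_gene_contexts(path)
  expect_equal(back$HANDG$exons, loc$ctx$exons)
  expect_equal(back$HANDG$strand, "-")
  expect_equal(back$HANDG$polyadenylation_sites,
               loc$ctx$polyadenylation_sites)
})
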