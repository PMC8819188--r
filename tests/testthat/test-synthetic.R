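test_that("sim_params validates its inputs", {
  p <- sim_params(seed = 7L)
  expect_s3_class(p, "pe_sim_params")
  expect_equal(p$p_transition, 165 / 257)
  expect_error(sim_params(seed = -1L), "seed")
  expect_error(sim_params(seed = 1L, evidence_rate = 1.5), "evidence_rate")
  expect_error(sim_params(seed = 1L, category_mix = c(NOT_A_CATEGORY = 1)),
               "category")
  expect_error(sim_params(seed = 1L,
                          category_mix = c(DONOR_MOTIF = 0)), "positive")
})

test_that("catalogue generation is deterministic in the seed", {
  p <- sim_params(seed = 99L, n_entries = 12L)
  a <- generate_catalogue(p)
  b <- generate_catalogue(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sequences, b$sequences)
  expect_identical(
    lapply(a$entries, function(e) e$mutations),
    lapply(b$entries, function(e) e$mutations)
  )
  c <- generate_catalogue(sim_params(seed = 100L, n_entries = 12L))
  expect_false(identical(a$sequences, c$sequences))
})

test_that("generated records validate cleanly and respect size bounds", {
  res <- generate_catalogue(sim_params(seed = 5L, n_entries = 25L))
  for (e in res$entries) {
    ctx <- res$contexts[[e$record$gene]]
    expect_length(validate_pseudoexon(e$record, ctx, res$sequences), 0L)
    len <- pe_length(e$record)
    expect_true(len >= 50L && len <= 250L)
    # the latent site pair is real: AG acceptor / GT donor on the transcript
    b <- pe_boundaries(e$record)
    chrom <- res$sequences[[e$record$chrom]]
    if (e$record$strand == "+") {
      expect_equal(substr(chrom, b[["acceptor"]] - 1L, b[["acceptor"]]), "AG")
      expect_equal(substr(chrom, b[["donor"]] + 2L, b[["donor"]] + 3L), "GT")
    } else {
      expect_equal(substr(chrom, b[["acceptor"]] + 2L, b[["acceptor"]] + 3L),
                   "CT")
      expect_equal(substr(chrom, b[["donor"]] - 1L, b[["donor"]]), "AC")
    }
  }
})

test_that("generator summary statistics sit within 3-sigma of their targets", {
  n <- 300L
  res <- generate_catalogue(sim_params(seed = 1234L, n_entries = n))
  p <- res$params
  mix <- p$category_mix / sum(p$category_mix)
  counts <- table(factor(res$truth$true_category, levels = names(mix)))
  for (cat in names(mix)) {
    expect_lt(abs(counts[[cat]] - n * mix[[cat]]),
              3 * sqrt(n * mix[[cat]] * (1 - mix[[cat]])) + 1e-9)
  }
  p_ti <- p$p_transition
  expect_lt(abs(sum(res$truth$transition) - n * p_ti),
            3 * sqrt(n * p_ti * (1 - p_ti)))
  ev <- sum(vapply(res$entries,
                   function(e) e$record$splice_evidence_acceptor, TRUE))
  p_ev <- p$evidence_rate
  expect_lt(abs(ev - n * p_ev), 3 * sqrt(n * p_ev * (1 - p_ev)))
})

test_that("generate_catalogue writes a readable on-disk bundle", {
  dir <- tempfile("cat")
  dir.create(dir)
  res <- generate_catalogue(sim_params(seed = 8L, n_entries = 6L), dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("catalogue.tsv", "truth.tsv", "contexts.json", "sequences.fa")))))
  entries <- read_catalogue(file.path(dir, "catalogue.tsv"))
  expect_length(entries, 6L)
  expect_identical(
    vapply(entries, function(e) e$record$pe_id, ""),
    vapply(res$entries, function(e) e$record$pe_id, "")
  )
  ctx <- read_gene_contexts(file.path(dir, "contexts.json"))
  expect_setequal(names(ctx), res$truth$gene)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sequences.fa"))
  expect_setequal(names(fa), names(res$sequences))
  expect_equal(as.character(fa[[res$truth$chrom[1L]]]),
               res$sequences[[res$truth$chrom[1L]]])
  truth <- read.delim(file.path(dir, "truth.tsv"), comment.char = "")
  expect_equal(nrow(truth), 6L)
})

test_that("explicit pseudoexon placement is honoured and bounded", {
  p <- sim_params(seed = 3L)
  loc <- generate_locus(p, seed = 11L, pe_offset = 620L)
  expect_s3_class(loc, "pe_locus")
  expect_error(generate_locus(p, seed = 11L, pe_offset = 10L), "pe_offset")
  sib <- generate_locus(p, seed = 12L, with_sibling = TRUE)
  expect_false(is.null(sib$sibling_record))
  # the sibling shares the intron but never overlaps the main pseudoexon
  expect_identical(sib$sibling_record$chrom, sib$record$chrom)
  expect_true(sib$sibling_record$pe_start >= sib$record$pe_end ||
                sib$sibling_record$pe_end <= sib$record$pe_start)
})

test_that("every category implant classifies back to its truth label", {
  p <- sim_params(seed = 77L)
  # the juxtaposing deletion (> large-deletion threshold) only fits in a
  # long intron with the pseudoexon placed early
  p_long <- sim_params(seed = 77L, intron_length_range = c(12000L, 13000L))
  cats <- c("DONOR_MOTIF", "ACCEPTOR_MOTIF", "BRANCHPOINT",
            "INTERNAL_ESE_ESS", "FLANKING_EXON_DEFINITION_LOSS",
            "PROXIMAL_INTRONIC_MOTIF", "POLYA_LOSS_READTHROUGH",
            "INTERNAL_DELETION_JUXTAPOSITION", "SIBLING_PE_ACTIVATION")
  for (cat in cats) {
    sib <- cat == "SIBLING_PE_ACTIVATION"
    juxta <- cat == "INTERNAL_DELETION_JUXTAPOSITION"
    loc <- generate_locus(if (juxta) p_long else p,
                          seed = 500L + match(cat, cats),
                          with_sibling = sib,
                          pe_offset = if (juxta) 620L else NULL)
    imp <- implant_mutation(loc, cat)
    cls <- classify_mutation(
      catalogue_entry(loc$record, list(imp$mutation)),
      loc$context, stats::setNames(list(loc$sequence), loc$record$chrom),
      siblings = if (sib) list(loc$sibling_record) else list()
    )
    expect_equal(cls$category, cat, info = cat)
  }
})
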