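test_that("additive motif scores equal a brute-force position sum", {
  m <- toy_donor_model()
  set.seed(1)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
               collapse = "")
    expected <- sum(vapply(1:9, function(j) {
      m$weights[j, substr(w, j, j)]
    }, 0))
    expect_equal(score_donor(w, m), expected)
  }
  expect_equal(score_donor("CAGGTAAGT", m), 9)  # consensus
  expect_equal(score_acceptor(paste0(strrep("T", 17), "CAG", "GTT"),
                              toy_acceptor_model()), 23)
  expect_error(score_donor("CAGGT", m), "9")
  expect_error(score_acceptor("CAGGTAAGT", toy_acceptor_model()),
               "acceptor")
})

test_that("delta_site_score equals independent rescoring of the window", {
  m <- toy_donor_model()
  wt <- "CAGGTAAGA"
  d <- delta_site_score(wt, list(at = 9L, ref = "A", alt = "T"), m)
  expect_equal(d$before, score_donor(wt, m))
  expect_equal(d$after, score_donor("CAGGTAAGT", m))
  expect_equal(d$delta, d$after - d$before)
  expect_equal(d$delta, 2)
  expect_false(d$window_destroyed)
  expect_error(delta_site_score(wt, list(at = 9L, ref = "C", alt = "T"), m),
               "mismatch")
  # a deletion inside the window leaves no scoreable 9-mer
  broke <- delta_site_score(wt, list(at = 4L, kind = "deletion", size = 2L), m)
  expect_true(broke$window_destroyed)
  expect_equal(broke$delta, 0)
})

test_that("find_candidate_sites matches a brute-force scan", {
  m <- toy_donor_model()
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  got <- find_candidate_sites(seq, m, "donor", threshold = -3)
  # oracle: every 9-window with GT at +1..+2 scoring >= threshold
  starts <- 0:(nchar(seq) - 9L)
  wins <- substring(seq, starts + 1L, starts + 9L)
  keep <- substr(wins, 4L, 5L) == "GT" &
    vapply(wins, function(w) score_motif(m, w), 0) >= -3
  expect_equal(got$position, starts[keep] + 3L)
  expect_equal(got$window_seq, unname(wins[keep]))
  # GC donors only when allowed
  gc_seq <- paste0("AAA", "CAGGCAAGT", "AAA")
  expect_equal(nrow(find_candidate_sites(gc_seq, m, "donor", threshold = 0)),
               0L)
  expect_equal(find_candidate_sites(gc_seq, m, "donor", threshold = 0,
                                    allow_gc = TRUE)$position, 6L)
  # acceptor boundary indexing: consensus at a known offset
  acc <- paste0("GG", strrep("T", 17), "CAG", "GTT", "GG")
  hits <- find_candidate_sites(acc, toy_acceptor_model(), "acceptor",
                               threshold = 20)
  expect_equal(hits$position, 22L)
})

test_that("spliceosome_type requires both U12 donor and branch motifs", {
  expect_equal(spliceosome_type("GTATCCTAA", "AAACCTTAATAAA"), "putative_U12")
  expect_equal(spliceosome_type("ATATCCTAA", "AAACCTTTATAAA"), "putative_U12")
  expect_equal(spliceosome_type("GTAAGTAAA", "AAACCTTAATAAA"), "U2")
  expect_equal(spliceosome_type("GTATCCTAA", "AAAAAAAAAAAAA"), "U2")
  expect_error(spliceosome_type("GTATC", "AAA"), "\\+7")
})

test_that("acceptor dinucleotide distance implements the one-nt rule", {
  expect_equal(acceptor_dinuc_distance("AG"), 0L)
  expect_equal(acceptor_dinuc_distance("AC"), 1L)
  expect_equal(acceptor_dinuc_distance("TG"), 1L)
  expect_equal(acceptor_dinuc_distance("CC"), 2L)
  expect_error(acceptor_dinuc_distance("AGG"), "2 nt")
})

test_that("maximum-entropy donor loader reproduces the scoring arithmetic", {
  # synthetic probability table: value = index / 16384
  path <- tempfile()
  probs <- (1:16384) / 16384
  writeLines(format(probs, digits = 12), path)
  m <- read_maxent_donor(path)
  kmer_index <- function(k) {
    v <- match(strsplit(k, "")[[1L]], c("A", "C", "G", "T")) - 1L
    sum(v * 4L^((length(v) - 1L):0L)) + 1L
  }
  bgd <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  cons1 <- c(A = 0.004, C = 0.0032, G = 0.9896, T = 0.0032)
  cons2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)
  for (w in c("CAGGTAAGT", "AAAGTTTTT", "TTTGTACGT")) {
    b <- strsplit(w, "")[[1L]]
    expected <- log2(cons1[b[4]] * cons2[b[5]] / (bgd[b[4]] * bgd[b[5]]) *
                       probs[kmer_index(paste(b[c(1:3, 6:9)],
                                              collapse = ""))])
    expect_equal(score_donor(w, m), unname(expected))
  }
  expect_error(suppressWarnings(read_maxent_donor(tempfile())),
               "cannot open|No such|such file")
})

test_that("maximum-entropy acceptor loader combines its nine sub-models", {
  dir <- tempfile()
  dir.create(dir)
  ks <- c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L)
  tables <- lapply(seq_along(ks), function(i) {
    v <- (1:(4^ks[i])) / (4^ks[i]) * i
    writeLines(format(v, digits = 12), file.path(dir, paste0("me2x3acc", i)))
    v
  })
  m <- read_maxent_acceptor(dir)
  kmer_index <- function(k) {
    v <- match(strsplit(k, "")[[1L]], c("A", "C", "G", "T")) - 1L
    sum(v * 4L^((length(v) - 1L):0L)) + 1L
  }
  bgd <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  cons1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.003)
  cons2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.003)
  w <- paste0(strrep("T", 10), "CTCTCTTC", "AG", "GTT")
  b <- strsplit(w, "")[[1L]]
  rest <- b[c(1:18, 21:23)]
  num_idx <- list(1:7, 8:14, 15:21, 5:11, 12:18)
  den_idx <- list(5:7, 8:11, 12:14, 15:18)
  p_num <- prod(vapply(1:5, function(i) {
    tables[[i]][kmer_index(paste(rest[num_idx[[i]]], collapse = ""))]
  }, 0))
  p_den <- prod(vapply(1:4, function(i) {
    tables[[i + 5L]][kmer_index(paste(rest[den_idx[[i]]], collapse = ""))]
  }, 0))
  expected <- log2(cons1[b[19]] * cons2[b[20]] / (bgd[b[19]] * bgd[b[20]]) *
                     p_num / p_den)
  expect_equal(score_acceptor(w, m), unname(expected))
})

test_that("motif models load from plain-text weight tables", {
  path <- tempfile()
  writeLines(c("# donor weights", "+1\tG\t2.5", "+2\tT\t1.5", "-1\tG\t0.5"),
             path)
  m <- read_motif_model(path, "donor")
  expect_equal(score_donor("AAGGTAAAA", m), 2.5 + 1.5 + 0.5)
  expect_equal(score_donor("AAAAAAAAA", m), 0)
  bad <- tempfile()
  writeLines("+99\tG\t1", bad)
  expect_error(read_motif_model(bad, "donor"), "unknown position")
})
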