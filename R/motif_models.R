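## Pluggable splice-motif models under a log-odds (bits) contract.
##
## Two families are supported: additive position-weight models (packaged toy
## and zero models; arbitrary tables loadable from plain text) and
## maximum-entropy models loaded verbatim from the published table layout
## (user-supplied; not redistributed here). The donor window spans positions
## -3..-1 (exonic) and +1..+6 (intronic), 9 nt; the +7 purine bias is handled
## downstream as a separate boolean check rather than by widening the window.
## The acceptor window spans -20..-1 (intronic) and +1..+3 (exonic), 23 nt.

donor_window_labels <- function() c(paste0("-", 3:1), paste0("+", 1:6))
acceptor_window_labels <- function() c(paste0("-", 20:1), paste0("+", 1:3))
branch_window_labels <- function() c(paste0("-", 5:1), "A", "+1")

.window_labels <- function(kind) {
  switch(kind,
    donor = donor_window_labels(),
    acceptor = acceptor_window_labels(),
    branch = branch_window_labels(),
    stop("unknown motif kind '", kind, "'", call. = FALSE)
  )
}

#' Construct an additive position-weight motif model
#'
#' Scores are sums of per-position, per-base weights, in bits.
#'
#' @param name model name.
#' @param kind `"donor"` (9-mer), `"acceptor"` (23-mer) or `"branch"`
#'   (7-mer, branch adenosine fixed at position 6).
#' @param weights numeric matrix, one row per window position (rownames =
#'   position labels) and columns `A`, `C`, `G`, `T`.
#' @param provenance free-text provenance note.
#' @return object of class `pe_motif_model`.
#' @export
motif_model <- function(name, kind = c("donor", "acceptor", "branch"),
                        weights, provenance = "user") {
  kind <- match.arg(kind)
  labels <- .window_labels(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != length(labels) ||
      !identical(colnames(weights), DNA_BASES)) {
    stop("weights must be a ", length(labels), " x 4 matrix with columns ",
         "A, C, G, T", call. = FALSE)
  }
  rownames(weights) <- labels
  structure(
    list(name = name, kind = kind, type = "additive", window = labels,
         weights = weights, scorer = NULL, provenance = provenance),
    class = "pe_motif_model"
  )
}

#' @export
print.pe_motif_model <- function(x, ...) {
  cat(sprintf("<pe_motif_model> %s (%s, %s, window %d)\n",
              x$name, x$kind, x$type, length(x$window)))
  invisible(x)
}

window_size <- function(model) length(model$window)

#' Score a window under a motif model
#'
#' @param model a `pe_motif_model`.
#' @param seq DNA string whose length equals the model window.
#' @return score in bits.
#' @export
score_motif <- function(model, seq) {
  assert_dna(seq, "motif window")
  if (nchar(seq) != window_size(model)) {
    stop("window is ", nchar(seq), " nt but the ", model$kind,
         " model expects ", window_size(model), call. = FALSE)
  }
  if (model$type == "additive") {
    bases <- seq_chars(seq)
    sum(model$weights[cbind(seq_along(bases), match(bases, DNA_BASES))])
  } else {
    model$scorer(seq)
  }
}

#' @rdname score_motif
#' @param seq9 a 9-nt donor window (-3..-1 | +1..+6).
#' @export
score_donor <- function(seq9, model) {
  if (model$kind != "donor") stop("not a donor model", call. = FALSE)
  score_motif(model, seq9)
}

#' @rdname score_motif
#' @param seq23 a 23-nt acceptor window (-20..-1 | +1..+3).
#' @export
score_acceptor <- function(seq23, model) {
  if (model$kind != "acceptor") stop("not an acceptor model", call. = FALSE)
  score_motif(model, seq23)
}

#' All-zero calibration model
#'
#' Scores every window 0 bits; downstream, no motif-based category can fire
#' under it, which makes it a convenient null for classifier calibration.
#'
#' @param kind motif kind.
#' @return a `pe_motif_model`.
#' @export
zero_motif_model <- function(kind = c("donor", "acceptor", "branch")) {
  kind <- match.arg(kind)
  labels <- .window_labels(kind)
  w <- matrix(0, nrow = length(labels), ncol = 4,
              dimnames = list(labels, DNA_BASES))
  motif_model(paste0("zero-", kind), kind, w, provenance = "packaged null")
}

## +1 for the consensus base at each position, -1 otherwise
.consensus_model <- function(name, kind, consensus) {
  labels <- .window_labels(kind)
  stopifnot(nchar(consensus) == length(labels))
  w <- matrix(-1, nrow = length(labels), ncol = 4,
              dimnames = list(labels, DNA_BASES))
  cons <- seq_chars(consensus)
  w[cbind(seq_along(cons), match(cons, DNA_BASES))] <- 1
  m <- motif_model(name, kind, w, provenance = "packaged toy model")
  attr(m, "consensus") <- consensus
  m
}

#' Packaged toy models
#'
#' Simple first-order models scoring +1 bits for the consensus base and -1
#' otherwise: donor consensus `CAGGTAAGT`, acceptor consensus of a 17-nt
#' polypyrimidine tract followed by `CAG` and exonic `GTT`, branch consensus
#' `TACTAAC` (branch adenosine at position 6). They exist so the whole
#' pipeline is testable without the published tables; they are not
#' calibrated to human splice sites.
#'
#' @return a `pe_motif_model`.
#' @export
toy_donor_model <- function() .consensus_model("toy-donor", "donor", "CAGGTAAGT")

#' @rdname toy_donor_model
#' @export
toy_acceptor_model <- function() {
  .consensus_model("toy-acceptor", "acceptor",
                   paste0(strrep("T", 17), "CAG", "GTT"))
}

#' @rdname toy_donor_model
#' @export
toy_branch_model <- function() .consensus_model("toy-branch", "branch", "TACTAAC")

#' Read an additive motif model from a plain-text table
#'
#' One line per `(position_label, base, weight)`, tab-separated; lines
#' beginning with `#` are ignored.
#'
#' @param path table file.
#' @param kind motif kind.
#' @param name model name (defaults to the file name).
#' @return a `pe_motif_model`.
#' @export
read_motif_model <- function(path, kind = c("donor", "acceptor", "branch"),
                             name = basename(path)) {
  kind <- match.arg(kind)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("position", "base", "weight"),
                           colClasses = c("character", "character", "numeric"),
                           comment.char = "#")
  labels <- .window_labels(kind)
  w <- matrix(0, nrow = length(labels), ncol = 4,
              dimnames = list(labels, DNA_BASES))
  idx <- cbind(match(tab$position, labels), match(toupper(tab$base), DNA_BASES))
  if (anyNA(idx)) {
    bad <- which(is.na(idx[, 1L]) | is.na(idx[, 2L]))[1L]
    stop("unknown position label or base in line ", bad, " of ", path,
         call. = FALSE)
  }
  w[idx] <- tab$weight
  motif_model(name, kind, w, provenance = path)
}

#' Score change caused by a mutation within a motif window
#'
#' @param wt_window wild-type window sequence.
#' @param mutation either the mutant window string, or a list with `at`
#'   (1-based position within the window), `ref`, `alt` and `kind`
#'   describing a change in window coordinates. SNVs outside the window
#'   leave the score unchanged (`delta = 0`).
#' @param model a `pe_motif_model`.
#' @return list with `before`, `after`, `delta` (bits) and
#'   `window_destroyed` (TRUE when a length-changing mutation leaves no
#'   scoreable window).
#' @export
delta_site_score <- function(wt_window, mutation, model) {
  before <- score_motif(model, wt_window)
  destroyed <- FALSE
  if (is.character(mutation)) {
    mut_window <- mutation
  } else if (is.null(mutation) ||
             is.null(mutation$at) || is.na(mutation$at) ||
             mutation$at < 1L || mutation$at > nchar(wt_window)) {
    mut_window <- wt_window
  } else {
    at <- as.integer(mutation$at)
    kind <- mutation$kind %||% "SNV"
    if (kind == "SNV") {
      if (substr(wt_window, at, at) != mutation$ref) {
        stop("reference allele mismatch at window position ", at,
             call. = FALSE)
      }
      mut_window <- wt_window
      substr(mut_window, at, at) <- mutation$alt
    } else {
      ## indel applied within the window: without flanking sequence the
      ## window cannot be refilled to full length
      span <- mutation$size %||% nchar(mutation$ref %||% "")
      mut_window <- paste0(
        substr(wt_window, 1L, at - 1L),
        mutation$alt %||% "",
        substr(wt_window, at + (if (kind == "insertion") 0L else span),
               nchar(wt_window))
      )
    }
  }
  if (nchar(mut_window) != window_size(model)) {
    destroyed <- TRUE
    after <- before
  } else {
    after <- score_motif(model, mut_window)
  }
  list(before = before, after = after, delta = after - before,
       window_destroyed = destroyed)
}

#' Scan a sequence for candidate splice sites
#'
#' Slides the model window along `seq` and reports every window scoring at or
#' above `threshold`. Unless `dinuc_filter = FALSE`, donor windows must carry
#' GT (or GC when `allow_gc = TRUE`) at +1..+2 and acceptor windows AG at
#' -2..-1. Positions are 0-based offsets of the cleavage boundary within
#' `seq`: the first intronic base for donors, the first exonic base for
#' acceptors.
#'
#' @param seq DNA string (sense strand).
#' @param model a `pe_motif_model` of the matching kind.
#' @param kind `"donor"` or `"acceptor"`.
#' @param threshold minimum score in bits.
#' @param allow_gc accept GC donors.
#' @param dinuc_filter require the canonical dinucleotide.
#' @return data.frame with `position`, `kind`, `score`, `window_seq`,
#'   sorted by position.
#' @export
find_candidate_sites <- function(seq, model, kind = c("donor", "acceptor"),
                                 threshold, allow_gc = FALSE,
                                 dinuc_filter = TRUE) {
  kind <- match.arg(kind)
  assert_dna(seq)
  w <- window_size(model)
  n <- nchar(seq)
  empty <- data.frame(position = integer(0), kind = character(0),
                      score = numeric(0), window_seq = character(0))
  if (n < w) return(empty)
  starts <- 0:(n - w)
  windows <- substring(seq, starts + 1L, starts + w)
  if (dinuc_filter) {
    keep <- if (kind == "donor") {
      d <- substr(windows, 4L, 5L)
      d == "GT" | (allow_gc & d == "GC")
    } else {
      substr(windows, 19L, 20L) == "AG"
    }
    starts <- starts[keep]
    windows <- windows[keep]
  }
  if (length(windows) == 0L) return(empty)
  scores <- vapply(windows, function(x) score_motif(model, x), 0,
                   USE.NAMES = FALSE)
  keep <- scores >= threshold
  boundary <- if (kind == "donor") starts + 3L else starts + 20L
  out <- data.frame(position = boundary[keep], kind = kind,
                    score = scores[keep], window_seq = windows[keep])
  out[order(out$position), , drop = FALSE]
}

#' Spliceosome-type check for a donor site
#'
#' Calls a site `putative_U12` only when the donor matches the minor
#' spliceosome consensus `[AG]TATCCT` at +1..+7 AND the branch region 5' of
#' the partner acceptor contains a U12 branch motif; otherwise `U2`. The
#' branch motif is an IUPAC string, by default `CCTTWAY` (the published
#' CCTTUAY read in DNA with the weakly constrained fifth position tolerated
#' as A or T).
#'
#' @param donor_window DNA covering at least intronic +1..+7 (pass the
#'   intronic side of the donor, 5'->3').
#' @param branch_region DNA of the ~40 nt 5' of the downstream acceptor.
#' @param u12_branch_motif IUPAC pattern for the U12 branch motif.
#' @return `"U2"` or `"putative_U12"`.
#' @export
spliceosome_type <- function(donor_window, branch_region,
                             u12_branch_motif = "CCTTWAY") {
  assert_dna(donor_window, "donor window")
  assert_dna(branch_region, "branch region")
  if (nchar(donor_window) < 7L) {
    stop("donor window must cover intronic +1..+7", call. = FALSE)
  }
  first7 <- substr(donor_window, 1L, 7L)
  donor_hit <- grepl("^[AG]TATCCT$", first7)
  if (!donor_hit) return("U2")
  branch_hit <- nrow(scan_motifs(branch_region, u12_branch_motif)) > 0L
  if (branch_hit) "putative_U12" else "U2"
}

#' Hamming distance of an acceptor dinucleotide from canonical AG
#'
#' Non-canonical acceptors in the human transcriptome tend to differ from AG
#' by a single nucleotide; the one-nucleotide rule flag is `distance <= 1`.
#'
#' @param dinuc 2-letter DNA string.
#' @return integer 0..2.
#' @export
acceptor_dinuc_distance <- function(dinuc) {
  assert_dna(dinuc, "acceptor dinucleotide")
  if (nchar(dinuc) != 2L) stop("dinucleotide must be 2 nt", call. = FALSE)
  sum(seq_chars(dinuc) != c("A", "G"))
}

## ---- maximum-entropy table loaders --------------------------------------

.kmer_index <- function(kmer) {
  ## base-4 index, A=0 C=1 G=2 T=3, first character most significant; 1-based
  vals <- match(seq_chars(kmer), DNA_BASES) - 1L
  sum(vals * 4L^((length(vals) - 1L):0L)) + 1L
}

.read_prob_file <- function(path, k) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != 4L^k) {
    stop(basename(path), " should hold ", 4L^k, " values (one per ", k,
         "-mer), found ", length(v), call. = FALSE)
  }
  v
}

MAXENT_BGD <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
MAXENT_DONOR_CONS1 <- c(A = 0.004, C = 0.0032, G = 0.9896, T = 0.0032)
MAXENT_DONOR_CONS2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)
MAXENT_ACC_CONS1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.003)
MAXENT_ACC_CONS2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.003)

#' Load maximum-entropy splice models from the published table layout
#'
#' `read_maxent_donor()` expects the published donor table (`me2x5`, 16384
#' probabilities indexed over the seven non-consensus window positions);
#' `read_maxent_acceptor()` expects a directory holding `me2x3acc1` ..
#' `me2x3acc9`. Scores are `log2` ratios against the published background
#' composition, combining the table probabilities with the consensus-
#' dinucleotide odds exactly as the published scoring scheme does. The
#' tables themselves are user-supplied inputs and are not shipped with this
#' package.
#'
#' @param path path to the `me2x5` file (or a directory containing it).
#' @return a `pe_motif_model` with a function scorer.
#' @export
read_maxent_donor <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "me2x5")
  probs <- .read_prob_file(path, 7L)
  scorer <- function(seq9) {
    b <- seq_chars(seq9)
    cons <- (MAXENT_DONOR_CONS1[b[4L]] * MAXENT_DONOR_CONS2[b[5L]]) /
      (MAXENT_BGD[b[4L]] * MAXENT_BGD[b[5L]])
    rest <- paste(b[c(1:3, 6:9)], collapse = "")
    unname(log2(cons * probs[.kmer_index(rest)]))
  }
  structure(
    list(name = "maxent-donor", kind = "donor", type = "maxent",
         window = donor_window_labels(), weights = NULL, scorer = scorer,
         provenance = path),
    class = "pe_motif_model"
  )
}

#' @rdname read_maxent_donor
#' @param dir directory holding `me2x3acc1` .. `me2x3acc9`.
#' @export
read_maxent_acceptor <- function(dir) {
  ks <- c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L)
  models <- lapply(1:9, function(i) {
    .read_prob_file(file.path(dir, paste0("me2x3acc", i)), ks[i])
  })
  ## sub-windows of the 21-mer left after removing the consensus AG
  num <- list(1:7, 8:14, 15:21, 5:11, 12:18)
  den <- list(5:7, 8:11, 12:14, 15:18)
  scorer <- function(seq23) {
    b <- seq_chars(seq23)
    cons <- (MAXENT_ACC_CONS1[b[19L]] * MAXENT_ACC_CONS2[b[20L]]) /
      (MAXENT_BGD[b[19L]] * MAXENT_BGD[b[20L]])
    rest <- b[c(1:18, 21:23)]
    p_num <- vapply(seq_along(num), function(i) {
      models[[i]][.kmer_index(paste(rest[num[[i]]], collapse = ""))]
    }, 0)
    p_den <- vapply(seq_along(den), function(i) {
      models[[i + 5L]][.kmer_index(paste(rest[den[[i]]], collapse = ""))]
    }, 0)
    unname(log2(cons * prod(p_num) / prod(p_den)))
  }
  structure(
    list(name = "maxent-acceptor", kind = "acceptor", type = "maxent",
         window = acceptor_window_labels(), weights = NULL, scorer = scorer,
         provenance = dir),
    class = "pe_motif_model"
  )
}
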