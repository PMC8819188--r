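## Mutation-category classifier.
##
## Assigns each (pseudoexon, mutation-set) pair to one mechanism category via
## an ordered decision procedure: splice-motif rules first (donor, acceptor,
## branch point), then internal rules, then rules acting outside the
## pseudoexon. Motif-window mutations whose score change is negligible fall
## through to later rules with a flag.

MUTATION_CATEGORIES <- c(
  "DONOR_MOTIF", "ACCEPTOR_MOTIF", "BRANCHPOINT", "INTERNAL_ESE_ESS",
  "INTERNAL_DELETION_JUXTAPOSITION", "FLANKING_EXON_DEFINITION_LOSS",
  "SIBLING_PE_ACTIVATION", "POLYA_LOSS_READTHROUGH",
  "PROXIMAL_INTRONIC_MOTIF", "UNKNOWN"
)

FLANKING_SUBCATEGORIES <- c("facing_site_loss", "whole_exon_skip",
                            "flanking_ese_loss", "next_but_one")

#' The mutation-category taxonomy
#'
#' @return character vector of category names in decision order.
#' @export
mutation_categories <- function() MUTATION_CATEGORIES

#' Classifier configuration
#'
#' @param epsilon negligible motif-score change, in bits (default 0.5).
#' @param large_deletion_threshold minimum size (nt) for a deletion to count
#'   as internal juxtaposition (default 10 kb).
#' @param proximal_window maximum distance (nt) from the pseudoexon for the
#'   proximal-intronic-motif rule (default 600).
#' @param branch_window branch-point search depth 5' of the acceptor
#'   (default 100 nt).
#' @param agez_scan_limit AG-exclusion-zone scan depth (default 500 nt).
#' @param allow_gc_donors accept GC donors in candidate-site scans.
#' @return object of class `pe_classify_config`.
#' @export
classify_config <- function(epsilon = 0.5, large_deletion_threshold = 10000L,
                            proximal_window = 600L, branch_window = 100L,
                            agez_scan_limit = 500L, allow_gc_donors = FALSE) {
  stopifnot(epsilon >= 0, large_deletion_threshold > 0,
            proximal_window >= 0, branch_window > 0, agez_scan_limit > 0)
  structure(
    list(epsilon = epsilon,
         large_deletion_threshold = as.integer(large_deletion_threshold),
         proximal_window = as.integer(proximal_window),
         branch_window = as.integer(branch_window),
         agez_scan_limit = as.integer(agez_scan_limit),
         allow_gc_donors = isTRUE(allow_gc_donors)),
    class = "pe_classify_config"
  )
}

#' The packaged toy model bundle
#'
#' Donor, acceptor and branch [toy_donor_model()] family models plus the
#' [toy_hexamer_table()], in the list layout [classify_mutation()] expects.
#'
#' @return named list with elements `donor`, `acceptor`, `branch`, `hexamer`.
#' @export
toy_models <- function() {
  list(donor = toy_donor_model(), acceptor = toy_acceptor_model(),
       branch = toy_branch_model(), hexamer = toy_hexamer_table())
}

#' Construct a classification result
#'
#' @param category one of [mutation_categories()].
#' @param subcategory only with `FLANKING_EXON_DEFINITION_LOSS`.
#' @param evidence named list describing the fired rule (must be non-empty
#'   for every category except `UNKNOWN`).
#' @param negligible_motif_effect was a motif-window mutation passed over
#'   because its score change was within epsilon?
#' @return object of class `pe_classification`.
#' @export
classification <- function(category, subcategory = NA_character_,
                           evidence = list(),
                           negligible_motif_effect = FALSE) {
  if (!category %in% MUTATION_CATEGORIES) {
    stop("unknown category '", category, "'", call. = FALSE)
  }
  if (!is.na(subcategory)) {
    if (category != "FLANKING_EXON_DEFINITION_LOSS") {
      stop("subcategory is only valid with FLANKING_EXON_DEFINITION_LOSS",
           call. = FALSE)
    }
    if (!subcategory %in% FLANKING_SUBCATEGORIES) {
      stop("unknown flanking subcategory '", subcategory, "'", call. = FALSE)
    }
  }
  if (category != "UNKNOWN" && length(evidence) == 0L) {
    stop("evidence must be non-empty for category ", category, call. = FALSE)
  }
  structure(
    list(category = category, subcategory = subcategory, evidence = evidence,
         negligible_motif_effect = isTRUE(negligible_motif_effect)),
    class = "pe_classification"
  )
}

#' @export
print.pe_classification <- function(x, ...) {
  cat(sprintf("<pe_classification> %s%s%s\n", x$category,
              if (is.na(x$subcategory)) "" else paste0("/", x$subcategory),
              if (x$negligible_motif_effect) " [negligible motif effect]" else ""))
  invisible(x)
}

## ---- window geometry -----------------------------------------------------

## genomic (0-based) position of the +1 base of a site, for any record-like
## list with pe_start, pe_end, strand
.g_plus1 <- function(rec, site) {
  if (site == "donor") {
    if (rec$strand == "+") rec$pe_end else rec$pe_start - 1L
  } else {
    if (rec$strand == "+") rec$pe_start else rec$pe_end - 1L
  }
}

## genomic half-open span of a full motif window, given the +1 anchor
.span_from_anchor <- function(g1, strand, site) {
  if (site == "donor") {
    if (strand == "+") c(g1 - 3L, g1 + 6L) else c(g1 - 5L, g1 + 4L)
  } else {
    if (strand == "+") c(g1 - 20L, g1 + 3L) else c(g1 - 2L, g1 + 21L)
  }
}

.window_span <- function(rec, site) {
  .span_from_anchor(.g_plus1(rec, site), rec$strand, site)
}

.extract_window <- function(chrseq, span, strand, what) {
  if (span[1L] < 0L || span[2L] > nchar(chrseq)) {
    stop("sequence does not cover the ", what, call. = FALSE)
  }
  w <- seq_sub(chrseq, span[1L], span[2L])
  if (strand == "-") revcomp(w) else w
}

## before/after motif score across a mutation set
.site_delta <- function(chrseq, mutres, rec, site, model) {
  wt <- .extract_window(chrseq, .window_span(rec, site), rec$strand,
                        paste(site, "window"))
  before <- score_motif(model, wt)
  ng1 <- mutres$shift(.g_plus1(rec, site))
  if (is.na(ng1)) {
    return(list(before = before, after = NA_real_, delta = NA_real_,
                destroyed = TRUE))
  }
  mw <- .extract_window(mutres$seq, .span_from_anchor(ng1, rec$strand, site),
                        rec$strand, paste("mutant ", site, " window"))
  after <- score_motif(model, mw)
  list(before = before, after = after, delta = after - before,
       destroyed = FALSE)
}

## AGEZ / best-branch-point state of an acceptor, given the A+1 anchor
.branch_state <- function(seq, a_plus1, strand, model, config) {
  take <- config$agez_scan_limit + 10L
  up <- if (strand == "+") {
    if (a_plus1 - 2L < 0L) stop("sequence does not cover the acceptor AG",
                                call. = FALSE)
    seq_sub(seq, max(0L, a_plus1 - 2L - take), a_plus1 - 2L)
  } else {
    revcomp(seq_sub(seq, a_plus1 + 3L,
                    min(nchar(seq), a_plus1 + 3L + take)))
  }
  agez <- compute_agez(up, config$agez_scan_limit)
  cands <- scan_branchpoints(up, model, config$branch_window)
  list(agez = agez,
       bps = if (nrow(cands) > 0L) cands$score[1L] else NA_real_,
       distance = if (nrow(cands) > 0L) cands$distance_to_acceptor[1L] else
         NA_integer_)
}

## genomic footprint of a mutation; insertions count both flanking bases
.footprint <- function(m) {
  gs <- m$genomic_start
  ge <- m$genomic_end
  if (is.na(gs) || is.na(ge)) {
    stop("mutation genomic coordinates are unresolved", call. = FALSE)
  }
  if (gs == ge) c(gs - 1L, gs + 1L) else c(gs, ge)
}

## full-sequence DeltaHx over a genomic slice, NULL when not computable
.delta_hx_on <- function(chrseq, s, e, strand, muts, table) {
  contained <- Filter(function(m) {
    !is.na(m$genomic_start) && m$genomic_start >= s && m$genomic_end <= e
  }, muts)
  if (length(contained) == 0L) return(NULL)
  tryCatch({
    wt_plus <- seq_sub(chrseq, s, e)
    mr <- mutate_sequence(wt_plus, contained, seq_offset = s)
    wt <- if (strand == "-") revcomp(wt_plus) else wt_plus
    mt <- if (strand == "-") revcomp(mr$seq) else mr$seq
    wt_total <- total_hexamer_score(wt, table)
    mut_total <- total_hexamer_score(mt, table)
    delta <- mut_total - wt_total
    structure(list(wt_total = wt_total, mut_total = mut_total, delta = delta,
                   direction = predict_directionality_value(delta)),
              class = "pe_delta_hx")
  }, error = function(err) NULL)
}

## DGKE-pattern check: a replacement site at least as strong as the lost one
## contradicts the expectation that cryptic replacements score lower
.warn_if_strong_replacement <- function(mutseq, anchor_new, strand, site,
                                        model, before, config) {
  half <- 30L
  lo <- max(0L, anchor_new - half)
  hi <- min(nchar(mutseq), anchor_new + half)
  region <- seq_sub(mutseq, lo, hi)
  if (strand == "-") region <- revcomp(region)
  hits <- tryCatch(
    find_candidate_sites(region, model, site, threshold = before,
                         allow_gc = config$allow_gc_donors),
    error = function(err) NULL
  )
  if (!is.null(hits) && nrow(hits) > 0L) {
    warning("a replacement ", site, " site scores at least the lost ",
            "original (", signif(max(hits$score), 3), " vs ",
            signif(before, 3), " bits)", call. = FALSE)
  }
}

## ---- classifier ----------------------------------------------------------

#' Classify an instigating mutation set
#'
#' Ordered decision procedure:
#' 1. `DONOR_MOTIF`: a mutation within donor positions -3..+6 raising the
#'    donor score by more than epsilon, or a pyrimidine-to-purine SNV at D+7.
#' 2. `ACCEPTOR_MOTIF`: a mutation within A-3..A-1 raising the acceptor score
#'    by more than epsilon.
#' 3. `BRANCHPOINT`: a mutation within the branch search window 5' of the
#'    acceptor for which [branchpoint_delta()] reports an enlarged AGEZ, an
#'    improved branch score, a branch point moved closer, or a pyrimidine
#'    gain.
#' 4. Inside the pseudoexon: a deletion larger than the large-deletion
#'    threshold is `INTERNAL_DELETION_JUXTAPOSITION`; otherwise a non-zero
#'    DeltaHx is `INTERNAL_ESE_ESS`.
#' 5. Outside the pseudoexon: facing canonical splice-site loss, whole-exon
#'    deletion, flanking-exon DeltaHx loss, next-but-one exon mutation
#'    (`FLANKING_EXON_DEFINITION_LOSS` subcategories), sibling pseudoexon
#'    motif creation (`SIBLING_PE_ACTIVATION`), deletion of all transcript
#'    polyadenylation sites (`POLYA_LOSS_READTHROUGH`), then any same-intron
#'    mutation within the proximal window (`PROXIMAL_INTRONIC_MOTIF`).
#' 6. `UNKNOWN`.
#'
#' Motif-window mutations whose absolute score change is within epsilon fall
#' through to later rules with `negligible_motif_effect` set.
#'
#' @param entry a [catalogue_entry()] whose mutations carry resolved genomic
#'   coordinates.
#' @param context the host [gene_context()].
#' @param sequences named list/vector of chromosome sequences.
#' @param models named list with `donor`, `acceptor`, `branch` motif models
#'   and a `hexamer` table (default [toy_models()]).
#' @param config a [classify_config()].
#' @param siblings other catalogued [pseudoexon_record()]s in the same
#'   intron, for the sibling-activation rule.
#' @return a [classification()].
#' @export
classify_mutation <- function(entry, context, sequences,
                              models = toy_models(),
                              config = classify_config(), siblings = list()) {
  stopifnot(inherits(entry, "pe_catalogue_entry"))
  rec <- entry$record
  chrseq <- sequences[[rec$chrom]]
  if (is.null(chrseq)) {
    stop("no sequence available for chromosome ", rec$chrom, call. = FALSE)
  }
  muts <- entry$mutations
  if (length(muts) == 0L) return(classification("UNKNOWN"))
  fps <- lapply(muts, .footprint)
  hits_span <- function(span) {
    any(vapply(fps, function(f) f[1L] < span[2L] && span[1L] < f[2L], TRUE))
  }
  mutres <- mutate_sequence(chrseq, muts)
  label <- format_site_position(relative_to_pe(muts[[1L]]$genomic_start, rec))
  negligible <- FALSE
  s <- rec$pe_start
  e <- rec$pe_end
  plus <- rec$strand == "+"

  ## (1) donor motif, -3..+6
  if (hits_span(.window_span(rec, "donor"))) {
    d <- .site_delta(chrseq, mutres, rec, "donor", models$donor)
    if (!is.na(d$delta) && d$delta > config$epsilon) {
      return(classification("DONOR_MOTIF", evidence = list(
        rule = "donor_motif", position = label, score_before = d$before,
        score_after = d$after, delta = d$delta)))
    }
    if (!is.na(d$delta) && abs(d$delta) <= config$epsilon) negligible <- TRUE
  }
  ## (1b) pyrimidine->purine SNV at D+7
  g_d7 <- if (plus) e + 6L else s - 7L
  for (m in muts) {
    if (m$kind == "SNV" && m$genomic_start == g_d7) {
      ref_t <- if (plus) m$ref_allele else revcomp(m$ref_allele)
      alt_t <- if (plus) m$alt_allele else revcomp(m$alt_allele)
      if (is_pyrimidine(ref_t) && is_purine(alt_t)) {
        return(classification("DONOR_MOTIF", evidence = list(
          rule = "donor_plus7_purine", position = "D+7", ref = ref_t,
          alt = alt_t), negligible_motif_effect = negligible))
      }
    }
  }

  ## (2) acceptor motif, A-3..A-1 only
  acc3 <- if (plus) c(s - 3L, s) else c(e, e + 3L)
  if (hits_span(acc3)) {
    a <- .site_delta(chrseq, mutres, rec, "acceptor", models$acceptor)
    if (!is.na(a$delta) && a$delta > config$epsilon) {
      return(classification("ACCEPTOR_MOTIF", evidence = list(
        rule = "acceptor_motif", position = label, score_before = a$before,
        score_after = a$after, delta = a$delta),
        negligible_motif_effect = negligible))
    }
    if (!is.na(a$delta) && abs(a$delta) <= config$epsilon) negligible <- TRUE
  }

  ## (3) branch search window 5' of the acceptor (A-4 back to A-(3+window))
  bw <- config$branch_window
  br_span <- if (plus) c(s - 3L - bw, s - 3L) else c(e + 3L, e + 3L + bw)
  if (hits_span(br_span)) {
    a1 <- .g_plus1(rec, "acceptor")
    na1 <- mutres$shift(a1)
    if (!is.na(na1)) {
      wt_state <- .branch_state(chrseq, a1, rec$strand, models$branch, config)
      mut_state <- .branch_state(mutres$seq, na1, rec$strand, models$branch,
                                 config)
      muts_s <- lapply(muts, function(m) { m$strand <- rec$strand; m })
      bd <- branchpoint_delta(wt_state, mut_state, muts_s)
      if (circuit_rule(bd) || bd$pyrimidine_gain) {
        return(classification("BRANCHPOINT", evidence = list(
          rule = "branchpoint", position = label,
          agez_before = bd$agez_before, agez_after = bd$agez_after,
          bps_before = bd$bps_before, bps_after = bd$bps_after,
          agez_increased = bd$agez_increased,
          bps_increased = bd$bps_increased, moved_closer = bd$moved_closer,
          pyrimidine_gain = bd$pyrimidine_gain),
          negligible_motif_effect = negligible))
      }
    }
  }

  ## (4) inside the pseudoexon
  if (hits_span(c(s, e))) {
    big <- Filter(function(m) {
      m$kind == "deletion" && !is.na(m$size) &&
        m$size > config$large_deletion_threshold
    }, muts)
    if (length(big) > 0L) {
      return(classification("INTERNAL_DELETION_JUXTAPOSITION",
                            evidence = list(
        rule = "internal_deletion_juxtaposition", position = label,
        deletion_size = big[[1L]]$size),
        negligible_motif_effect = negligible))
    }
    dh <- .delta_hx_on(chrseq, s, e, rec$strand, muts, models$hexamer)
    if (!is.null(dh) && dh$delta != 0) {
      return(classification("INTERNAL_ESE_ESS", evidence = list(
        rule = "internal_ese_ess", position = label, delta_hx = dh$delta,
        direction = dh$direction),
        negligible_motif_effect = negligible))
    }
  }

  ## (5) outside the pseudoexon
  ex <- context$exons
  i <- rec$intron_index
  flank <- list()
  if (i <= nrow(ex)) {
    flank$upstream <- list(pe_start = ex$start[i], pe_end = ex$end[i],
                           strand = context$strand, site = "donor")
  }
  if (i + 1L <= nrow(ex)) {
    flank$downstream <- list(pe_start = ex$start[i + 1L],
                             pe_end = ex$end[i + 1L],
                             strand = context$strand, site = "acceptor")
  }
  ## a deletion removing an entire flanking exon is diagnosed as exon skip,
  ## not as loss of the facing site it necessarily also destroys
  covers_exon <- function(fx) {
    any(vapply(muts, function(m) {
      m$kind == "deletion" && !is.na(m$genomic_start) &&
        m$genomic_start <= fx$pe_start && m$genomic_end >= fx$pe_end
    }, TRUE))
  }
  ## (5a) facing canonical splice-site loss
  for (fx in flank) {
    if (covers_exon(fx)) next
    span <- .window_span(fx, fx$site)
    if (!hits_span(span)) next
    d <- tryCatch(.site_delta(chrseq, mutres, fx, fx$site,
                              models[[fx$site]]),
                  error = function(err) NULL)
    if (is.null(d)) next
    if (d$destroyed || (!is.na(d$delta) && d$delta < -config$epsilon)) {
      ng1 <- mutres$shift(.g_plus1(fx, fx$site))
      if (!is.na(ng1)) {
        .warn_if_strong_replacement(mutres$seq, ng1, fx$strand, fx$site,
                                    models[[fx$site]], d$before, config)
      }
      return(classification("FLANKING_EXON_DEFINITION_LOSS",
                            "facing_site_loss", evidence = list(
        rule = "facing_site_loss", facing_site = fx$site,
        score_before = d$before, score_after = d$after, delta = d$delta,
        site_destroyed = d$destroyed),
        negligible_motif_effect = negligible))
    }
    if (!is.na(d$delta) && abs(d$delta) <= config$epsilon) negligible <- TRUE
  }
  ## (5b) whole flanking exon deleted
  for (fx in flank) {
    for (m in muts) {
      if (m$kind == "deletion" && !is.na(m$genomic_start) &&
          m$genomic_start <= fx$pe_start && m$genomic_end >= fx$pe_end) {
        return(classification("FLANKING_EXON_DEFINITION_LOSS",
                              "whole_exon_skip", evidence = list(
          rule = "whole_exon_skip", deletion_size = m$size),
          negligible_motif_effect = negligible))
      }
    }
  }
  ## (5c) flanking-exon enhancer loss
  for (fx in flank) {
    if (!hits_span(c(fx$pe_start, fx$pe_end))) next
    dh <- .delta_hx_on(chrseq, fx$pe_start, fx$pe_end, fx$strand, muts,
                       models$hexamer)
    if (!is.null(dh) && dh$delta < 0) {
      return(classification("FLANKING_EXON_DEFINITION_LOSS",
                            "flanking_ese_loss", evidence = list(
        rule = "flanking_ese_loss", delta_hx = dh$delta),
        negligible_motif_effect = negligible))
    }
  }
  ## (5d) next-but-one exon
  for (j in c(i - 1L, i + 2L)) {
    if (j < 1L || j > nrow(ex)) next
    if (hits_span(c(ex$start[j], ex$end[j]))) {
      return(classification("FLANKING_EXON_DEFINITION_LOSS", "next_but_one",
                            evidence = list(
        rule = "next_but_one", exon_index = j),
        negligible_motif_effect = negligible))
    }
  }
  ## (5e) sibling pseudoexon activation
  for (sib in siblings) {
    if (hits_span(.window_span(sib, "donor"))) {
      d <- tryCatch(.site_delta(chrseq, mutres, sib, "donor", models$donor),
                    error = function(err) NULL)
      if (!is.null(d) && !is.na(d$delta) && d$delta > config$epsilon) {
        return(classification("SIBLING_PE_ACTIVATION", evidence = list(
          rule = "sibling_donor", sibling = sib$pe_id, delta = d$delta),
          negligible_motif_effect = negligible))
      }
    }
    sib_acc3 <- if (sib$strand == "+") {
      c(sib$pe_start - 3L, sib$pe_start)
    } else {
      c(sib$pe_end, sib$pe_end + 3L)
    }
    if (hits_span(sib_acc3)) {
      d <- tryCatch(.site_delta(chrseq, mutres, sib, "acceptor",
                                models$acceptor),
                    error = function(err) NULL)
      if (!is.null(d) && !is.na(d$delta) && d$delta > config$epsilon) {
        return(classification("SIBLING_PE_ACTIVATION", evidence = list(
          rule = "sibling_acceptor", sibling = sib$pe_id, delta = d$delta),
          negligible_motif_effect = negligible))
      }
    }
  }
  ## (5f) deletion removing all transcript polyadenylation sites
  pa <- context$polyadenylation_sites
  if (length(pa) > 0L) {
    for (m in muts) {
      if (m$kind == "deletion" && !is.na(m$genomic_start) &&
          all(pa >= m$genomic_start & pa < m$genomic_end)) {
        return(classification("POLYA_LOSS_READTHROUGH", evidence = list(
          rule = "polya_loss", deletion_size = m$size,
          sites_removed = length(pa)),
          negligible_motif_effect = negligible))
      }
    }
  }
  ## (5g) proximal intronic motif
  if (i + 1L <= nrow(ex)) {
    intron_span <- if (context$strand == "+") {
      c(ex$end[i], ex$start[i + 1L])
    } else {
      c(ex$end[i + 1L], ex$start[i])
    }
    dists <- vapply(fps, function(f) {
      if (f[2L] <= s) s - f[2L] + 1L
      else if (f[1L] >= e) f[1L] - e + 1L
      else 0L
    }, 1L)
    if (hits_span(intron_span) && any(dists > 0L &
                                      dists <= config$proximal_window)) {
      return(classification("PROXIMAL_INTRONIC_MOTIF", evidence = list(
        rule = "proximal_intronic_motif", position = label,
        distance = min(dists[dists > 0L])),
        negligible_motif_effect = negligible))
    }
  }

  ## (6) unknown
  classification("UNKNOWN", negligible_motif_effect = negligible)
}

#' Classify a whole catalogue
#'
#' Applies [classify_mutation()] to every entry; per-entry errors are
#' collected rather than fatal. Siblings for the sibling-activation rule are
#' derived from the catalogue itself (same gene and intron).
#'
#' @param entries list of [catalogue_entry()] objects.
#' @param contexts named list of [gene_context()] objects keyed by gene
#'   symbol (a single context is recycled).
#' @param sequences named list/vector of chromosome sequences.
#' @param models,config as in [classify_mutation()].
#' @return list with `results` (one [classification()] or `NULL` per entry),
#'   `tally` (named integer over [mutation_categories()]) and `errors`.
#' @export
batch_classify <- function(entries, contexts, sequences,
                           models = toy_models(),
                           config = classify_config()) {
  recs <- lapply(entries, function(e) e$record)
  results <- vector("list", length(entries))
  errors <- list()
  for (k in seq_along(entries)) {
    entry <- entries[[k]]
    ctx <- if (inherits(contexts, "pe_gene_context")) contexts else
      contexts[[entry$record$gene]]
    sibs <- Filter(function(r) {
      identical(r$gene, entry$record$gene) &&
        identical(r$intron_index, entry$record$intron_index)
    }, recs[-k])
    results[[k]] <- tryCatch({
      if (is.null(ctx)) stop("no gene context for ", entry$record$gene,
                             call. = FALSE)
      classify_mutation(entry, ctx, sequences, models, config,
                        siblings = sibs)
    }, error = function(err) {
      errors[[length(errors) + 1L]] <<- list(
        index = k, pe_id = entry$record$pe_id,
        message = conditionMessage(err))
      NULL
    })
  }
  cats <- vapply(results, function(r) {
    if (is.null(r)) NA_character_ else r$category
  }, "")
  tally <- table(factor(cats, levels = MUTATION_CATEGORIES))
  list(results = results,
       tally = stats::setNames(as.integer(tally), MUTATION_CATEGORIES),
       errors = errors)
}
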