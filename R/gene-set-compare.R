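#' Cluster gene models into loci by span overlap
#'
#' Single-linkage clustering: two models belong to the same locus when
#' their spans overlap by at least one base on the same sequence (and the
#' same strand when `strand_aware`), transitively closed.  Loci are
#' returned in deterministic (seqid, start) order.
#'
#' @param models list of [gene_model()] objects.
#' @param strand_aware cluster each strand separately (default `TRUE`;
#'   gene loci on opposite strands are biologically distinct).
#' @return list of `locus` objects: `seqid`, `strand`, `start`, `end`,
#'   `members` (list of gene models).
#' @export
cluster_loci <- function(models, strand_aware = TRUE) {
  if (length(models) == 0L) return(list())
  sp <- model_spans(models)
  key <- if (strand_aware) paste(sp$seqid, sp$strand) else sp$seqid
  loci <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ir <- IRanges::IRanges(sp$start[idx], sp$end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in seq_along(red)) {
      members <- models[idx[grp == g]]
      strands <- unique(vapply(members, `[[`, "", "strand"))
      loci[[length(loci) + 1L]] <- structure(
        list(seqid = sp$seqid[idx[1L]],
             strand = if (length(strands) == 1L) strands else "*",
             start = IRanges::start(red)[g], end = IRanges::end(red)[g],
             members = members),
        class = "locus")
    }
  }
  ord <- order(vapply(loci, `[[`, "", "seqid"),
               vapply(loci, `[[`, 0L, "start"),
               vapply(loci, `[[`, 0L, "end"))
  loci[ord]
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s:%d-%d(%s) %d member(s)\n", x$seqid, x$start,
              x$end, x$strand, length(x$members)))
  invisible(x)
}

#' Default predictor source order used for tie-breaking
#' @export
DEFAULT_SOURCE_ORDER <- c("orig_snap", "orig_aug", "high_snap", "high_aug",
                          "low_snap", "low_aug")

#' Choose the single best gene model at each locus
#'
#' Per locus the member with the minimal AED wins; ties go to the longer
#' spliced length, then to the earlier source in `source_order`, then to
#' the lexicographically smaller transcript id, so the choice is
#' deterministic.
#'
#' @param loci list of loci from [cluster_loci()]; every member must
#'   carry an AED.
#' @param source_order character vector ranking source labels for the
#'   final tie-break.
#' @return list of gene models, one per locus.
#' @export
select_best_per_locus <- function(loci,
                                  source_order = DEFAULT_SOURCE_ORDER) {
  lapply(loci, function(loc) {
    aeds <- vapply(loc$members, `[[`, 0, "aed")
    if (anyNA(aeds)) {
      stop("locus ", loc$seqid, ":", loc$start, "-", loc$end,
           " has unscored members")
    }
    lens <- vapply(loc$members, spliced_length, 0L)
    src <- match(vapply(loc$members, `[[`, "", "source_label"),
                 source_order)
    src[is.na(src)] <- length(source_order) + 1L
    ids <- model_ids(loc$members)
    loc$members[[order(aeds, -lens, src, ids)[1L]]]
  })
}

overlap_hits <- function(query_spans, ref_spans, min_overlap = 1L,
                         strand_aware = FALSE) {
  hit <- logical(nrow(query_spans))
  qkey <- if (strand_aware) paste(query_spans$seqid, query_spans$strand)
          else query_spans$seqid
  rkey <- if (strand_aware) paste(ref_spans$seqid, ref_spans$strand)
          else ref_spans$seqid
  for (k in unique(qkey)) {
    qi <- which(qkey == k)
    ri <- which(rkey == k)
    if (length(ri) == 0L) next
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(query_spans$start[qi], query_spans$end[qi]),
      IRanges::IRanges(ref_spans$start[ri], ref_spans$end[ri]),
      minoverlap = min_overlap)
    hit[qi] <- hit[qi] | ov > 0L
  }
  hit
}

#' Find models unique to a query annotation
#'
#' A query model is novel when its span overlaps no model span in any
#' reference set by `min_overlap` or more bases.  Comparison is
#' strand-agnostic by default, matching the usual span-intersection
#' convention.
#'
#' @param query list of [gene_model()] objects.
#' @param references a list of gene models, or a list of such lists.
#' @param min_overlap minimum overlap (bp) that disqualifies novelty
#'   (default 1).
#' @param strand_aware require same-strand overlap to disqualify
#'   (default `FALSE`).
#' @return list of novel gene models.
#' @export
find_novel <- function(query, references, min_overlap = 1L,
                       strand_aware = FALSE) {
  if (length(query) == 0L) return(list())
  if (length(references) > 0L && inherits(references[[1L]], "gene_model")) {
    references <- list(references)
  }
  qsp <- model_spans(query)
  hit <- logical(length(query))
  for (ref in references) {
    if (length(ref) == 0L) next
    hit <- hit | overlap_hits(qsp, model_spans(ref), min_overlap,
                              strand_aware)
  }
  query[!hit]
}

#' Identify standard models improved by an alternative predictor
#'
#' A standard model is improved when the merged annotation's model at an
#' overlapping locus comes from a source outside `standard_sources` and
#' has a strictly lower AED.  With several overlapping merged models the
#' lowest-AED qualifying one is reported.
#'
#' @param standard list of gene models from the standard annotation (with
#'   AEDs).
#' @param merged list of gene models chosen per locus in the merged
#'   annotation (e.g. from [select_best_per_locus()]).
#' @param standard_sources source labels counted as "standard"; defaults
#'   to the labels present in `standard`.
#' @param min_overlap minimum span overlap in bp (default 1).
#' @param strand_aware require same-strand overlap (default `TRUE`,
#'   matching strand-aware locus construction).
#' @return data.frame with columns `standard_id`, `replacement_id`,
#'   `aed_before`, `aed_after`.
#' @export
find_improved <- function(standard, merged, standard_sources = NULL,
                          min_overlap = 1L, strand_aware = TRUE) {
  empty <- data.frame(standard_id = character(0),
                      replacement_id = character(0),
                      aed_before = numeric(0), aed_after = numeric(0))
  if (length(standard) == 0L || length(merged) == 0L) return(empty)
  if (is.null(standard_sources)) {
    standard_sources <- unique(vapply(standard, `[[`, "", "source_label"))
  }
  msp <- model_spans(merged)
  rows <- lapply(standard, function(s) {
    same <- msp$seqid == s$seqid & msp$start <= s$end & msp$end >= s$start &
      (msp$end - pmax(msp$start, s$start) + 1L) >= 0L
    ov_width <- pmin(msp$end, s$end) - pmax(msp$start, s$start) + 1L
    cand <- which(same & ov_width >= min_overlap &
                    (!strand_aware | !(msp$strand %in% c("+", "-")) |
                       !(s$strand %in% c("+", "-")) |
                       msp$strand == s$strand))
    cand <- cand[!(msp$source_label[cand] %in% standard_sources) &
                   msp$aed[cand] < s$aed]
    if (length(cand) == 0L) return(NULL)
    best <- cand[order(msp$aed[cand], msp$transcript_id[cand])][1L]
    data.frame(standard_id = s$transcript_id,
               replacement_id = msp$transcript_id[best],
               aed_before = s$aed, aed_after = msp$aed[best])
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
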