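#' Number of genomic positions covered by both interval sets
#'
#' @param a,b interval sets (data.frames with `start`/`end`), assumed to
#'   lie on the same sequence.
#' @return integer overlap in bases.
#' @export
overlap_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  ra <- IRanges::reduce(as_iranges(a))
  rb <- IRanges::reduce(as_iranges(b))
  sum(IRanges::width(IRanges::intersect(ra, rb)))
}

model_footprint <- function(model, kind = "transcript") {
  if (identical(kind, "protein")) return(model$cds)
  if (!is.null(model$exons) && nrow(model$exons) > 0L) model$exons
  else model$cds
}

aed_row <- function(transcript_id, best_evidence_id, sn, sp) {
  data.frame(transcript_id = transcript_id,
             best_evidence_id = best_evidence_id,
             sn = sn, sp = sp, aed = 1 - (sn + sp) / 2)
}

#' Annotation edit distance against a single evidence alignment
#'
#' At nucleotide resolution, with `o` the number of bases shared by the
#' model footprint and the evidence blocks, sensitivity `sn = o / |evidence|`,
#' specificity `sp = o / |footprint|`, and `AED = 1 - (sn + sp) / 2`: 0
#' means perfect concordance, 1 means the evidence lends no support.
#' Transcript evidence is compared against the exon footprint (CDS when
#' exons are absent); protein evidence against the CDS footprint.  A
#' model and evidence on different sequences, or on explicitly opposite
#' strands, score `AED = 1`.
#'
#' @param model a [gene_model()].
#' @param ev an [evidence_alignment()].
#' @return One-row data.frame: `transcript_id`, `best_evidence_id`, `sn`,
#'   `sp`, `aed`.
#' @export
aed_single <- function(model, ev) {
  incompatible <- !identical(model$seqid, ev$seqid) ||
    (model$strand %in% c("+", "-") && ev$strand %in% c("+", "-") &&
       model$strand != ev$strand)
  if (incompatible) {
    return(aed_row(model$transcript_id, ev$evidence_id, 0, 0))
  }
  fp <- model_footprint(model, ev$kind)
  o <- overlap_bases(fp, ev$blocks)
  aed_row(model$transcript_id, ev$evidence_id,
          sn = o / interval_width(ev$blocks),
          sp = o / interval_width(fp))
}

#' Best (minimum) AED of a model over an evidence collection
#'
#' @param model a [gene_model()].
#' @param evidence list of [evidence_alignment()] objects.
#' @return One-row data.frame as in [aed_single()]; with no evidence the
#'   AED is 1 and `best_evidence_id` is `NA`.
#' @export
aed_best <- function(model, evidence) {
  if (length(evidence) == 0L) {
    return(aed_row(model$transcript_id, NA_character_, 0, 0))
  }
  rows <- do.call(rbind, lapply(evidence, aed_single, model = model))
  rows <- rows[order(rows$aed, rows$best_evidence_id), , drop = FALSE]
  rows[1L, , drop = FALSE]
}

#' Score a set of models against a set of evidence alignments
#'
#' Evidence whose footprint span does not overlap a model's span cannot
#' beat AED = 1, so only span-overlapping pairs are evaluated; models
#' with no overlapping evidence score 1.
#'
#' @param models list of [gene_model()] objects.
#' @param evidence list of [evidence_alignment()] objects.
#' @return data.frame with one row per model: `transcript_id`,
#'   `best_evidence_id`, `sn`, `sp`, `aed`.
#' @export
aed_table <- function(models, evidence) {
  if (length(models) == 0L) {
    return(aed_row(character(0), character(0), numeric(0), numeric(0)))
  }
  ev_seqid <- vapply(evidence, `[[`, "", "seqid")
  ev_start <- vapply(evidence, function(e) min(e$blocks$start), 0L)
  ev_end <- vapply(evidence, function(e) max(e$blocks$end), 0L)
  rows <- lapply(models, function(m) {
    cand <- which(ev_seqid == m$seqid & ev_start <= m$end &
                    ev_end >= m$start)
    aed_best(m, evidence[cand])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach best-evidence AEDs to gene models
#'
#' @inheritParams aed_table
#' @return The model list with each model's `aed` field set.
#' @export
score_models <- function(models, evidence) {
  tab <- aed_table(models, evidence)
  for (i in seq_along(models)) models[[i]]$aed <- tab$aed[i]
  models
}

#' Count and percentage of models with AED below 0.5
#'
#' Models with AED strictly below 0.5 are conventionally taken as the
#' well-supported fraction of an annotation, a genome-wide quality
#' summary.
#'
#' @param results numeric AED vector, or a data.frame with an `aed`
#'   column.
#' @return list with `count` and `percent` (`NA` percent on empty input,
#'   with a warning).
#' @export
aed_half_fraction <- function(results) {
  aeds <- if (is.data.frame(results)) results$aed else as.numeric(results)
  if (length(aeds) == 0L) {
    warning("no AED results; percentage undefined")
    return(list(count = 0L, percent = NA_real_))
  }
  count <- sum(aeds < 0.5)
  list(count = count, percent = 100 * count / length(aeds))
}

#' Cumulative AED curve
#'
#' Fraction of models with AED at or below each threshold on a 0..1 grid
#' with step 0.01; non-decreasing with endpoint 1 at threshold 1.
#'
#' @inheritParams aed_half_fraction
#' @return data.frame with columns `threshold` and `cumulative_fraction`.
#' @export
aed_cumulative_curve <- function(results) {
  aeds <- if (is.data.frame(results)) results$aed else as.numeric(results)
  if (length(aeds) == 0L) stop("no AED results")
  grid <- seq(0, 1, by = 0.01)
  data.frame(threshold = grid,
             cumulative_fraction = vapply(grid, function(t)
               mean(aeds <= t), 0))
}

#' Mean spliced transcript length of a model set
#'
#' @param models list of [gene_model()] objects.
#' @return Mean of per-model spliced lengths (exons, or CDS when exons
#'   are absent); `NA` with a warning on empty input.
#' @export
mean_transcript_length <- function(models) {
  if (length(models) == 0L) {
    warning("no models; mean length undefined")
    return(NA_real_)
  }
  mean(vapply(models, spliced_length, 0L))
}
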