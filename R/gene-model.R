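#' @importFrom methods is
#' @importFrom stats rnorm runif rbinom rlnorm rnbinom setNames
#' @importFrom utils head tail
NULL

## Interval sets are plain data.frames with integer `start`/`end` columns,
## 1-based inclusive (GFF3 convention).  Conversion to IRanges happens only
## inside interval arithmetic.

#' Build a validated interval set
#'
#' @param start,end integer vectors of equal length; 1-based inclusive.
#' @return A data.frame with columns `start` and `end`, sorted by `start`.
#' Intervals must be non-overlapping.
#' @export
intervals <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  if (length(start) > 0L) {
    if (anyNA(start) || anyNA(end)) stop("intervals contain NA coordinates")
    if (any(start < 1L)) stop("interval start must be >= 1")
    if (any(end < start)) stop("interval end must be >= start")
    o <- order(start, end)
    start <- start[o]
    end <- end[o]
    if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
      stop("intervals overlap")
    }
  }
  structure(list(start = start, end = end), class = "data.frame",
            row.names = seq_along(start))
}

as_iranges <- function(x) IRanges::IRanges(start = x$start, end = x$end)

interval_width <- function(x) sum(x$end - x$start + 1L)

#' Construct a gene model
#'
#' A transcript-level annotation: a genomic span holding ordered,
#' non-overlapping CDS intervals and (optionally) exon intervals, a source
#' label identifying the predictor that produced it, and an optional
#' annotation edit distance (AED).
#'
#' @param gene_id,transcript_id non-empty identifier strings.
#' @param seqid sequence (chromosome/scaffold) identifier.
#' @param start,end 1-based inclusive span of the model.
#' @param strand one of `"+"`, `"-"`, `"*"` (unknown).
#' @param cds interval set (see [intervals()]) of coding segments; required,
#'   total length must be positive.
#' @param exons interval set of exons, or `NULL` when unknown.  When
#'   present, every CDS interval must lie within some exon.
#' @param source_label predictor/source tag (e.g. `"est2genome"`,
#'   `"high_snap"`).
#' @param aed annotation edit distance in \[0, 1\], or `NA` when unscored.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, seqid, start, end,
                       strand = "*", cds, exons = NULL,
                       source_label = "unknown", aed = NA_real_) {
  m <- structure(
    list(
      gene_id = as.character(gene_id),
      transcript_id = as.character(transcript_id),
      seqid = as.character(seqid),
      start = as.integer(start),
      end = as.integer(end),
      strand = as.character(strand),
      cds = if (is.data.frame(cds)) intervals(cds$start, cds$end) else cds,
      exons = if (is.null(exons)) NULL else
        intervals(exons$start, exons$end),
      source_label = as.character(source_label),
      aed = as.numeric(aed)
    ),
    class = "gene_model"
  )
  validate_gene_model(m)
  m
}

validate_gene_model <- function(m) {
  stopifnot(is.list(m))
  for (f in c("gene_id", "transcript_id", "seqid")) {
    if (!nzchar(m[[f]])) stop("gene model field '", f, "' is empty")
  }
  if (!m$strand %in% c("+", "-", "*")) {
    stop("gene model ", m$transcript_id, ": invalid strand '", m$strand, "'")
  }
  if (is.na(m$start) || is.na(m$end) || m$start < 1L || m$end < m$start) {
    stop("gene model ", m$transcript_id, ": invalid span")
  }
  parts <- list(cds = m$cds)
  if (!is.null(m$exons)) parts$exons <- m$exons
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (nrow(p) > 0L && (min(p$start) < m$start || max(p$end) > m$end)) {
      stop("gene model ", m$transcript_id, ": ", nm,
           " intervals outside model span")
    }
  }
  if (interval_width(m$cds) <= 0L) {
    stop("gene model ", m$transcript_id, ": empty CDS")
  }
  if (!is.null(m$exons) && nrow(m$exons) > 0L) {
    contained <- vapply(seq_len(nrow(m$cds)), function(j) {
      any(m$exons$start <= m$cds$start[j] & m$exons$end >= m$cds$end[j])
    }, TRUE)
    if (!all(contained)) {
      stop("gene model ", m$transcript_id,
           ": CDS interval not contained in any exon")
    }
  }
  if (!is.na(m$aed) && (m$aed < 0 || m$aed > 1)) {
    stop("gene model ", m$transcript_id, ": aed outside [0, 1]")
  }
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d(%s) src=%s cds=%d aed=%s\n",
              x$transcript_id, x$gene_id, x$seqid, x$start, x$end, x$strand,
              x$source_label, nrow(x$cds),
              ifelse(is.na(x$aed), "NA", format(x$aed))))
  invisible(x)
}

#' Spliced length of a gene model
#'
#' Sum of exon widths, falling back to CDS widths when exons are absent.
#'
#' @param model a [gene_model()].
#' @return integer number of bases.
#' @export
spliced_length <- function(model) {
  if (!is.null(model$exons) && nrow(model$exons) > 0L) {
    interval_width(model$exons)
  } else {
    interval_width(model$cds)
  }
}

#' Construct an evidence alignment
#'
#' The genomic footprint of a transcript or protein alignment, used as the
#' comparison target for AED.
#'
#' @param evidence_id identifier.
#' @param seqid sequence identifier shared by all blocks.
#' @param blocks interval set of aligned blocks; total length must be
#'   positive.
#' @param kind `"transcript"` or `"protein"`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return An object of class `evidence_alignment`.
#' @export
evidence_alignment <- function(evidence_id, seqid, blocks,
                               kind = c("transcript", "protein"),
                               strand = "*") {
  kind <- match.arg(kind)
  e <- structure(
    list(
      evidence_id = as.character(evidence_id),
      kind = kind,
      seqid = as.character(seqid),
      strand = as.character(strand),
      blocks = intervals(blocks$start, blocks$end)
    ),
    class = "evidence_alignment"
  )
  if (!nzchar(e$evidence_id)) stop("evidence_id is empty")
  if (!e$strand %in% c("+", "-", "*")) stop("invalid strand")
  if (interval_width(e$blocks) <= 0L) stop("evidence has empty blocks")
  e
}

#' @export
print.evidence_alignment <- function(x, ...) {
  cat(sprintf("<evidence_alignment> %s [%s] %s(%s) blocks=%d\n",
              x$evidence_id, x$kind, x$seqid, x$strand, nrow(x$blocks)))
  invisible(x)
}

#' Summarise a list of gene models as a data.frame of spans
#'
#' @param models list of [gene_model()] objects.
#' @return data.frame with one row per model: transcript_id, gene_id,
#'   seqid, start, end, strand, source_label, aed.
#' @export
model_spans <- function(models) {
  if (length(models) == 0L) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      source_label = character(0), aed = numeric(0)))
  }
  data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    seqid = vapply(models, `[[`, "", "seqid"),
    start = vapply(models, `[[`, 0L, "start"),
    end = vapply(models, `[[`, 0L, "end"),
    strand = vapply(models, `[[`, "", "strand"),
    source_label = vapply(models, `[[`, "", "source_label"),
    aed = vapply(models, `[[`, 0, "aed")
  )
}

model_ids <- function(models) vapply(models, `[[`, "", "transcript_id")

## Restore the caller's RNG state after seeded work.  All randomised
## operations in the package run through this so that a fixed seed gives
## identical results without disturbing the session RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}
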