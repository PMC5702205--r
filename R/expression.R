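#' Transcripts per million (TPM)
#'
#' Per sample, `rate_i = count_i / length_i` and
#' `TPM_i = 1e6 * rate_i / sum(rate)`, so each column sums to one
#' million.
#'
#' @param counts non-negative count vector, or matrix with transcripts in
#'   rows and samples in columns.
#' @param lengths positive transcript lengths (one per transcript, shared
#'   across samples).
#' @return TPM values with the shape and dimnames of `counts`.
#' @export
tpm <- function(counts, lengths) {
  m <- as.matrix(counts)
  if (length(lengths) != nrow(m)) {
    stop("need one length per transcript (", nrow(m), "), got ",
         length(lengths))
  }
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(m < 0)) stop("counts must be non-negative")
  rate <- m / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(which(tot == 0), collapse = ", "))
  }
  out <- sweep(rate, 2L, tot, "/") * 1e6
  if (is.null(dim(counts))) {
    stats::setNames(drop(out), names(counts))
  } else {
    out
  }
}

#' Translatome enrichment index (TEI)
#'
#' Ratio of TRAP-seq TPM to mRNA-seq TPM per transcript.  A zero mRNA TPM
#' makes the index undefined (`NA`), which is reported distinctly from a
#' TEI of 0 (zero TRAP signal over positive mRNA signal).
#'
#' @param trap_tpm,mrna_tpm non-negative TPM vectors or matrices of equal
#'   shape.
#' @return TEI values with the same shape.
#' @export
tei <- function(trap_tpm, mrna_tpm) {
  if (length(trap_tpm) != length(mrna_tpm)) {
    stop("trap_tpm and mrna_tpm must have the same shape")
  }
  if (any(trap_tpm < 0, na.rm = TRUE) || any(mrna_tpm < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative")
  }
  out <- ifelse(mrna_tpm > 0, trap_tpm / mrna_tpm, NA_real_)
  dim(out) <- dim(trap_tpm)
  dimnames(out) <- dimnames(trap_tpm)
  if (is.null(dim(trap_tpm))) names(out) <- names(trap_tpm)
  out
}

#' Scale matrix rows to sum to one
#'
#' Used for heatmap display: each row is divided by its sum; all-zero
#' rows are left unchanged with a warning, so row sums are either 0 or 1.
#'
#' @param m numeric matrix with non-negative entries.
#' @return The row-scaled matrix.
#' @export
row_scale <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) left unscaled")
    rs[zero] <- 1
  }
  m / rs
}

#' Transcript ids with detectable expression
#'
#' @param counts count matrix (transcripts in rows, named).
#' @param min_count minimum count in at least one sample (default 1).
#' @return Character vector of row names meeting the threshold.
#' @export
expressed_ids <- function(counts, min_count = 1) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) stop("count matrix must have row names")
  rownames(m)[apply(m >= min_count, 1L, any)]
}

#' Expression support for a set of novel models
#'
#' @param novel_ids transcript ids of novel models.
#' @param expressed transcript ids with expression support (e.g. from
#'   [expressed_ids()]).
#' @return list with `count` (size of the intersection) and `percent`
#'   (rounded to the nearest integer percent; `NA` when `novel_ids` is
#'   empty, with a warning).
#' @export
support_fraction <- function(novel_ids, expressed) {
  if (length(novel_ids) == 0L) {
    warning("no novel models; support percentage undefined")
    return(list(count = 0L, percent = NA_real_))
  }
  count <- length(intersect(novel_ids, expressed))
  list(count = count, percent = round(100 * count / length(novel_ids)))
}
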