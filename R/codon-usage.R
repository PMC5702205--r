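## Standard genetic code bookkeeping, derived from Biostrings::GENETIC_CODE
## at load time.  Degeneracy classes for the effective-number-of-codons
## statistic: nine 2-fold amino acids, Ile as the sole 3-fold, five 4-fold,
## and Leu/Ser/Arg as 6-fold.

codon_tables <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  stops <- codons[aa == "*"]
  syn <- table(aa[aa != "*"])
  list(codons = codons, aa = aa, stops = stops,
       syn_count = stats::setNames(as.integer(syn), names(syn)))
})

#' Tally in-frame codons of a CDS
#'
#' Frame-0 codons are counted over the standard genetic code.  The
#' terminal stop codon is excluded from usage statistics, as are internal
#' stop codons (with a warning) and codons containing non-ACGT bases
#' (counted in `skipped`).
#'
#' @param seq a CDS as a character string, [Biostrings::DNAString], or a
#'   length-one [Biostrings::DNAStringSet]; length must be a multiple of
#'   3.
#' @param id transcript id to record (defaults to the sequence name, or
#'   `"cds"`).
#' @return An object of class `codon_usage`: `transcript_id`, `counts`
#'   (named 64-vector; stop codons always 0), `n_codons`, `skipped`,
#'   `internal_stops`, `terminal_stop`.
#' @export
count_codons <- function(seq, id = NULL) {
  if (is(seq, "DNAStringSet")) {
    if (is.null(id)) id <- names(seq)[1L]
    seq <- as.character(seq[[1L]])
  } else if (is(seq, "DNAString")) {
    seq <- as.character(seq)
  }
  if (is.null(id)) id <- "cds"
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a positive multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  cod <- substring(seq, starts, starts + 2L)
  valid <- cod %in% codon_tables$codons
  skipped <- sum(!valid)
  cod <- cod[valid]
  is_stop <- cod %in% codon_tables$stops
  terminal_stop <- length(cod) > 0L && is_stop[length(cod)]
  if (terminal_stop) {
    cod <- cod[-length(cod)]
    is_stop <- is_stop[-length(is_stop)]
  }
  internal_stops <- sum(is_stop)
  if (internal_stops > 0L) {
    warning(id, ": ", internal_stops,
            " internal stop codon(s) excluded from usage counts")
    cod <- cod[!is_stop]
  }
  counts <- stats::setNames(integer(64L), codon_tables$codons)
  tab <- table(cod)
  counts[names(tab)] <- as.integer(tab)
  structure(list(transcript_id = id, counts = counts,
                 n_codons = sum(counts), skipped = skipped,
                 internal_stops = internal_stops,
                 terminal_stop = terminal_stop),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %s: %d codons (%d skipped)\n",
              x$transcript_id, x$n_codons, x$skipped))
  invisible(x)
}

#' GC content at synonymously variable third codon positions (GC3s)
#'
#' The fraction of third positions that are G or C among codons whose
#' amino acid has two or more synonymous codons; Met (ATG), Trp (TGG) and
#' stop codons are excluded.
#'
#' @param u a `codon_usage` object.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when no
#'   eligible codons are present.
#' @export
gc3s <- function(u) {
  stopifnot(inherits(u, "codon_usage"))
  aa <- codon_tables$aa
  eligible <- aa != "*" & codon_tables$syn_count[aa] >= 2L
  n_elig <- sum(u$counts[eligible])
  if (n_elig == 0L) {
    warning(u$transcript_id, ": no synonymously variable codons; ",
            "GC3s undefined")
    return(NA_real_)
  }
  third <- substring(codon_tables$codons, 3L, 3L)
  sum(u$counts[eligible & third %in% c("G", "C")]) / n_elig
}

## Homozygosity estimate for one amino acid: F = (n * sum p^2 - 1)/(n - 1)
codon_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (Nc)
#'
#' Wright's codon-usage-bias statistic on the 20..61 scale: 61 means
#' uniform synonymous usage, 20 means one codon per amino acid.  Per
#' amino acid with at least two observations the codon homozygosity
#' `F = (n * sum(p^2) - 1) / (n - 1)` is estimated, averaged within the
#' 2-, 3-, 4- and 6-fold degeneracy classes, and combined as
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61.
#'
#' Conventions for sparse data: amino acids with fewer than two
#' observations are excluded from their class mean; amino acids with
#' `F = 0` are excluded and the class mean recomputed; a missing 3-fold
#' class (no Ile) is replaced by `(F2 + F4)/2`; if any other class is
#' empty, Nc is undefined (`NA`).  Applied fallbacks are recorded in the
#' `"fallbacks"` attribute.
#'
#' @param u a `codon_usage` object.
#' @return Nc in \[20, 61\], or `NA` when undefined.
#' @export
effective_codon_number <- function(u) {
  stopifnot(inherits(u, "codon_usage"))
  aa <- codon_tables$aa
  fallbacks <- character(0)
  f_by_aa <- list()
  for (a in names(codon_tables$syn_count)) {
    k <- codon_tables$syn_count[[a]]
    if (k < 2L) next
    f <- codon_homozygosity(u$counts[aa == a])
    if (!is.na(f)) f_by_aa[[a]] <- c(f = f, k = k)
  }
  if (length(f_by_aa) == 0L) return(NA_real_)
  fmat <- do.call(rbind, f_by_aa)
  class_mean <- function(k) {
    f <- fmat[fmat[, "k"] == k, "f"]
    if (length(f) == 0L) return(NA_real_)
    if (any(f == 0)) {
      fallbacks <<- c(fallbacks,
                      sprintf("zero-F amino acid(s) dropped from %d-fold",
                              k))
      f <- f[f > 0]
      if (length(f) == 0L) return(NA_real_)
    }
    mean(f)
  }
  f2 <- class_mean(2L)
  f3 <- class_mean(3L)
  f4 <- class_mean(4L)
  f6 <- class_mean(6L)
  if (is.na(f3)) {
    if (is.na(f2) || is.na(f4)) return(NA_real_)
    f3 <- (f2 + f4) / 2
    fallbacks <- c(fallbacks, "3-fold class imputed as (F2 + F4)/2")
  }
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  nc <- min(nc, 61)
  attr(nc, "fallbacks") <- fallbacks
  nc
}

#' Expected Nc under no selection on codon usage
#'
#' The null relationship between the effective number of codons and GC3s
#' when codon usage is driven by base composition alone:
#' `Nc(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3s value(s) in \[0, 1\].
#' @return Expected Nc (vectorised).
#' @export
nc_null_curve <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Codon-usage summary table for a set of CDS sequences
#'
#' @param seqs a named [Biostrings::DNAStringSet] of CDS sequences.
#' @return data.frame with columns `transcript_id`, `n_codons`, `gc3s`,
#'   `nc`.
#' @export
codon_usage_table <- function(seqs) {
  rows <- lapply(seq_along(seqs), function(i) {
    u <- count_codons(seqs[i])
    data.frame(transcript_id = u$transcript_id, n_codons = u$n_codons,
               gc3s = suppressWarnings(gc3s(u)),
               nc = as.numeric(effective_codon_number(u)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
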