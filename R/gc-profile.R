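#' Extract the spliced CDS sequence of a gene model
#'
#' CDS intervals are concatenated in genomic order and, for minus-strand
#' models, reverse-complemented, so the result reads 5' to 3' in
#' transcript orientation.
#'
#' @param model a [gene_model()].
#' @param genome named [Biostrings::DNAStringSet] holding `model$seqid`.
#' @return A [Biostrings::DNAStringSet] of length one named by the
#'   transcript id.
#' @export
extract_cds_sequence <- function(model, genome) {
  if (!model$seqid %in% names(genome)) {
    stop("sequence '", model$seqid, "' not found in genome")
  }
  chr <- genome[[model$seqid]]
  if (max(model$cds$end) > length(chr)) {
    stop("model '", model$transcript_id, "': CDS interval beyond end of '",
         model$seqid, "' (", length(chr), " bp)")
  }
  pieces <- Biostrings::extractAt(chr, as_iranges(model$cds))
  seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (identical(model$strand, "-")) {
    seq <- Biostrings::reverseComplement(seq)
  }
  out <- Biostrings::DNAStringSet(list(seq))
  names(out) <- model$transcript_id
  out
}

#' @rdname extract_cds_sequence
#' @param models list of gene models.
#' @export
extract_cds_sequences <- function(models, genome) {
  if (length(models) == 0L) return(Biostrings::DNAStringSet())
  seqids <- vapply(models, `[[`, "", "seqid")
  strands <- vapply(models, `[[`, "", "strand")
  missing <- setdiff(unique(seqids), names(genome))
  if (length(missing) > 0L) {
    stop("sequence '", missing[1L], "' not found in genome")
  }
  out <- Biostrings::DNAStringSet(rep("", length(models)))
  for (sq in unique(seqids)) {
    idx <- which(seqids == sq)
    cds_list <- lapply(models[idx], function(m) {
      if (max(m$cds$end) > length(genome[[sq]])) {
        stop("model '", m$transcript_id,
             "': CDS interval beyond end of '", sq, "' (",
             length(genome[[sq]]), " bp)")
      }
      m$cds
    })
    nparts <- vapply(cds_list, nrow, 0L)
    all_iv <- do.call(rbind, cds_list)
    chars <- as.character(Biostrings::extractAt(genome[[sq]],
                                                as_iranges(all_iv)))
    grp <- factor(rep(seq_along(idx), nparts), levels = seq_along(idx))
    out[idx] <- Biostrings::DNAStringSet(
      vapply(split(chars, grp), paste, "", collapse = ""))
  }
  minus <- strands == "-"
  if (any(minus)) {
    out[minus] <- Biostrings::reverseComplement(out[minus])
  }
  names(out) <- model_ids(models)
  out
}

#' Per-sequence nucleotide composition and GC content
#'
#' GC percent is computed as `100 * (G + C) / (A + C + G + T)`: ambiguous
#' `N` bases are excluded from the denominator.  Sequences consisting only
#' of `N` get `NA` GC and are flagged.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @return data.frame with columns `transcript_id`, `A`, `C`, `G`, `T`,
#'   `N`, `length`, `gc_percent`, `flagged`.
#' @export
gc_content <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (length(seqs) == 0L) {
    return(data.frame(transcript_id = character(0), A = integer(0),
                      C = integer(0), G = integer(0), T = integer(0),
                      N = integer(0), length = integer(0),
                      gc_percent = numeric(0), flagged = logical(0)))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence")
  af <- Biostrings::alphabetFrequency(seqs)
  other <- rowSums(af) - af[, "A"] - af[, "C"] - af[, "G"] - af[, "T"] -
    af[, "N"]
  n <- af[, "N"] + other  # non-ACGT treated as N
  denom <- af[, "A"] + af[, "C"] + af[, "G"] + af[, "T"]
  gc <- ifelse(denom > 0, 100 * (af[, "G"] + af[, "C"]) / denom, NA_real_)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  data.frame(transcript_id = ids, A = af[, "A"], C = af[, "C"],
             G = af[, "G"], T = af[, "T"], N = as.integer(n),
             length = Biostrings::width(seqs), gc_percent = gc,
             flagged = denom == 0, row.names = NULL)
}

new_gc_histogram <- function(raw, smoothed, smooth_window) {
  structure(list(bins = 0:100, raw = raw, smoothed = smoothed,
                 smooth_window = as.integer(smooth_window)),
            class = "gc_histogram")
}

#' Bin GC percentages into an integer-percent histogram
#'
#' Each record falls in bin `floor(gc_percent)`; a GC of exactly 100 goes
#' to bin 100.  Records with undefined GC (all-N sequences) are skipped
#' and counted in the `skipped` attribute.
#'
#' @param records data.frame from [gc_content()], or a numeric vector of
#'   GC percentages.
#' @return An object of class `gc_histogram` with fields `bins` (0..100),
#'   `raw`, `smoothed` (initially equal to `raw`) and `smooth_window`.
#' @export
build_gc_histogram <- function(records) {
  gc <- if (is.data.frame(records)) records$gc_percent else as.numeric(records)
  skipped <- sum(is.na(gc))
  if (skipped > 0L) {
    warning(skipped, " record(s) with undefined GC skipped")
    gc <- gc[!is.na(gc)]
  }
  if (any(gc < 0 | gc > 100)) stop("gc_percent outside [0, 100]")
  raw <- tabulate(pmin(floor(gc), 100) + 1L, nbins = 101L)
  h <- new_gc_histogram(raw, as.numeric(raw), 1L)
  attr(h, "skipped") <- skipped
  h
}

#' Smooth a GC histogram with a truncated centred moving average
#'
#' `smoothed[b]` is the mean of the raw counts over the window of
#' `smooth_window` bins centred on `b`, intersected with \[0, 100\] (the
#' window is truncated at the edges, not padded).
#'
#' @param h a `gc_histogram`.
#' @param smooth_window odd integer >= 1 (default 7).
#' @return The histogram with its `smoothed` field replaced.
#' @export
smooth_histogram <- function(h, smooth_window = 7L) {
  w <- as.integer(smooth_window)
  if (is.na(w) || w < 1L || w %% 2L == 0L) {
    stop("smooth_window must be an odd integer >= 1")
  }
  half <- (w - 1L) %/% 2L
  n <- length(h$raw)
  sm <- vapply(seq_len(n), function(i) {
    mean(h$raw[max(1L, i - half):min(n, i + half)])
  }, 0)
  h$smoothed <- sm
  h$smooth_window <- w
  h
}

#' @export
print.gc_histogram <- function(x, ...) {
  cat(sprintf("<gc_histogram> %d records, smooth_window=%d, mode bin=%d\n",
              sum(x$raw), x$smooth_window, which.max(x$smoothed) - 1L))
  invisible(x)
}

#' Detect peaks in a smoothed GC histogram
#'
#' Bin `b` is a peak when the `(peak_window - 1) / 2` bins on each side of
#' it all exist (edge bins are ineligible) and all have strictly lower
#' smoothed counts than bin `b`.  Ties therefore never produce peaks.
#'
#' @param h a `gc_histogram` (smooth it first with [smooth_histogram()]).
#' @param peak_window odd integer >= 3 (default 5).
#' @return Integer vector of peak bins in ascending order (possibly
#'   empty).
#' @export
detect_peaks <- function(h, peak_window = 5L) {
  w <- as.integer(peak_window)
  if (is.na(w) || w < 3L || w %% 2L == 0L) {
    stop("peak_window must be an odd integer >= 3")
  }
  half <- (w - 1L) %/% 2L
  s <- h$smoothed
  n <- length(s)
  peaks <- integer(0)
  for (i in (half + 1L):(n - half)) {
    side <- s[c((i - half):(i - 1L), (i + 1L):(i + half))]
    if (all(side < s[i])) peaks <- c(peaks, i - 1L)
  }
  peaks
}

#' GC partition cutoffs
#'
#' @param low_peak,high_peak integer percent bins, `low_peak < high_peak`.
#' @param peak_window window used to detect them.
#' @return An object of class `gc_cutoffs`.
#' @export
gc_cutoffs <- function(low_peak, high_peak, peak_window = 5L) {
  low_peak <- as.integer(low_peak)
  high_peak <- as.integer(high_peak)
  if (is.na(low_peak) || is.na(high_peak) || low_peak < 0L ||
      high_peak > 100L || low_peak >= high_peak) {
    stop("invalid cutoffs: need 0 <= low_peak < high_peak <= 100")
  }
  structure(list(low_peak = low_peak, high_peak = high_peak,
                 peak_window = as.integer(peak_window)),
            class = "gc_cutoffs")
}

#' @export
print.gc_cutoffs <- function(x, ...) {
  cat(sprintf("<gc_cutoffs> low=%d high=%d (peak_window=%d)\n",
              x$low_peak, x$high_peak, x$peak_window))
  invisible(x)
}

#' Determine low/high GC cutoffs from a bimodal histogram
#'
#' Among the detected peaks, the two with the highest smoothed counts are
#' retained (ties broken toward the bin farther from 50); the lesser bin
#' becomes the low cutoff and the greater the high cutoff.  With fewer
#' than two peaks an error asks the user to supply cutoffs manually.
#'
#' @inheritParams detect_peaks
#' @return A [gc_cutoffs()] object.
#' @export
determine_cutoffs <- function(h, peak_window = 5L) {
  peaks <- detect_peaks(h, peak_window)
  if (length(peaks) < 2L) {
    stop("fewer than two GC peaks detected (", length(peaks),
         "); the distribution may not be bimodal - pick high/low GC ",
         "cutoff values manually and construct them with gc_cutoffs()")
  }
  height <- h$smoothed[peaks + 1L]
  ord <- order(-height, -abs(peaks - 50L), peaks)
  top <- peaks[ord[1:2]]
  gc_cutoffs(min(top), max(top), peak_window)
}

#' GC content of the flanking genomic regions of a model
#'
#' GC percent of `flank_bp` bases immediately upstream and downstream (in
#' genome coordinates) of the model span, truncated at the sequence ends.
#' An empty flank yields `NA`.
#'
#' @inheritParams extract_cds_sequence
#' @param flank_bp flank size in bases (default 5000).
#' @return Named numeric vector `c(upstream =, downstream =)`.
#' @export
flanking_gc <- function(model, genome, flank_bp = 5000L) {
  if (!model$seqid %in% names(genome)) {
    stop("sequence '", model$seqid, "' not found in genome")
  }
  chr <- genome[[model$seqid]]
  flank_bp <- as.integer(flank_bp)
  gc_of <- function(from, to) {
    if (flank_bp <= 0L || to < from || to < 1L || from > length(chr)) {
      return(NA_real_)
    }
    s <- Biostrings::subseq(chr, max(1L, from), min(length(chr), to))
    f <- Biostrings::alphabetFrequency(s)
    denom <- f[["A"]] + f[["C"]] + f[["G"]] + f[["T"]]
    if (denom == 0) NA_real_ else 100 * (f[["G"]] + f[["C"]]) / denom
  }
  c(upstream = gc_of(model$start - flank_bp, model$start - 1L),
    downstream = gc_of(model$end + 1L, model$end + flank_bp))
}

#' Write GC-profile output files
#'
#' Emits the four profile outputs under `dir` with prefix `base_name`:
#' `<base>_cds.fasta` (when `cds` is supplied), `<base>_gc_content.txt`
#' (TSV: transcript_id, A, C, G, T, N, length, gc_percent to 2 decimals),
#' `<base>_distribution.txt` (TSV: bin, raw, smoothed) and
#' `<base>_cutoff.txt` (two lines, `low<TAB><int>` / `high<TAB><int>`).
#'
#' @param records data.frame from [gc_content()].
#' @param h a `gc_histogram`.
#' @param cutoffs a `gc_cutoffs` object, or `NULL` to skip the cutoff
#'   file.
#' @param base_name file-name prefix.
#' @param dir output directory.
#' @param cds optional [Biostrings::DNAStringSet] of CDS sequences.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_profile_outputs <- function(records, h, cutoffs, base_name,
                                  dir = ".", cds = NULL) {
  paths <- c()
  if (!is.null(cds)) {
    p <- file.path(dir, paste0(base_name, "_cds.fasta"))
    write_fasta(cds, p)
    paths["cds"] <- p
  }
  p <- file.path(dir, paste0(base_name, "_gc_content.txt"))
  con <- file(p, open = "wb")
  writeLines(c(paste(c("transcript_id", "A", "C", "G", "T", "N", "length",
                       "gc_percent"), collapse = "\t"),
               vapply(seq_len(nrow(records)), function(i) {
                 paste(records$transcript_id[i], records$A[i], records$C[i],
                       records$G[i], records$T[i], records$N[i],
                       records$length[i],
                       ifelse(is.na(records$gc_percent[i]), "NA",
                              sprintf("%.2f", records$gc_percent[i])),
                       sep = "\t")
               }, "")), con, sep = "\n")
  close(con)
  paths["gc_content"] <- p
  p <- file.path(dir, paste0(base_name, "_distribution.txt"))
  con <- file(p, open = "wb")
  writeLines(c("bin\traw\tsmoothed",
               sprintf("%d\t%d\t%s", h$bins, h$raw,
                       vapply(h$smoothed, as.character, ""))), con,
             sep = "\n")
  close(con)
  paths["distribution"] <- p
  if (!is.null(cutoffs)) {
    p <- file.path(dir, paste0(base_name, "_cutoff.txt"))
    con <- file(p, open = "wb")
    writeLines(c(sprintf("low\t%d", cutoffs$low_peak),
                 sprintf("high\t%d", cutoffs$high_peak)), con, sep = "\n")
    close(con)
    paths["cutoff"] <- p
  }
  invisible(paths)
}

#' Re-read a GC content table written by [write_profile_outputs()]
#'
#' GC percent is recomputed from the integer base counts, so the round
#' trip is exact rather than limited to the two decimals stored in the
#' file.
#'
#' @param path path to a `*_gc_content.txt` file.
#' @return data.frame in the [gc_content()] layout.
#' @export
read_gc_content <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "A", "C", "G", "T", "N", "length")
  if (!all(need %in% names(d))) stop("malformed gc_content file: ", path)
  denom <- d$A + d$C + d$G + d$T
  d$gc_percent <- ifelse(denom > 0, 100 * (d$G + d$C) / denom, NA_real_)
  d$flagged <- denom == 0
  d
}

#' Read a cutoff file written by [write_profile_outputs()]
#'
#' @param path path to a `*_cutoff.txt` file.
#' @return A [gc_cutoffs()] object.
#' @export
read_gc_cutoffs <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("which", "value"))
  lo <- d$value[match("low", d$which)]
  hi <- d$value[match("high", d$which)]
  if (is.na(lo) || is.na(hi)) stop("malformed cutoff file: ", path)
  gc_cutoffs(lo, hi)
}
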