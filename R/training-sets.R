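#' Training set of gene models
#'
#' @param label set label, e.g. `"low_gc"`, `"high_gc"`,
#'   `"standard_random_1"`.
#' @param members list of [gene_model()] objects, unique by transcript id.
#' @param provenance how the set was built: a [gc_cutoffs()] object or a
#'   seed.
#' @return An object of class `training_set`.
#' @export
training_set <- function(label, members, provenance = NULL) {
  ids <- model_ids(members)
  if (anyDuplicated(ids)) {
    stop("training set '", label, "': duplicate transcript id ",
         ids[duplicated(ids)][1L])
  }
  structure(list(label = label, members = members,
                 provenance = provenance),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %s: %d models\n", x$label,
              length(x$members)))
  invisible(x)
}

#' @export
length.training_set <- function(x) length(x$members)

#' Select high-quality models for predictor training
#'
#' Keeps transcript-derived gene models whose AED does not exceed the
#' threshold (boundary inclusive; the default 0.2 keeps models well
#' supported by their aligned transcript evidence).
#'
#' @param models list of [gene_model()] objects, all carrying an AED.
#' @param aed_threshold inclusive AED ceiling (default 0.2).
#' @return Filtered list of gene models.
#' @export
select_training_models <- function(models, aed_threshold = 0.2) {
  aeds <- vapply(models, `[[`, 0, "aed")
  if (anyNA(aeds)) {
    stop("model '", model_ids(models)[is.na(aeds)][1L],
         "' has no AED; score models before selecting training data")
  }
  models[aeds <= aed_threshold]
}

#' Partition gene models into low- and high-GC training sets
#'
#' Models at or below the low peak form the low-GC set and models at or
#' above the high peak form the high-GC set (both boundaries inclusive);
#' models strictly between the cutoffs belong to neither.
#'
#' @param models list of [gene_model()] objects.
#' @param gc a data.frame from [gc_content()] (or a numeric vector named
#'   by transcript id) providing each model's CDS GC percent.
#' @param cutoffs a [gc_cutoffs()] object.
#' @return list with `training_set` elements `low` and `high`.
#' @export
partition_by_gc <- function(models, gc, cutoffs) {
  stopifnot(inherits(cutoffs, "gc_cutoffs"))
  if (is.data.frame(gc)) {
    gcv <- stats::setNames(gc$gc_percent, gc$transcript_id)
  } else {
    gcv <- gc
  }
  ids <- model_ids(models)
  missing <- setdiff(ids, names(gcv))
  if (length(missing) > 0L) {
    stop("no GC record for model '", missing[1L], "'")
  }
  g <- unname(gcv[ids])
  if (anyNA(g)) stop("undefined GC for model '", ids[is.na(g)][1L], "'")
  low <- models[g <= cutoffs$low_peak]
  high <- models[g >= cutoffs$high_peak]
  if (length(low) == 0L && length(high) == 0L) {
    warning("no models at or beyond either GC cutoff; both sets empty")
  }
  list(low = training_set("low_gc", low, provenance = cutoffs),
       high = training_set("high_gc", high, provenance = cutoffs))
}

#' Draw randomized training subsets
#'
#' Three independent subsets of `k` models are sampled without
#' replacement, seeded with `base_seed`, `base_seed + 1` and
#' `base_seed + 2` (Mersenne-Twister with rejection sampling), so results
#' are reproducible across platforms.  The subsets are independent draws
#' and may overlap.
#'
#' @param models list of [gene_model()] objects.
#' @param k subset size, `1 <= k <= length(models)`.
#' @param base_seed integer seed.
#' @return list of three `training_set`s labelled
#'   `standard_random_1..3`.
#' @export
random_training_subsets <- function(models, k, base_seed) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(models)) {
    stop("k must be between 1 and the number of models (",
         length(models), ")")
  }
  lapply(1:3, function(j) {
    seed <- as.integer(base_seed) + j - 1L
    idx <- with_local_seed(seed, sample(length(models), k))
    training_set(paste0("standard_random_", j), models[sort(idx)],
                 provenance = list(seed = seed, k = k))
  })
}

#' Write a training set to disk
#'
#' Emits `<base>.gff3` (canonical dialect), `<base>_ids.txt` (one
#' transcript id per line) and, when `cds` is supplied,
#' `<base>_cds.fasta`.
#'
#' @param ts a `training_set`.
#' @param base file-name prefix.
#' @param dir output directory.
#' @param cds optional [Biostrings::DNAStringSet] of the members' CDS
#'   sequences (subset by member id before writing).
#' @return Named character vector of paths, invisibly.
#' @export
write_training_set <- function(ts, base, dir = ".", cds = NULL) {
  stopifnot(inherits(ts, "training_set"))
  paths <- c()
  p <- file.path(dir, paste0(base, ".gff3"))
  write_gff3(ts$members, p)
  paths["gff3"] <- p
  p <- file.path(dir, paste0(base, "_ids.txt"))
  con <- file(p, open = "wb")
  writeLines(model_ids(ts$members), con, sep = "\n")
  close(con)
  paths["ids"] <- p
  if (!is.null(cds)) {
    keep <- intersect(names(cds), model_ids(ts$members))
    p <- file.path(dir, paste0(base, "_cds.fasta"))
    write_fasta(cds[keep], p)
    paths["cds"] <- p
  }
  invisible(paths)
}
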