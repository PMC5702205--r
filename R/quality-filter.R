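#' Build the evidence/Pfam-supported ("standard") gene list
#'
#' A model is retained when it has some evidence support (AED strictly
#' below 1) or a Pfam domain hit at or below `pfam_cutoff` on its
#' full-sequence e-value.  Models without an AED are treated as
#' unsupported (AED 1) with a warning.
#'
#' @param models list of [gene_model()] objects (or a data.frame with
#'   `transcript_id` and `aed` columns).
#' @param pfam_hits data.frame from [read_domain_table()] (may be
#'   `NULL`).
#' @param pfam_cutoff full-sequence e-value ceiling for domain rescue
#'   (default 1e-10).
#' @return Character vector of retained transcript ids.
#' @export
maker_standard_list <- function(models, pfam_hits = NULL,
                                pfam_cutoff = 1e-10) {
  if (is.data.frame(models)) {
    ids <- models$transcript_id
    aeds <- models$aed
  } else {
    ids <- model_ids(models)
    aeds <- vapply(models, `[[`, 0, "aed")
  }
  if (anyNA(aeds)) {
    warning(sum(is.na(aeds)),
            " model(s) without AED treated as unsupported (AED = 1)")
    aeds[is.na(aeds)] <- 1
  }
  pfam_ok <- character(0)
  if (!is.null(pfam_hits) && nrow(pfam_hits) > 0L) {
    pfam_ok <- unique(
      pfam_hits$query_id[pfam_hits$full_seq_evalue <= pfam_cutoff])
  }
  ids[aeds < 1 | ids %in% pfam_ok]
}

TE_REASONS <- c("gypsy_hit", "transposase_hit", "te_pfam_domain",
                "te_refmap_overlap")

#' Flag and remove transposable-element-related gene models
#'
#' A model is removed when any of four rules fires: a Gypsy domain hit at
#' or below `gypsy_cutoff`; a transposase homology hit at or below
#' `transposase_cutoff`; a Pfam hit, at or below `pfam_cutoff`, whose
#' accession is on the TE domain list; or membership among the query ids
#' of any reference-TE refmap entry (any class code, optionally
#' restricted with `refmap_codes`).  Reasons are accumulated, not
#' short-circuited.
#'
#' @param models list of [gene_model()] objects, or a character vector of
#'   transcript ids (e.g. the output of [maker_standard_list()]).
#' @param te_pfam_domains character vector of TE-associated Pfam
#'   accessions; when empty the domain rule is inert (warning).
#' @param pfam_hits,gypsy_hits data.frames from [read_domain_table()].
#' @param transposase_hits data.frame from [read_homology_table()].
#' @param te_refmap data.frame from [read_refmap()].
#' @param gypsy_cutoff,transposase_cutoff,pfam_cutoff e-value ceilings
#'   (defaults 1e-5, 1e-10, 1e-10); all compare the full-sequence e-value
#'   for domain tables.
#' @param refmap_codes optional class-code whitelist; `NULL` (default)
#'   counts any refmap membership as TE overlap.
#' @return data.frame with one row per model: `transcript_id`, `kept`,
#'   and `reasons` (comma-separated, empty when kept).
#' @export
te_filter <- function(models, te_pfam_domains, pfam_hits = NULL,
                      gypsy_hits = NULL, transposase_hits = NULL,
                      te_refmap = NULL, gypsy_cutoff = 1e-5,
                      transposase_cutoff = 1e-10, pfam_cutoff = 1e-10,
                      refmap_codes = NULL) {
  ids <- if (is.character(models)) models else model_ids(models)
  if (length(te_pfam_domains) == 0L) {
    warning("empty TE Pfam domain list; the TE domain rule is inert")
  }
  gypsy_ids <- character(0)
  if (!is.null(gypsy_hits) && nrow(gypsy_hits) > 0L) {
    gypsy_ids <- unique(
      gypsy_hits$query_id[gypsy_hits$full_seq_evalue <= gypsy_cutoff])
  }
  tpase_ids <- character(0)
  if (!is.null(transposase_hits) && nrow(transposase_hits) > 0L) {
    tpase_ids <- unique(
      transposase_hits$query_id[transposase_hits$evalue <=
                                  transposase_cutoff])
  }
  tepfam_ids <- character(0)
  if (!is.null(pfam_hits) && nrow(pfam_hits) > 0L &&
      length(te_pfam_domains) > 0L) {
    sel <- pfam_hits$domain_accession %in% te_pfam_domains &
      pfam_hits$full_seq_evalue <= pfam_cutoff
    tepfam_ids <- unique(pfam_hits$query_id[sel])
  }
  refmap_ids <- character(0)
  if (!is.null(te_refmap) && nrow(te_refmap) > 0L) {
    keep <- if (is.null(refmap_codes)) rep(TRUE, nrow(te_refmap))
            else te_refmap$class_code %in% refmap_codes
    refmap_ids <- unique(unlist(te_refmap$query_ids[keep]))
  }
  reasons <- vapply(ids, function(id) {
    r <- c(if (id %in% gypsy_ids) "gypsy_hit",
           if (id %in% tpase_ids) "transposase_hit",
           if (id %in% tepfam_ids) "te_pfam_domain",
           if (id %in% refmap_ids) "te_refmap_overlap")
    paste(r, collapse = ",")
  }, "")
  data.frame(transcript_id = ids, kept = !nzchar(reasons),
             reasons = unname(reasons), row.names = NULL)
}
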