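## Readers for the three tabular dialects consumed by the quality filters:
## HMMER3 --tblout, 12-column BLAST tabular (-outfmt 6) and gffcompare
## .refmap files.  All skip '#' comment lines and validate column counts,
## reporting the offending line number on failure.

split_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  list(lines = lines[keep], numbers = keep)
}

#' Read a HMMER3 per-target table (\code{--tblout})
#'
#' @param path path to a tblout file (e.g. from `hmmscan --tblout`).
#' @return data.frame with columns `query_id`, `domain_name`,
#'   `domain_accession`, `full_seq_evalue`, `domain_evalue`.
#' @export
read_domain_table <- function(path) {
  tl <- split_table_lines(path)
  rows <- lapply(seq_along(tl$lines), function(i) {
    f <- strsplit(trimws(tl$lines[i]), "\\s+")[[1L]]
    if (length(f) < 18L) {
      stop("tblout parse error at line ", tl$numbers[i], ": expected >= 18",
           " columns, found ", length(f))
    }
    ev_full <- suppressWarnings(as.numeric(f[5L]))
    ev_dom <- suppressWarnings(as.numeric(f[8L]))
    if (is.na(ev_full) || is.na(ev_dom) || ev_full <= 0 || ev_dom <= 0) {
      stop("tblout parse error at line ", tl$numbers[i],
           ": invalid e-value")
    }
    data.frame(query_id = f[3L], domain_name = f[1L],
               domain_accession = f[2L], full_seq_evalue = ev_full,
               domain_evalue = ev_dom)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE,
                              stringsAsFactors = FALSE)))
}

#' Read a 12-column BLAST tabular file (\code{-outfmt 6})
#'
#' @param path path to a tabular BLAST output file.
#' @return data.frame with the 12 standard columns; the fields used
#'   downstream are `query_id`, `subject_id`, `percent_identity` and
#'   `evalue`.
#' @export
read_homology_table <- function(path) {
  tl <- split_table_lines(path)
  rows <- lapply(seq_along(tl$lines), function(i) {
    f <- strsplit(tl$lines[i], "\t")[[1L]]
    if (length(f) == 1L) f <- strsplit(trimws(tl$lines[i]), "\\s+")[[1L]]
    if (length(f) != 12L) {
      stop("homology table parse error at line ", tl$numbers[i],
           ": expected 12 columns, found ", length(f))
    }
    ev <- suppressWarnings(as.numeric(f[11L]))
    pid <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(ev) || ev <= 0) {
      stop("homology table parse error at line ", tl$numbers[i],
           ": invalid e-value")
    }
    if (is.na(pid) || pid < 0 || pid > 100) {
      stop("homology table parse error at line ", tl$numbers[i],
           ": invalid percent identity")
    }
    data.frame(query_id = f[1L], subject_id = f[2L],
               percent_identity = pid, aln_length = as.integer(f[4L]),
               mismatches = as.integer(f[5L]), gap_opens = as.integer(f[6L]),
               q_start = as.integer(f[7L]), q_end = as.integer(f[8L]),
               s_start = as.integer(f[9L]), s_end = as.integer(f[10L]),
               evalue = ev, bit_score = as.numeric(f[12L]))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE,
                              stringsAsFactors = FALSE)))
}

#' Read a gffcompare .refmap file
#'
#' @param path path to a `.refmap` TSV produced by gffcompare.
#' @return data.frame with columns `ref_gene_id`, `ref_transcript_id`,
#'   `class_code` and a list-column `query_ids` holding the transcript ids
#'   of the matching query models (the part after the last `|` of each
#'   comma-separated entry).
#' @export
read_refmap <- function(path) {
  tl <- split_table_lines(path)
  lines <- tl$lines
  numbers <- tl$numbers
  if (length(lines) > 0L && grepl("class_code", lines[1L])) {
    lines <- lines[-1L]
    numbers <- numbers[-1L]
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) != 4L) {
      stop("refmap parse error at line ", numbers[i],
           ": expected 4 columns, found ", length(f))
    }
    if (nchar(f[3L]) != 1L) {
      stop("refmap parse error at line ", numbers[i],
           ": class code must be a single character")
    }
    qids <- strsplit(f[4L], ",")[[1L]]
    qids <- vapply(strsplit(qids, "\\|"), function(p) p[length(p)], "")
    data.frame(ref_gene_id = f[1L], ref_transcript_id = f[2L],
               class_code = f[3L],
               query_ids = I(list(qids)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE,
                              stringsAsFactors = FALSE)))
}

## Writers for the same dialects; used by the simulator so that fixtures
## can be materialised as the plain-text formats the readers expect.

#' @rdname read_domain_table
#' @param hits data.frame as returned by `read_domain_table`.
#' @export
write_domain_table <- function(hits, path) {
  header <- paste0("#", paste(c("target_name", "accession", "query_name",
                                "accession", "E-value", "score", "bias",
                                "E-value", "score", "bias", "exp", "reg",
                                "clu", "ov", "env", "dom", "rep", "inc"),
                              collapse = " "))
  body <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$domain_name[i], hits$domain_accession[i], hits$query_id[i],
          "-", format(hits$full_seq_evalue[i], digits = 3), "10.0", "0.1",
          format(hits$domain_evalue[i], digits = 3), "9.0", "0.1",
          "1.0", "1", "1", "0", "1", "1", "1", "1")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' @rdname read_homology_table
#' @param hits data.frame as returned by `read_homology_table`.
#' @export
write_homology_table <- function(hits, path) {
  body <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$query_id[i], hits$subject_id[i],
          format(hits$percent_identity[i], nsmall = 1), "100", "5", "1",
          "1", "100", "1", "100", format(hits$evalue[i], digits = 3),
          "200", sep = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' @rdname read_refmap
#' @param entries data.frame as returned by `read_refmap`.
#' @export
write_refmap <- function(entries, path) {
  header <- paste("ref_gene_id", "ref_id", "class_code", "qry_id_list",
                  sep = "\t")
  body <- vapply(seq_len(nrow(entries)), function(i) {
    q <- paste(paste0("q|", entries$query_ids[[i]]), collapse = ",")
    paste(entries$ref_gene_id[i], entries$ref_transcript_id[i],
          entries$class_code[i], q, sep = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
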