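# Sequence, annotation and track I/O; dataset assembly.

AA_ALPHABET <- c(AA20, "X")

#' Read protein sequences from a FASTA file
#'
#' The accession is the first whitespace-delimited header token; Uniprot-style
#' `db|ACC|NAME` headers are reduced to `ACC` (with `NAME` kept as the display
#' name, e.g. `>sp|Q9UKB1|FBXW11_HUMAN` gives accession `Q9UKB1`). Residues are
#' uppercased; any character outside the 20-letter amino-acid alphabet plus X
#' is rejected. CRLF line endings and trailing blank lines are tolerated.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `name`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  first_tok <- vapply(strsplit(headers, "[[:space:]]+"), `[`, "", 1L)
  acc <- first_tok
  nm <- vapply(seq_along(headers), function(i) {
    toks <- strsplit(headers[i], "[[:space:]]+")[[1]]
    if (length(toks) >= 2L) toks[2L] else first_tok[i]
  }, "")
  piped <- grepl("|", first_tok, fixed = TRUE)
  if (any(piped)) {
    parts <- strsplit(first_tok[piped], "|", fixed = TRUE)
    acc[piped] <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
    nm[piped] <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else p[length(p)], "")
  }
  if (anyDuplicated(acc))
    stop("duplicate accession in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non amino-acid characters in sequence(s): ",
         paste(acc[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ", paste(acc[!nzchar(seqs)], collapse = ", "))
  data.frame(accession = unname(acc), name = unname(nm), sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Headers are written as `accession name` (just `accession` when the two are
#' equal), so `write_fasta` composed with [read_fasta()] is the identity on
#' accession, name and sequence.
#'
#' @param records data.frame with `accession`, `name`, `sequence` (as returned
#'   by [read_fasta()]), or a `slim_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "slim_dataset")) records <- records$records
  hdr <- ifelse(records$name == records$accession, records$accession,
                paste(records$accession, records$name))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read per-residue disorder score tracks
#'
#' Expects a TSV with columns `accession`, `position`, `score` (header line
#' optional). Scores must lie in `[0, 1]`; positions must be the contiguous
#' run `1..L` for each accession.
#'
#' @param path TSV file path.
#' @return named list of numeric score vectors, one per accession.
#' @export
read_disorder_tracks <- function(path) {
  df <- read_tsv_flex(path, c("accession", "position", "score"))
  df$position <- as.integer(df$position)
  df$score <- as.numeric(df$score)
  if (anyNA(df$position) || anyNA(df$score))
    stop("malformed disorder track file: ", path)
  if (any(df$score < 0 | df$score > 1))
    stop("disorder scores outside [0,1] in ", path)
  out <- lapply(split(df, df$accession), function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, seq_len(nrow(d))))
      stop("disorder track for ", d$accession[1L],
           " is not a contiguous 1..L run")
    d$score
  })
  out[order(names(out))]
}

#' Write disorder tracks to TSV
#' @param tracks named list of numeric vectors (see [read_disorder_tracks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disorder_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(a) {
    data.frame(accession = a, position = seq_along(tracks[[a]]),
               score = tracks[[a]], stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequence feature annotations
#'
#' Expects a TSV with columns `accession`, `feature_type`, `start`, `end`
#' (1-based inclusive coordinates; header optional). Interval validity against
#' sequence lengths is checked at dataset assembly ([slim_dataset()]).
#'
#' @param path TSV file path.
#' @return data.frame with columns `accession`, `feature_type`, `start`, `end`.
#' @export
read_features <- function(path) {
  df <- read_tsv_flex(path, c("accession", "feature_type", "start", "end"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop("malformed feature file: ", path)
  if (any(df$start < 1L | df$start > df$end))
    stop("invalid feature interval(s) in ", path)
  df$feature_type <- toupper(df$feature_type)
  df
}

#' Write feature annotations to TSV
#' @param features data.frame as returned by [read_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Tolerant TSV reader: optional header, CRLF, trailing blank lines.
read_tsv_flex <- function(path, cols) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  has_header <- identical(tolower(strsplit(lines[1L], "\t")[[1L]][1L]),
                          cols[1L]) ||
    grepl(paste0("^", cols[1L]), tolower(lines[1L]))
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) stop("no data rows in ", path)
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < length(cols)))
    stop("expected ", length(cols), " columns in ", path)
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, seq_along(cols))),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Assemble a protein dataset
#'
#' Bundles sequence records with optional feature annotations, disorder
#' tracks, per-protein orthologue alignments and query accessions, and
#' validates the cross-references: every feature/track/alignment must refer to
#' a record, tracks must have one score per residue, feature intervals must
#' lie inside the sequence, and query accessions must be dataset members.
#'
#' @param records data.frame from [read_fasta()] (or matching shape).
#' @param features optional data.frame from [read_features()].
#' @param disorder optional named list from [read_disorder_tracks()].
#' @param alignments optional named list; each element is a named character
#'   vector of aligned (equal-length, gapped with `-`) orthologue rows which
#'   must include the protein itself under its accession.
#' @param query optional character vector of query accessions.
#' @return object of class `slim_dataset`.
#' @export
slim_dataset <- function(records, features = NULL, disorder = NULL,
                         alignments = NULL, query = character(0)) {
  stopifnot(is.data.frame(records),
            all(c("accession", "name", "sequence") %in% names(records)))
  records$length <- nchar(records$sequence)
  if (anyDuplicated(records$accession))
    stop("duplicate accession: ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "))
  if (any(records$length == 0L)) stop("empty sequence in records")
  len <- stats::setNames(records$length, records$accession)
  if (!is.null(features) && nrow(features)) {
    unknown <- setdiff(features$accession, records$accession)
    if (length(unknown))
      stop("features reference unknown accession(s): ",
           paste(unknown, collapse = ", "))
    if (any(features$end > len[features$accession]))
      stop("feature interval extends beyond sequence end")
  }
  if (!is.null(disorder)) {
    unknown <- setdiff(names(disorder), records$accession)
    if (length(unknown))
      stop("disorder tracks reference unknown accession(s): ",
           paste(unknown, collapse = ", "))
    bad <- names(disorder)[lengths(disorder) != len[names(disorder)]]
    if (length(bad))
      stop("disorder track length mismatch for: ", paste(bad, collapse = ", "))
  }
  if (!is.null(alignments)) {
    unknown <- setdiff(names(alignments), records$accession)
    if (length(unknown))
      stop("alignments reference unknown accession(s): ",
           paste(unknown, collapse = ", "))
  }
  if (length(query)) {
    unknown <- setdiff(query, records$accession)
    if (length(unknown))
      stop("query accession(s) not in dataset: ", paste(unknown, collapse = ", "))
  }
  structure(list(records = records,
                 features = if (is.null(features))
                   data.frame(accession = character(0), feature_type = character(0),
                              start = integer(0), end = integer(0)) else features,
                 disorder = disorder,
                 alignments = alignments,
                 query = query,
                 planted = NULL),
            class = "slim_dataset")
}

#' @export
print.slim_dataset <- function(x, ...) {
  cat(sprintf("slim_dataset: %d proteins (%d-%d aa)\n", nrow(x$records),
              min(x$records$length), max(x$records$length)))
  cat(sprintf("  features: %d  disorder tracks: %d  alignments: %d  query: %s\n",
              nrow(x$features),
              if (is.null(x$disorder)) 0L else length(x$disorder),
              if (is.null(x$alignments)) 0L else length(x$alignments),
              if (length(x$query)) paste(x$query, collapse = ",") else "none"))
  if (!is.null(x$planted))
    cat(sprintf("  planted motif instances: %d\n", nrow(x$planted)))
  invisible(x)
}
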