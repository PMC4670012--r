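# Disorder, feature and conservation masking. A masked sequence carries a
# boolean mask track (TRUE = masked), the X-rendered text, and the effective
# residue composition over unmasked residues.

#' Construct a masked sequence
#'
#' @param record one-row data.frame (accession, name, sequence) or a list with
#'   those fields.
#' @param mask logical vector, one element per residue; `TRUE` = masked.
#' @return object of class `masked_seq` with fields `accession`, `name`,
#'   `sequence` (original), `mask`, `masked_text` (masked residues rendered as
#'   `X`), `composition` (frequencies over the 20 amino acids among unmasked
#'   residues; `X` residues are excluded), and `effective_length` (number of
#'   unmasked residues).
#' @export
masked_sequence <- function(record, mask = NULL) {
  if (inherits(record, "masked_seq")) return(record)
  seq <- record$sequence
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  L <- nchar(seq)
  if (is.null(mask)) mask <- rep(FALSE, L)
  stopifnot(is.logical(mask), length(mask) == L)
  s <- strsplit(seq, "")[[1L]]
  masked <- s
  masked[mask] <- "X"
  unmasked <- s[!mask & s != "X"]
  comp <- tabulate(factor(unmasked, levels = AA20), nbins = 20L)
  comp <- if (length(unmasked)) comp / length(unmasked) else rep(0, 20L)
  names(comp) <- AA20
  structure(list(accession = record$accession,
                 name = if (!is.null(record$name)) record$name else record$accession,
                 sequence = seq,
                 mask = mask,
                 masked_text = paste(masked, collapse = ""),
                 composition = comp,
                 effective_length = sum(!mask)),
            class = "masked_seq")
}

#' @export
print.masked_seq <- function(x, ...) {
  cat(sprintf("masked_seq %s: %d aa, %d masked (%.1f%%)\n", x$accession,
              nchar(x$sequence), sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Disorder masking
#'
#' Masks residues whose disorder score falls below `iucut` (default 0.2):
#' motif evidence is only accepted from predicted-disordered sequence. The
#' inequality is strict, so `iucut = 0` masks nothing.
#'
#' @param record protein record (see [masked_sequence()]).
#' @param track numeric disorder scores in `[0,1]`, one per residue.
#' @param iucut masking threshold.
#' @return `masked_seq`.
#' @export
mask_disorder <- function(record, track, iucut = 0.2) {
  if (is.null(track))
    stop("disorder masking requested without track for ", record$accession)
  L <- nchar(record$sequence)
  if (length(track) != L)
    stop("disorder track length mismatch for ", record$accession)
  masked_sequence(record, track < iucut)
}

#' Feature masking
#'
#' Masks residues falling inside any annotated interval whose type is listed
#' in `ftmask` (default: globular domains and transmembrane segments, i.e.
#' `DOMAIN` and `TRANSMEM`). Types are matched case-insensitively; a type in
#' `ftmask` that never occurs in the annotation yields a warning, not an
#' error.
#'
#' @param record protein record.
#' @param features feature data.frame (see [read_features()]); rows for other
#'   accessions are ignored.
#' @param ftmask character vector of feature types to mask.
#' @return `masked_seq`.
#' @export
mask_features <- function(record, features, ftmask = c("DOMAIN", "TRANSMEM")) {
  L <- nchar(record$sequence)
  mask <- rep(FALSE, L)
  ftmask <- toupper(ftmask)
  if (length(ftmask) && nrow(features)) {
    f <- features[features$accession == record$accession &
                    toupper(features$feature_type) %in% ftmask, , drop = FALSE]
    unknown <- setdiff(ftmask, unique(toupper(features$feature_type)))
    if (length(unknown) && nrow(features))
      warning("feature type(s) never seen in annotation: ",
              paste(unknown, collapse = ", "))
    if (nrow(f)) {
      if (any(f$end > L)) stop("feature interval beyond sequence end for ",
                               record$accession)
      for (r in seq_len(nrow(f))) mask[f$start[r]:f$end[r]] <- TRUE
    }
  }
  masked_sequence(record, mask)
}

#' Relative local conservation masking
#'
#' Per-residue conservation `s_i` is the fraction of non-gap orthologue rows
#' matching the query residue at that alignment column. The relative local
#' conservation is a windowed z-score: `r_i = (s_i - mean(s, window)) /
#' sd(s, window)` over a centred window (truncated at the termini), with the
#' standard deviation floored at 1e-6 so uniformly conserved windows give
#' `r_i = 0`. Residues with `r_i < 0` — conserved less than their local
#' context — are masked.
#'
#' @param record protein record.
#' @param alignment named character vector of equal-length aligned rows,
#'   including the query under its accession; gaps are `-`.
#' @param window window width in alignment-resolved residues (default 30).
#' @return `masked_seq`.
#' @export
mask_conservation <- function(record, alignment, window = 30L) {
  acc <- record$accession
  if (is.null(alignment) || !acc %in% names(alignment))
    stop("orthologue alignment lacking the query sequence ", acc)
  rows <- toupper(alignment)
  width <- unique(nchar(rows))
  if (length(width) != 1L) stop("alignment rows differ in length for ", acc)
  qrow <- strsplit(rows[[acc]], "")[[1L]]
  qcols <- which(qrow != "-")
  ungapped <- paste(qrow[qcols], collapse = "")
  if (!identical(ungapped, toupper(record$sequence)))
    stop("alignment row for ", acc, " does not match its sequence")
  orth <- rows[setdiff(names(rows), acc)]
  L <- length(qcols)
  if (length(orth) == 0L) {
    warning("no orthologues for ", acc, "; conservation undefined, nothing masked")
    return(masked_sequence(record, rep(FALSE, L)))
  }
  om <- do.call(rbind, strsplit(unname(orth), ""))[, qcols, drop = FALSE]
  qres <- qrow[qcols]
  nongap <- om != "-"
  matches <- sweep(om, 2L, qres, "==") & nongap
  denom <- colSums(nongap)
  s <- ifelse(denom > 0, colSums(matches) / pmax(denom, 1L), 0)
  half <- window %/% 2L
  r <- vapply(seq_len(L), function(i) {
    idx <- max(1L, i - half):min(L, i + half)
    (s[i] - mean(s[idx])) / max(stats::sd(s[idx]), 1e-6)
  }, 0)
  masked_sequence(record, r < 0)
}

#' Compose masks by union
#'
#' Unions the masked sets of several maskings of the same sequence and
#' recomputes composition and effective length. Union semantics make masking
#' idempotent and order-independent.
#'
#' @param record protein record.
#' @param masks list of `masked_seq` objects or logical mask vectors.
#' @return `masked_seq`.
#' @export
compose_masks <- function(record, masks) {
  L <- nchar(record$sequence)
  mask <- rep(FALSE, L)
  for (m in masks) {
    v <- if (inherits(m, "masked_seq")) m$mask else m
    stopifnot(is.logical(v), length(v) == L)
    mask <- mask | v
  }
  masked_sequence(record, mask)
}

# Apply the masking switches of a discovery config to every record of a
# dataset; returns a named list of masked_seq.
mask_dataset <- function(dataset, config) {
  recs <- dataset$records
  out <- vector("list", nrow(recs))
  names(out) <- recs$accession
  for (i in seq_len(nrow(recs))) {
    record <- as.list(recs[i, ])
    masks <- list()
    if (isTRUE(config$dismask)) {
      track <- dataset$disorder[[record$accession]]
      masks <- c(masks, list(mask_disorder(record, track, iucut = config$iucut)))
    }
    if (isTRUE(config$ftmask_on) && length(config$ftmask))
      masks <- c(masks, list(suppressWarnings(
        mask_features(record, dataset$features, ftmask = config$ftmask))))
    if (isTRUE(config$consmask)) {
      aln <- dataset$alignments[[record$accession]]
      masks <- c(masks, list(mask_conservation(record, aln,
                                               window = config$conswindow)))
    }
    out[[i]] <- compose_masks(record, masks)
  }
  out
}
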