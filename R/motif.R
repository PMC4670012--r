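# SLiM regular expressions: parsing, information content, matching.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T",
          "V","W","Y")

#' Parse a SLiM regular expression
#'
#' SLiM patterns are a restricted protein regular-expression dialect: fixed
#' residues (`D`), ambiguity classes (`[ST]`), wildcards (`.`) with optional
#' repeat counts (`.{2}`) or ranges (`.{2,3}`), and optional `^`/`$` anchors.
#' `DSG.{2,3}[ST]` reads "D, S, G, two or three wildcards, then serine or
#' threonine". Whitespace is not permitted anywhere in a pattern.
#'
#' @param text pattern string, e.g. `"DSG.{2,3}[ST]"`.
#' @param name optional motif name carried through to result tables.
#' @return an object of class `slim_motif` with elements:
#'   `source_text`, `name`, `elements` (list of per-element lists with `kind`
#'   (`"fixed"`, `"class"` or `"wildcard"`), `allowed`, `min`, `max`),
#'   `n_defined` (number of non-wildcard elements), `anchor_start`,
#'   `anchor_end`, `variants` (fixed-length expansions, see Details) and `ic`.
#' @details Variable wildcard repeats are expanded into fixed-length variants:
#'   `DSG.{2,3}[ST]` has two variants, of lengths 6 and 7. Matching and
#'   occurrence probabilities operate per variant. Negated classes (`[^..]`)
#'   are not part of the dialect and are rejected.
#' @examples
#' m <- parse_motif("DSG.{2,3}[ST]")
#' m$n_defined   # 4
#' m$ic          # 3 + (1 - log(2)/log(20))
#' @export
parse_motif <- function(text, name = NULL, .allow_no_defined = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("motif pattern must be a non-empty string")
  if (grepl("[[:space:]]", text))
    stop("whitespace is not permitted in motif patterns: ", sQuote(text))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  i <- 1L
  anchor_start <- FALSE
  anchor_end <- FALSE
  if (chars[1L] == "^") { anchor_start <- TRUE; i <- 2L }
  elements <- list()
  bad <- function(msg, off) {
    stop(sprintf("motif parse error at offset %d in %s: %s", off, sQuote(text), msg))
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "$") {
      if (i != n) bad("'$' only allowed at the end", i)
      anchor_end <- TRUE
      i <- i + 1L
    } else if (ch == "^") {
      bad("'^' only allowed at the start", i)
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <-
        list(kind = "fixed", allowed = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      if (j <= n && chars[j] == "^") bad("negated classes are not supported", j)
      cls <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% AA20) bad(sprintf("illegal class character '%s'", chars[j]), j)
        cls <- c(cls, chars[j])
        j <- j + 1L
      }
      if (j > n) bad("unbalanced '['", i)
      if (length(cls) == 0L) bad("empty class", i)
      elements[[length(elements) + 1L]] <-
        list(kind = "class", allowed = unique(cls), min = 1L, max = 1L)
      i <- j + 1L
    } else if (ch == ".") {
      minr <- 1L; maxr <- 1L
      i <- i + 1L
      if (i <= n && chars[i] == "{") {
        j <- i + 1L
        while (j <= n && chars[j] != "}") j <- j + 1L
        if (j > n) bad("unbalanced '{'", i)
        body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        if (grepl("^[0-9]+$", body)) {
          minr <- maxr <- as.integer(body)
        } else if (grepl("^[0-9]+,[0-9]+$", body)) {
          parts <- as.integer(strsplit(body, ",")[[1]])
          minr <- parts[1L]; maxr <- parts[2L]
        } else bad(sprintf("bad repeat '{%s}'", body), i)
        if (minr > maxr) bad(sprintf("repeat min %d exceeds max %d", minr, maxr), i)
        i <- j + 1L
      }
      elements[[length(elements) + 1L]] <-
        list(kind = "wildcard", allowed = AA20, min = minr, max = maxr)
    } else {
      bad(sprintf("illegal character '%s'", ch), i)
    }
  }
  if (length(elements) == 0L) bad("pattern has no elements", n)
  n_defined <- sum(vapply(elements, function(e) e$kind != "wildcard", TRUE))
  if (n_defined < 1L && !.allow_no_defined)
    stop("motif must contain at least one defined (non-wildcard) position: ",
         sQuote(text))
  m <- structure(list(
    source_text = text,
    name = if (is.null(name)) text else name,
    elements = elements,
    n_defined = n_defined,
    anchor_start = anchor_start,
    anchor_end = anchor_end
  ), class = "slim_motif")
  m$variants <- motif_variants(m)
  m$ic <- information_content(m)
  m
}

# Expand variable wildcard repeats into fixed-length variants. Each variant is
# a list of per-position allowed-residue sets (wildcards as NULL = any).
motif_variants <- function(m) {
  per_elem <- lapply(m$elements, function(e) {
    if (e$kind == "wildcard") {
      lapply(e$min:e$max, function(r) rep(list(NULL), r))
    } else {
      list(list(e$allowed))
    }
  })
  variants <- list(list())
  for (choices in per_elem) {
    variants <- unlist(lapply(variants, function(v) {
      lapply(choices, function(ch) c(v, ch))
    }), recursive = FALSE)
  }
  variants
}

#' Information content of a SLiM pattern
#'
#' Each non-wildcard element contributes `1 - log(|allowed|)/log(20)`: a fixed
#' residue scores 1, a two-residue class like `[ST]` scores
#' `1 - log(2)/log(20)`, and wildcards contribute nothing. The total lies in
#' `[0, n_defined]`. This per-position base-20 normalisation is this package's
#' declared definition of the IC column of result tables.
#'
#' @param m a `slim_motif` or a pattern string.
#' @return non-negative numeric scalar.
#' @export
information_content <- function(m) {
  if (is.character(m)) m <- parse_motif(m, .allow_no_defined = TRUE)
  sum(vapply(m$elements, function(e) {
    if (e$kind == "wildcard") 0 else 1 - log(length(e$allowed)) / log(20)
  }, 0))
}

# Translate one fixed-length variant to a PCRE character-class string.
# Defined positions never match the mask letter X; wildcards match any
# uppercase letter including X (masking excludes defined-position evidence,
# not spacers crossing masked residues).
variant_regex <- function(variant) {
  paste(vapply(variant, function(allowed) {
    if (is.null(allowed)) "[A-Z]"
    else if (length(allowed) == 1L) allowed
    else paste0("[", paste(allowed, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Find all occurrences of a motif in a (masked) sequence
#'
#' Scans every fixed-length variant of the pattern at every start position.
#' Overlapping occurrences are all reported; two variants matching the same
#' `(start, end)` span count once. Masked residues are expected to be rendered
#' as `X`: defined positions never match `X`, wildcard positions do.
#'
#' @param m a `slim_motif` or pattern string.
#' @param sequence a character string (typically `masked_text` of a
#'   [masked_sequence()]), or a `masked_seq` object.
#' @param accession accession recorded in the result (defaults to the masked
#'   sequence's accession, or `NA`).
#' @return data.frame with columns `accession`, `motif`, `pattern`, `start`,
#'   `end`, `match`, sorted by `(start, end)`.
#' @examples
#' find_occurrences("DSG.{2,3}[ST]", "ADSGILSTY")  # spans (2,7) and (2,8)
#' @export
find_occurrences <- function(m, sequence, accession = NA_character_) {
  if (is.character(m)) m <- parse_motif(m)
  if (inherits(sequence, "masked_seq")) {
    if (is.na(accession)) accession <- sequence$accession
    sequence <- sequence$masked_text
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  starts <- integer(0); ends <- integer(0)
  for (v in m$variants) {
    w <- length(v)
    if (w > L) next
    rx <- paste0("(?=", variant_regex(v), ")")
    hit <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    if (hit[1L] == -1L) next
    s <- as.integer(hit)
    if (m$anchor_start) s <- s[s == 1L]
    e <- s + w - 1L
    if (m$anchor_end) { keep <- e == L; s <- s[keep]; e <- e[keep] }
    starts <- c(starts, s); ends <- c(ends, e)
  }
  if (length(starts)) {
    keep <- !duplicated(paste(starts, ends))
    starts <- starts[keep]; ends <- ends[keep]
    o <- order(starts, ends)
    starts <- starts[o]; ends <- ends[o]
  }
  data.frame(
    accession = rep(accession, length(starts)),
    motif = rep(m$name, length(starts)),
    pattern = rep(m$source_text, length(starts)),
    start = starts, end = ends,
    match = if (length(starts)) substring(sequence, starts, ends) else character(0),
    stringsAsFactors = FALSE
  )
}

#' Parse a motif list
#'
#' Accepts a comma-separated string of patterns (`"DSG,DSG.{2,3}[ST]"`) or a
#' path to a one-per-line file whose lines are either a bare pattern or
#' `name whitespace pattern`.
#'
#' @param x character scalar: comma-separated patterns, or a file path.
#' @return list of `slim_motif` objects.
#' @export
parse_motif_list <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x) && !grepl(",", x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    specs <- lapply(lines, function(ln) {
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(parts) == 1L) list(name = NULL, pattern = parts[1L])
      else list(name = parts[1L], pattern = parts[2L])
    })
  } else {
    pats <- trimws(split_outside_braces(x))
    pats <- pats[nzchar(pats)]
    specs <- lapply(pats, function(p) list(name = NULL, pattern = p))
  }
  if (length(specs) == 0L) stop("no motifs supplied")
  bad <- character(0)
  out <- list()
  for (sp in specs) {
    m <- tryCatch(parse_motif(sp$pattern, name = sp$name), error = function(e) e)
    if (inherits(m, "error")) bad <- c(bad, sp$pattern) else out[[length(out) + 1L]] <- m
  }
  if (length(bad))
    stop("unparsable motif pattern(s): ", paste(sQuote(bad), collapse = ", "))
  out
}

# Split a comma-separated motif list on commas that are not inside {m,n}
# repeats or [..] classes.
split_outside_braces <- function(x) {
  chars <- strsplit(x, "")[[1L]]
  depth <- 0L
  out <- character(0)
  buf <- character(0)
  for (ch in chars) {
    if (ch %in% c("{", "[")) depth <- depth + 1L
    if (ch %in% c("}", "]")) depth <- max(0L, depth - 1L)
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  c(out, paste(buf, collapse = ""))
}

#' @export
print.slim_motif <- function(x, ...) {
  cat(sprintf("SLiM pattern %s (%s)\n", sQuote(x$source_text), x$name))
  cat(sprintf("  defined positions: %d  variants: %d  IC: %.4f\n",
              x$n_defined, length(x$variants), x$ic))
  invisible(x)
}
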