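# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T",
          "V","W","Y")

# Brute-force motif matcher: enumerate every fixed-length variant at every
# start and check residues position by position. Independent of the regex
# machinery inside find_occurrences.
bf_find <- function(m, text) {
  if (is.character(m)) m <- parse_motif(m)
  s <- strsplit(text, "")[[1L]]
  L <- length(s)
  hits <- NULL
  for (v in m$variants) {
    w <- length(v)
    if (w > L) next
    starts <- if (m$anchor_start) 1L else seq_len(L - w + 1L)
    for (st in starts) {
      en <- st + w - 1L
      if (m$anchor_end && en != L) next
      ok <- TRUE
      for (q in seq_len(w)) {
        allowed <- v[[q]]
        if (is.null(allowed)) next           # wildcard: any letter incl. X
        if (!s[st + q - 1L] %in% allowed) { ok <- FALSE; break }
      }
      if (ok) hits <- rbind(hits, c(st, en))
    }
  }
  if (is.null(hits)) return(matrix(integer(0), ncol = 2L))
  hits <- unique(hits)
  hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
}

# Exhaustive Poisson-binomial tails by 2^n enumeration.
bf_poisbin <- function(probs, k) {
  n <- length(probs)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1, probs, 1 - probs)))
  X <- rowSums(outcomes)
  list(p_ge = sum(pr[X >= k]), p_le = sum(pr[X <= k]))
}

# Transitive-closure connected components on an accession edge list.
bf_components <- function(accs, edges) {
  n <- length(accs)
  M <- diag(TRUE, n)
  rownames(M) <- colnames(M) <- accs
  if (nrow(edges)) {
    M[cbind(edges$accession_a, edges$accession_b)] <- TRUE
    M[cbind(edges$accession_b, edges$accession_a)] <- TRUE
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M > 0)) break
    M <- M2
  }
  comp <- lapply(seq_len(n), function(i) sort(accs[M[i, ]]))
  comp <- unique(comp)
  comp[order(vapply(comp, `[`, "", 1L))]
}

# Random sequence over the 20-letter alphabet (optionally with some X).
random_seq <- function(L, x_frac = 0) {
  pool <- AA20
  s <- sample(pool, L, replace = TRUE)
  if (x_frac > 0) {
    nx <- rbinom(1L, L, x_frac)
    if (nx > 0) s[sample.int(L, nx)] <- "X"
  }
  paste(s, collapse = "")
}

# Random SLiM pattern: n_def defined positions (fixed or small class),
# separated by wildcard runs (exact or {m,n} ranges).
random_pattern <- function(n_def = sample(2:4, 1L), classes = TRUE,
                           ranges = TRUE, distinct = FALSE) {
  letters_pool <- if (distinct) sample(AA20, n_def) else
    sample(AA20, n_def, replace = TRUE)
  parts <- character(0)
  for (i in seq_len(n_def)) {
    el <- if (classes && runif(1) < 0.3) {
      cls <- unique(c(letters_pool[i], sample(AA20, sample(1:3, 1L))))
      paste0("[", paste(cls, collapse = ""), "]")
    } else letters_pool[i]
    parts <- c(parts, el)
    if (i < n_def) {
      if (ranges && runif(1) < 0.4) {
        m <- sample(0:2, 1L); n <- m + sample(1:2, 1L)
        parts <- c(parts, sprintf(".{%d,%d}", m, n))
      } else {
        parts <- c(parts, strrep(".", sample(0:2, 1L)))
      }
    }
  }
  paste(parts, collapse = "")
}

# A tiny hand-built dataset of unrelated sequences sharing a planted word.
toy_records <- function(seqs, prefix = "P") {
  data.frame(accession = paste0(prefix, seq_along(seqs)),
             name = paste0(prefix, seq_along(seqs)),
             sequence = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

unmasked_list <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i)
    masked_sequence(as.list(records[i, ])))
  names(out) <- records$accession
  out
}

# Singleton-UPC partition over records (no homology edges).
singleton_upc <- function(records) {
  cluster_upc(records, data.frame(accession_a = character(0),
                                  accession_b = character(0),
                                  evalue = numeric(0), bitscore = numeric(0),
                                  stringsAsFactors = FALSE))
}
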