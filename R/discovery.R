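# The discovery engines: de novo motif discovery, query-restricted discovery,
# and known-motif occurrence/enrichment search.

#' Discovery configuration
#'
#' Collects the tunable parameters of the discovery engines. Defaults follow
#' the conventional settings for short-linear-motif discovery: up to 5 defined
#' positions, wildcard spacers up to 2, candidate motifs must recur in at
#' least 3 unrelated protein clusters, disorder masking at score < 0.2 and
#' feature masking of DOMAIN/TRANSMEM intervals are on, conservation masking
#' is off (it requires user-supplied orthologue alignments).
#'
#' @param max_defined maximum defined (non-wildcard) positions per motif.
#' @param max_wildcard maximum consecutive wildcard spacer length (0-9).
#' @param min_upc_support minimum number of distinct UPCs a candidate must
#'   occur in to be scored.
#' @param ambiguity if `TRUE`, defined positions may generalise to their
#'   equivalence group when that raises UPC support.
#' @param equivalence_groups residue equivalence classes used by `ambiguity`.
#' @param sig_cutoff significance threshold for reporting.
#' @param dismask,iucut disorder masking switch and threshold.
#' @param ftmask_on,ftmask feature masking switch and feature types masked.
#' @param consmask,conswindow conservation masking switch and window.
#' @param upc_mode how UPC probabilities aggregate member sequences:
#'   `"max"` (cluster behaves as its most motif-prone member; invariant to
#'   homolog copies) or `"independent"`.
#' @param evalue_cut homology E-value threshold for UPC construction.
#' @param problen `"full"` or `"masked"`: length used for candidate start
#'   counts in occurrence probabilities.
#' @param compmask `"seq"` (per-sequence unmasked composition) or `"pool"`
#'   (dataset-wide pooled composition applied to every sequence).
#' @param seed integer recorded in run metadata and used for any stochastic
#'   step (the core pipeline is deterministic).
#' @return list of class `slim_config`.
#' @export
slim_config <- function(max_defined = 5L, max_wildcard = 2L,
                        min_upc_support = 3L, ambiguity = FALSE,
                        equivalence_groups = c("ILMV", "KR", "DE", "ST", "FYW"),
                        sig_cutoff = 0.05,
                        dismask = TRUE, iucut = 0.2,
                        ftmask_on = TRUE, ftmask = c("DOMAIN", "TRANSMEM"),
                        consmask = FALSE, conswindow = 30L,
                        upc_mode = c("max", "independent"),
                        evalue_cut = 1e-4,
                        problen = c("full", "masked"),
                        compmask = c("seq", "pool"),
                        seed = 1L) {
  stopifnot(max_defined >= 2L, max_wildcard >= 0L, max_wildcard <= 9L,
            min_upc_support >= 1L, sig_cutoff > 0, sig_cutoff <= 1,
            iucut >= 0, evalue_cut > 0)
  structure(list(max_defined = as.integer(max_defined),
                 max_wildcard = as.integer(max_wildcard),
                 min_upc_support = as.integer(min_upc_support),
                 ambiguity = isTRUE(ambiguity),
                 equivalence_groups = equivalence_groups,
                 sig_cutoff = sig_cutoff,
                 dismask = isTRUE(dismask), iucut = iucut,
                 ftmask_on = isTRUE(ftmask_on), ftmask = toupper(ftmask),
                 consmask = isTRUE(consmask),
                 conswindow = as.integer(conswindow),
                 upc_mode = match.arg(upc_mode),
                 evalue_cut = evalue_cut,
                 problen = match.arg(problen),
                 compmask = match.arg(compmask),
                 seed = as.integer(seed)),
            class = "slim_config")
}

#' Apply `key=value` custom parameters to a configuration
#'
#' Accepts the compact command-style parameter strings, e.g.
#' `"iucut=0.3 ftmask=DOMAIN,TRANSMEM maxwild=1"`. Pairs are separated by
#' whitespace and/or commas; a comma-separated value list (as in `ftmask`)
#' is recognised because continuation tokens contain no `=`. Keys are
#' case-insensitive. Unknown keys raise an error listing the supported keys;
#' `orthdb` is recognised but rejected (orthologue retrieval is out of scope —
#' supply alignments directly).
#'
#' @param config a [slim_config()].
#' @param text custom parameter string (may be empty).
#' @return updated `slim_config`.
#' @export
apply_custom_params <- function(config, text) {
  stopifnot(inherits(config, "slim_config"))
  if (is.null(text) || !nzchar(trimws(text))) return(config)
  toks <- strsplit(trimws(text), "[,[:space:]]+")[[1L]]
  pairs <- list()
  for (tok in toks) {
    if (grepl("=", tok, fixed = TRUE)) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      pairs[[length(pairs) + 1L]] <- list(key = tolower(kv[1L]),
                                          value = paste(kv[-1L], collapse = "="))
    } else if (length(pairs)) {
      pairs[[length(pairs)]]$value <- c(pairs[[length(pairs)]]$value, tok)
    } else stop("malformed custom parameter token: ", sQuote(tok))
  }
  supported <- c("iucut", "ftmask", "dismask", "consmask", "conswindow",
                 "maxdef", "maxwild", "minupc", "sigcut", "upcmode",
                 "ambiguity", "evalcut", "problen", "compmask", "seed")
  as_flag <- function(v) toupper(v[1L]) %in% c("T", "TRUE", "1", "ON", "YES")
  for (p in pairs) {
    key <- p$key; v <- p$value
    switch(key,
      iucut = { config$iucut <- as.numeric(v[1L]) },
      ftmask = {
        if (length(v) == 1L && toupper(v) %in% c("F", "FALSE", "0", "OFF", "NONE")) {
          config$ftmask_on <- FALSE
        } else {
          config$ftmask <- toupper(v); config$ftmask_on <- TRUE
        }
      },
      dismask = { config$dismask <- as_flag(v) },
      consmask = { config$consmask <- as_flag(v) },
      conswindow = { config$conswindow <- as.integer(v[1L]) },
      maxdef = { config$max_defined <- as.integer(v[1L]) },
      maxwild = { config$max_wildcard <- as.integer(v[1L]) },
      minupc = { config$min_upc_support <- as.integer(v[1L]) },
      sigcut = { config$sig_cutoff <- as.numeric(v[1L]) },
      upcmode = { config$upc_mode <- match.arg(tolower(v[1L]),
                                               c("max", "independent")) },
      ambiguity = { config$ambiguity <- as_flag(v) },
      evalcut = { config$evalue_cut <- as.numeric(v[1L]) },
      problen = { config$problen <- match.arg(tolower(v[1L]),
                                              c("full", "masked")) },
      compmask = { config$compmask <- match.arg(tolower(v[1L]),
                                                c("seq", "pool")) },
      seed = { config$seed <- as.integer(v[1L]) },
      orthdb = stop("orthdb is not supported: orthologue retrieval is out of ",
                    "scope; supply per-protein alignments in the dataset instead"),
      stop("unknown custom parameter ", sQuote(key), "; supported keys: ",
           paste(supported, collapse = ", "))
    )
  }
  config
}

#' @export
print.slim_config <- function(x, ...) {
  cat("slim_config:\n")
  cat(sprintf("  motif space: 2-%d defined positions, spacers 0-%d, ambiguity %s\n",
              x$max_defined, x$max_wildcard, if (x$ambiguity) "on" else "off"))
  cat(sprintf("  support: >= %d UPCs  sig cutoff: %g  UPC mode: %s\n",
              x$min_upc_support, x$sig_cutoff, x$upc_mode))
  cat(sprintf("  masking: disorder %s (iucut=%g), features %s (%s), conservation %s\n",
              if (x$dismask) "on" else "off", x$iucut,
              if (x$ftmask_on) "on" else "off", paste(x$ftmask, collapse = ","),
              if (x$consmask) "on" else "off"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# SLiMBuild-style candidate enumeration.
#
# Candidates are grown apriori-style from the data: all defined-position
# dimers with exact wildcard spacers 0..max_wildcard, filtered by UPC support,
# then repeatedly extended rightwards by one defined position. Keys encode the
# exact word as letter/spacer-digit alternation, e.g. "D0S0G" = DSG,
# "D2S" = D..S. Support pruning is valid because extending a word can never
# increase its support.

key_to_pattern <- function(key) {
  chars <- strsplit(key, "")[[1L]]
  out <- character(0)
  for (ch in chars) {
    out <- c(out, if (grepl("[0-9]", ch)) strrep(".", as.integer(ch)) else ch)
  }
  paste(out, collapse = "")
}

key_letters <- function(key) {
  chars <- strsplit(key, "")[[1L]]
  chars[seq(1L, length(chars), by = 2L)]
}

key_spacers <- function(key) {
  chars <- strsplit(key, "")[[1L]]
  if (length(chars) < 3L) return(integer(0))
  as.integer(chars[seq(2L, length(chars) - 1L, by = 2L)])
}

#' Enumerate candidate motifs occurring in a masked dataset
#'
#' Generates every exact-spacer word of 2..`max_defined` defined positions
#' (wildcard spacers of 0..`max_wildcard` between consecutive defined
#' positions) actually present in the unmasked residues of the dataset, and
#' retains those occurring in at least `min_upc_support` distinct Unrelated
#' Protein Clusters. Words sharing defined residues and differing in a single
#' spacer by contiguous amounts additionally yield a merged variable-spacer
#' candidate (e.g. `DSG.{2,3}[ST]`-style `.{m,n}` ranges); with
#' `ambiguity = TRUE`, defined positions may generalise to their equivalence
#' group when that strictly raises UPC support.
#'
#' @param masked_seqs named list of `masked_seq` objects.
#' @param upc a `upc_partition` covering the sequences.
#' @param config a [slim_config()].
#' @return list with `candidates` (data.frame: `key`, `pattern`, `n_defined`,
#'   list-columns `allowed` (per-position residue sets), `var_lens` (variant
#'   lengths), `support_acc`, `support_upc`) and `occurrences` (data.frame
#'   `key`, `accession`, `start`, `end`).
#' @export
slimbuild_enumerate <- function(masked_seqs, upc, config = slim_config()) {
  if (upc$n_upc < config$min_upc_support)
    stop("insufficient unrelated sequences: ", upc$n_upc,
         " UPCs < min_upc_support = ", config$min_upc_support)
  accs <- names(masked_seqs)
  chars <- lapply(masked_seqs, function(ms) strsplit(ms$masked_text, "")[[1L]])
  oks <- lapply(chars, function(s) s != "X")
  memb <- upc$membership
  maxw <- config$max_wildcard

  filter_support <- function(st) {
    # st: list(key, acc, start, end) vectors -> rows whose key meets support
    if (!length(st$key)) return(st)
    pair <- !duplicated(paste0(st$key, "\r", memb[st$acc]))
    counts <- table(st$key[pair])
    keep_keys <- names(counts)[counts >= config$min_upc_support]
    keep <- st$key %in% keep_keys
    lapply(st, `[`, keep)
  }

  # Dimer stage.
  key <- character(0); acc <- character(0); start <- integer(0); end <- integer(0)
  for (a in accs) {
    s <- chars[[a]]; ok <- oks[[a]]; L <- length(s)
    for (w in 0:maxw) {
      i <- seq_len(max(0L, L - 1L - w))
      if (!length(i)) next
      j <- i + 1L + w
      keep <- ok[i] & ok[j]
      if (!any(keep)) next
      i <- i[keep]; j <- j[keep]
      key <- c(key, paste0(s[i], w, s[j]))
      acc <- c(acc, rep(a, length(i)))
      start <- c(start, i); end <- c(end, j)
    }
  }
  current <- filter_support(list(key = key, acc = acc, start = start, end = end))
  stages <- list(current)

  # Extension stages.
  k <- 2L
  while (k < config$max_defined && length(current$key)) {
    ekey <- character(0); eacc <- character(0)
    estart <- integer(0); eend <- integer(0)
    by_acc <- split(seq_along(current$acc), current$acc)
    for (a in names(by_acc)) {
      idx <- by_acc[[a]]
      s <- chars[[a]]; ok <- oks[[a]]; L <- length(s)
      for (w in 0:maxw) {
        j <- current$end[idx] + 1L + w
        keep <- j <= L
        keep[keep] <- ok[j[keep]]
        if (!any(keep)) next
        ii <- idx[keep]; jj <- j[keep]
        ekey <- c(ekey, paste0(current$key[ii], w, s[jj]))
        eacc <- c(eacc, rep(a, length(ii)))
        estart <- c(estart, current$start[ii]); eend <- c(eend, jj)
      }
    }
    current <- filter_support(list(key = ekey, acc = eacc,
                                   start = estart, end = eend))
    stages[[length(stages) + 1L]] <- current
    k <- k + 1L
  }

  occ <- data.frame(key = unlist(lapply(stages, `[[`, "key")),
                    accession = unlist(lapply(stages, `[[`, "acc")),
                    start = unlist(lapply(stages, `[[`, "start")),
                    end = unlist(lapply(stages, `[[`, "end")),
                    stringsAsFactors = FALSE)
  if (nrow(occ)) {
    occ <- occ[!duplicated(paste0(occ$key, "\r", occ$accession, "\r",
                                  occ$start, "\r", occ$end)), , drop = FALSE]
  }
  keys <- sort(unique(occ$key))

  cand <- make_candidates(keys, occ, memb)

  merged <- merge_spacer_ranges(cand, occ, memb)
  cand <- rbind(cand, merged$candidates)
  occ <- rbind(occ, merged$occurrences)

  if (config$ambiguity && nrow(cand)) {
    amb <- ambiguous_candidates(cand, masked_seqs, memb, config)
    cand <- rbind(cand, amb$candidates)
    occ <- rbind(occ, amb$occurrences)
  }
  rownames(cand) <- NULL
  rownames(occ) <- NULL
  list(candidates = cand, occurrences = occ)
}

make_candidates <- function(keys, occ, memb) {
  if (!length(keys))
    return(data.frame(key = character(0), pattern = character(0),
                      n_defined = integer(0),
                      allowed = I(list()), var_lens = I(list()),
                      support_acc = I(list()), support_upc = I(list()),
                      stringsAsFactors = FALSE))
  occ_by_key <- split(occ$accession, occ$key)
  df <- data.frame(key = keys,
                   pattern = vapply(keys, key_to_pattern, ""),
                   n_defined = vapply(keys, function(k) length(key_letters(k)), 0L),
                   stringsAsFactors = FALSE)
  df$allowed <- I(lapply(keys, function(k) as.list(key_letters(k))))
  df$var_lens <- I(lapply(keys, function(k)
    length(key_letters(k)) + sum(key_spacers(k))))
  df$support_acc <- I(lapply(keys, function(k) sort(unique(occ_by_key[[k]]))))
  df$support_upc <- I(lapply(df$support_acc, function(a) sort(unique(memb[a]))))
  df
}

# Merge exact-spacer words into .{m,n} variable-spacer candidates: words with
# identical defined residues and identical spacers except at one position,
# where the observed spacings form a contiguous run of length >= 2, produce an
# additional merged candidate whose occurrences are the union.
merge_spacer_ranges <- function(cand, occ, memb) {
  empty <- list(candidates = cand[0, , drop = FALSE],
                occurrences = occ[0, , drop = FALSE])
  multi <- cand[cand$n_defined >= 2L & lengths(cand$var_lens) == 1L, ,
                drop = FALSE]
  if (!nrow(multi)) return(empty)
  info <- lapply(multi$key, function(k)
    list(letters = key_letters(k), spacers = key_spacers(k)))
  occ_rows_by_key <- split(seq_len(nrow(occ)), occ$key)
  out_c <- list(); out_o <- list()
  nsp <- vapply(info, function(x) length(x$spacers), 0L)
  for (j in sort(unique(nsp[nsp >= 1L]))) {
    idx <- which(nsp == j)
    for (pos in seq_len(j)) {
      sig <- vapply(idx, function(i) {
        sp <- info[[i]]$spacers; sp[pos] <- -1L
        paste(c(info[[i]]$letters, sp), collapse = "|")
      }, "")
      for (grp in split(idx, sig)) {
        if (length(grp) < 2L) next
        vals <- sort(vapply(grp, function(i) info[[i]]$spacers[pos], 0L))
        if (!identical(vals, seq(min(vals), max(vals)))) next
        m <- min(vals); n <- max(vals)
        base <- info[[grp[1L]]]
        sp_txt <- vapply(seq_len(j), function(q) {
          if (q == pos) sprintf(".{%d,%d}", m, n) else strrep(".", base$spacers[q])
        }, "")
        pattern <- paste0(paste0(base$letters[-length(base$letters)], sp_txt,
                                 collapse = ""),
                          base$letters[length(base$letters)])
        mkey <- paste0("rng:", pattern)
        keys_in <- vapply(grp, function(i) multi$key[i], "")
        sub <- occ[unlist(occ_rows_by_key[keys_in], use.names = FALSE), ,
                   drop = FALSE]
        sub <- sub[!duplicated(paste(sub$accession, sub$start, sub$end)), ,
                   drop = FALSE]
        sub$key <- mkey
        acc <- sort(unique(sub$accession))
        spac <- base$spacers; lens <- vapply(vals, function(v) {
          spac[pos] <- v; length(base$letters) + sum(spac)
        }, 0L)
        row <- data.frame(key = mkey, pattern = pattern,
                          n_defined = length(base$letters),
                          stringsAsFactors = FALSE)
        row$allowed <- I(list(as.list(base$letters)))
        row$var_lens <- I(list(sort(lens)))
        row$support_acc <- I(list(acc))
        row$support_upc <- I(list(sort(unique(memb[acc]))))
        out_c[[length(out_c) + 1L]] <- row
        out_o[[length(out_o) + 1L]] <- sub
      }
    }
  }
  if (!length(out_c)) return(empty)
  list(candidates = do.call(rbind, out_c), occurrences = do.call(rbind, out_o))
}

# Ambiguity pass: generalise one defined position of an exact candidate to its
# full equivalence group; keep the generalised candidate iff its UPC support
# strictly exceeds the original's.
ambiguous_candidates <- function(cand, masked_seqs, memb, config) {
  groups <- lapply(config$equivalence_groups, function(g) strsplit(g, "")[[1L]])
  exact <- cand[!grepl("^(rng|amb):", cand$key), , drop = FALSE]
  out_c <- list(); out_o <- list(); seen <- character(0)
  for (i in seq_len(nrow(exact))) {
    letters <- key_letters(exact$key[i])
    spacers <- key_spacers(exact$key[i])
    base_support <- length(exact$support_upc[[i]])
    for (pos in seq_along(letters)) {
      grp <- Filter(function(g) letters[pos] %in% g, groups)
      if (!length(grp)) next
      g <- grp[[1L]]
      parts <- vapply(seq_along(letters), function(q) {
        el <- if (q == pos) paste0("[", paste(g, collapse = ""), "]") else letters[q]
        sp <- if (q < length(letters)) strrep(".", spacers[q]) else ""
        paste0(el, sp)
      }, "")
      pattern <- paste(parts, collapse = "")
      akey <- paste0("amb:", pattern)
      if (akey %in% seen) next
      seen <- c(seen, akey)
      mot <- parse_motif(pattern)
      occs <- do.call(rbind, lapply(names(masked_seqs), function(a)
        find_occurrences(mot, masked_seqs[[a]], accession = a)))
      if (is.null(occs) || !nrow(occs)) next
      support <- length(unique(memb[occs$accession]))
      if (support <= base_support) next
      row <- data.frame(key = akey, pattern = pattern,
                        n_defined = length(letters), stringsAsFactors = FALSE)
      row$allowed <- I(list(lapply(seq_along(letters), function(q)
        if (q == pos) g else letters[q])))
      row$var_lens <- I(list(length(letters) + sum(spacers)))
      row$support_acc <- I(list(sort(unique(occs$accession))))
      row$support_upc <- I(list(sort(unique(memb[occs$accession]))))
      out_c[[length(out_c) + 1L]] <- row
      out_o[[length(out_o) + 1L]] <-
        data.frame(key = akey, accession = occs$accession,
                   start = occs$start, end = occs$end, stringsAsFactors = FALSE)
    }
  }
  if (!length(out_c))
    return(list(candidates = cand[0, , drop = FALSE],
                occurrences = data.frame(key = character(0),
                                         accession = character(0),
                                         start = integer(0), end = integer(0),
                                         stringsAsFactors = FALSE)))
  list(candidates = do.call(rbind, out_c), occurrences = do.call(rbind, out_o))
}

# ---------------------------------------------------------------------------
# Vectorised candidate scoring. Agreement with the scalar reference path
# (sequence_occurrence_probability / upc_probability / poisson_binomial_tails)
# is asserted in the test suite.

score_candidates <- function(cand, masked_seqs, upc, config,
                             exclude_upc = integer(0)) {
  ncand <- nrow(cand)
  accs <- names(masked_seqs)
  clusters <- upc$clusters
  use_cl <- setdiff(seq_along(clusters), exclude_upc)
  n_cl <- length(use_cl)
  if (!ncand)
    return(data.frame(key = character(0), n_occ = integer(0),
                      n_seq = integer(0), n_upc = integer(0),
                      e_upc = numeric(0), p_upc = numeric(0),
                      p_und_upc = numeric(0)))
  comp <- vapply(masked_seqs, function(ms) ms$composition, numeric(20L))
  if (config$compmask == "pool") {
    counts <- vapply(masked_seqs, function(ms)
      ms$composition * ms$effective_length, numeric(20L))
    pooled <- rowSums(counts)
    pooled <- if (sum(pooled) > 0) pooled / sum(pooled) else pooled
    comp <- matrix(pooled, nrow = 20L, ncol = length(masked_seqs),
                   dimnames = dimnames(comp))
  }
  logF <- log(comp)
  Ls <- vapply(masked_seqs, function(ms)
    if (config$problen == "full") nchar(ms$sequence) else ms$effective_length, 0L)
  eff0 <- vapply(masked_seqs, function(ms) ms$effective_length == 0L, TRUE)

  # Per-candidate per-sequence single-variant match probability p_v.
  logP <- matrix(0, ncand, length(accs), dimnames = list(NULL, accs))
  for (i in seq_len(ncand)) {
    acc_lp <- 0
    for (allowed in cand$allowed[[i]]) {
      if (length(allowed) == 1L) acc_lp <- acc_lp + logF[allowed, ]
      else acc_lp <- acc_lp + log(colSums(comp[allowed, , drop = FALSE]))
    }
    logP[i, ] <- acc_lp
  }
  p_v <- pmin(exp(logP), 1 - 1e-15)

  # Total candidate start count across variants.
  n_tot <- t(vapply(seq_len(ncand), function(i) {
    lens <- cand$var_lens[[i]]
    colSums(matrix(pmax(0L, rep(Ls, each = length(lens)) - lens + 1L),
                   nrow = length(lens)))
  }, numeric(length(accs))))

  p_seq <- -expm1(n_tot * log1p(-p_v))
  p_seq[, eff0] <- 0
  p_seq <- pmin(pmax(p_seq, 0), 1)

  # UPC-level probabilities.
  p_cl <- matrix(0, ncand, n_cl)
  for (c_idx in seq_len(n_cl)) {
    members <- clusters[[use_cl[c_idx]]]
    cols <- p_seq[, members, drop = FALSE]
    if (config$upc_mode == "max") {
      p_cl[, c_idx] <- do.call(pmax, as.data.frame(cols))
    } else {
      p_cl[, c_idx] <- pmin(pmax(-expm1(rowSums(log1p(-cols))), 0), 1)
    }
  }

  # Exact Poisson-binomial distribution per candidate (matrix DP over
  # clusters), then inclusive tails at the observed support.
  D <- matrix(0, ncand, n_cl + 1L)
  D[, 1L] <- 1
  for (c_idx in seq_len(n_cl)) {
    p <- p_cl[, c_idx]
    D <- D * (1 - p) + cbind(0, D[, -ncol(D), drop = FALSE] * p)
  }
  k_obs <- vapply(cand$support_upc, function(u)
    length(setdiff(u, exclude_upc)), 0L)
  p_ge <- vapply(seq_len(ncand), function(i)
    sum(D[i, (k_obs[i] + 1L):(n_cl + 1L)]), 0)
  p_le <- vapply(seq_len(ncand), function(i) sum(D[i, 1L:(k_obs[i] + 1L)]), 0)

  data.frame(key = cand$key,
             n_upc = k_obs,
             e_upc = rowSums(p_cl),
             p_upc = pmin(pmax(p_ge, 0), 1),
             p_und_upc = pmin(pmax(p_le, 0), 1),
             stringsAsFactors = FALSE)
}

# Count the distinct exact-spacer words constructible from one masked
# sequence: the size of the query-defined motif space.
query_space_size <- function(mseq, config) {
  s <- strsplit(mseq$masked_text, "")[[1L]]
  L <- length(s)
  ok <- s != "X"
  maxw <- config$max_wildcard
  keys <- character(0)
  current <- data.frame(key = s[which(ok)], end = which(ok),
                        stringsAsFactors = FALSE)
  for (k in 2:config$max_defined) {
    ext <- list()
    for (w in 0:maxw) {
      j <- current$end + 1L + w
      keep <- j <= L
      keep[keep] <- ok[j[keep]]
      if (!any(keep)) next
      ext[[length(ext) + 1L]] <- data.frame(
        key = paste0(current$key[keep], w, s[j[keep]]),
        end = j[keep], stringsAsFactors = FALSE)
    }
    if (!length(ext)) break
    current <- do.call(rbind, ext)
    keys <- c(keys, unique(current$key))
  }
  length(unique(keys))
}

# ---------------------------------------------------------------------------
# Result bundle assembly shared by the engines.

build_result <- function(program, cand, occ, stats, upc, masked_seqs, config,
                         search_space, query = character(0),
                         exclude_upc = integer(0), ranked = TRUE) {
  keep_acc <- unlist(upc$clusters[setdiff(seq_len(upc$n_upc), exclude_upc)])
  occ_counted <- occ[occ$accession %in% keep_acc, , drop = FALSE]
  occ_n <- table(factor(occ_counted$key, levels = cand$key))
  pair <- !duplicated(paste0(occ_counted$key, "\r", occ_counted$accession))
  seq_n <- table(factor(occ_counted$key[pair], levels = cand$key))
  ic <- vapply(seq_len(nrow(cand)), function(i)
    sum(vapply(cand$allowed[[i]], function(a) 1 - log(length(a)) / log(20), 0)),
    0)
  summary <- data.frame(rank = rep(NA_integer_, nrow(cand)),
                        sig = rep(NA_real_, nrow(cand)),
                        motif = if (ranked) rep(NA_character_, nrow(cand))
                                else cand$motif_name,
                        pattern = cand$pattern,
                        ic = ic,
                        n_occ = as.integer(occ_n),
                        n_seq = as.integer(seq_n),
                        n_upc = stats$n_upc,
                        e_upc = stats$e_upc,
                        p_upc = stats$p_upc,
                        p_und_upc = stats$p_und_upc,
                        stringsAsFactors = FALSE)
  if (ranked) {
    summary$sig <- vapply(stats$p_upc, corrected_significance, 0,
                          search_space_size = search_space)
    o <- order(summary$sig, -summary$ic, summary$pattern)
    summary <- summary[o, , drop = FALSE]
    cand_keys <- cand$key[o]
    summary$rank <- seq_len(nrow(summary))
    summary$signif <- summary$sig < config$sig_cutoff
  } else {
    cand_keys <- cand$key
    summary$signif <- NA
  }
  rownames(summary) <- NULL
  key_pattern <- stats::setNames(summary$pattern, cand_keys)
  key_motif <- stats::setNames(
    if (ranked) rep(NA_character_, length(cand_keys)) else summary$motif,
    cand_keys)
  report_keys <- if (ranked) cand_keys[summary$signif] else cand_keys
  occ_rep <- occ[occ$key %in% report_keys, , drop = FALSE]
  occurrences <- data.frame(
    motif = unname(key_motif[occ_rep$key]),
    pattern = unname(key_pattern[occ_rep$key]),
    accession = occ_rep$accession,
    start = occ_rep$start, end = occ_rep$end,
    match = vapply(seq_len(nrow(occ_rep)), function(i)
      substr(masked_seqs[[occ_rep$accession[i]]]$masked_text,
             occ_rep$start[i], occ_rep$end[i]), ""),
    stringsAsFactors = FALSE)
  occurrences <- occurrences[order(match(occ_rep$key, cand_keys),
                                   occurrences$accession, occurrences$start,
                                   occurrences$end), , drop = FALSE]
  rownames(occurrences) <- NULL
  structure(list(program = program,
                 summary = summary,
                 occurrences = occurrences,
                 upc = upc,
                 masked = masked_seqs,
                 config = config,
                 search_space = search_space,
                 query = query,
                 seed = config$seed,
                 timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            class = "slim_result")
}

prepare_run <- function(dataset, config) {
  stopifnot(inherits(dataset, "slim_dataset"))
  masked <- mask_dataset(dataset, config)
  if (all(vapply(masked, function(m) m$effective_length == 0L, TRUE)))
    stop("masking removed every residue of the dataset; ",
         "relax the masking settings")
  edges <- pairwise_homology(dataset, evalue_cut = config$evalue_cut)
  upc <- cluster_upc(dataset, edges)
  list(masked = masked, upc = upc)
}

#' De novo discovery of over-represented short linear motifs
#'
#' Runs the full discovery pipeline: masking, Unrelated Protein Cluster (UPC)
#' construction from pairwise homology, candidate enumeration
#' ([slimbuild_enumerate()]), per-candidate enrichment statistics over UPCs,
#' and significance correction for the size of the enumerable motif space
#' ([motif_space_size()]). Candidates are ranked by ascending significance,
#' ties broken by descending information content then pattern text.
#'
#' @param dataset a [slim_dataset()].
#' @param config a [slim_config()].
#' @return object of class `slim_result`; `$summary` holds one row per scored
#'   candidate (all candidates are retained, with `signif` flagging those
#'   below `sig_cutoff`), `$occurrences` the per-occurrence table for
#'   significant candidates.
#' @seealso [qslimfinder()], [slimprob()]
#' @export
slimfinder <- function(dataset, config = slim_config()) {
  if (nrow(dataset$records) < 3L)
    stop("de novo discovery requires at least 3 sequences")
  prep <- prepare_run(dataset, config)
  enum <- slimbuild_enumerate(prep$masked, prep$upc, config)
  stats <- score_candidates(enum$candidates, prep$masked, prep$upc, config)
  space <- motif_space_size(config$max_defined, config$max_wildcard)
  build_result("slimfinder", enum$candidates, enum$occurrences, stats,
               prep$upc, prep$masked, config, space)
}

#' Query-restricted discovery of short linear motifs
#'
#' Like [slimfinder()], but the motif space is defined by one query protein:
#' only candidates with at least one occurrence in the (masked) query are
#' considered, the significance correction uses the number of distinct
#' patterns constructible from the query sequence, and enrichment statistics
#' are computed over the UPCs excluding the query's own cluster. Restricting
#' the space this way increases sensitivity for motifs shared with the query.
#'
#' @param dataset a [slim_dataset()].
#' @param query query accession; defaults to the dataset's first recorded
#'   query accession. When several are supplied the first (input order) is
#'   used.
#' @param config a [slim_config()].
#' @return `slim_result`; `$summary` statistics exclude the query's UPC, while
#'   `$occurrences` retains query occurrences.
#' @export
qslimfinder <- function(dataset, query = NULL, config = slim_config()) {
  if (is.null(query)) query <- dataset$query
  if (length(query) == 0L) stop("query-restricted discovery requires a query accession")
  query <- query[1L]
  if (!query %in% dataset$records$accession)
    stop("query accession not in dataset: ", query)
  if (nrow(dataset$records) < 3L)
    stop("de novo discovery requires at least 3 sequences")
  prep <- prepare_run(dataset, config)
  enum <- slimbuild_enumerate(prep$masked, prep$upc, config)
  in_query <- vapply(enum$candidates$support_acc, function(a) query %in% a, TRUE)
  cand <- enum$candidates[in_query, , drop = FALSE]
  occ <- enum$occurrences[enum$occurrences$key %in% cand$key, , drop = FALSE]
  q_upc <- unname(prep$upc$membership[query])
  stats <- score_candidates(cand, prep$masked, prep$upc, config,
                            exclude_upc = q_upc)
  space <- max(1L, query_space_size(prep$masked[[query]], config))
  build_result("qslimfinder", cand, occ, stats, prep$upc, prep$masked, config,
               space, query = query, exclude_upc = q_upc)
}

#' Occurrence and enrichment statistics for known motifs
#'
#' Searches the masked dataset for each supplied SLiM regular expression and
#' reports, per motif: occurrence counts (`n_occ`), proteins with at least one
#' occurrence (`n_seq`), Unrelated Protein Clusters with at least one
#' occurrence (`n_upc`), the expected number of clusters containing the motif
#' (`e_upc`), and the exact inclusive tail probabilities `p_upc` =
#' P(X >= n_upc) and `p_und_upc` = P(X <= n_upc) under the Poisson-binomial
#' chance model. Motifs are reported in input order; no ranking or corrected
#' significance applies.
#'
#' @param dataset a [slim_dataset()].
#' @param motifs motif input accepted by [parse_motif_list()], or a list of
#'   `slim_motif` objects.
#' @param config a [slim_config()].
#' @return `slim_result` with `$summary` in input order and the full
#'   `$occurrences` table.
#' @export
slimprob <- function(dataset, motifs, config = slim_config()) {
  if (is.character(motifs)) motifs <- parse_motif_list(motifs)
  if (inherits(motifs, "slim_motif")) motifs <- list(motifs)
  if (!length(motifs)) stop("no motifs supplied")
  prep <- prepare_run(dataset, config)
  masked <- prep$masked
  keys <- vapply(seq_along(motifs), function(i)
    sprintf("m%03d:%s", i, motifs[[i]]$source_text), "")
  occ <- do.call(rbind, lapply(seq_along(motifs), function(i) {
    rows <- do.call(rbind, lapply(names(masked), function(a)
      find_occurrences(motifs[[i]], masked[[a]], accession = a)))
    if (is.null(rows) || !nrow(rows))
      return(data.frame(key = character(0), accession = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE))
    data.frame(key = keys[i], accession = rows$accession, start = rows$start,
               end = rows$end, stringsAsFactors = FALSE)
  }))
  cand <- data.frame(key = keys,
                     pattern = vapply(motifs, `[[`, "", "source_text"),
                     n_defined = vapply(motifs, `[[`, 0L, "n_defined"),
                     stringsAsFactors = FALSE)
  cand$motif_name <- vapply(motifs, `[[`, "", "name")
  cand$allowed <- I(lapply(motifs, function(m)
    lapply(Filter(function(e) e$kind != "wildcard", m$elements), `[[`, "allowed")))
  cand$var_lens <- I(lapply(motifs, function(m) sort(lengths(m$variants))))
  cand$support_acc <- I(lapply(keys, function(k)
    sort(unique(occ$accession[occ$key == k]))))
  cand$support_upc <- I(lapply(cand$support_acc, function(a)
    sort(unique(prep$upc$membership[a]))))
  stats <- score_candidates(cand, masked, prep$upc, config)
  build_result("slimprob", cand, occ, stats, prep$upc, masked, config,
               search_space = 1L, ranked = FALSE)
}

#' @export
print.slim_result <- function(x, max_rows = 10L, ...) {
  cat(sprintf("%s run: %d proteins in %d UPCs; %d motif(s) scored\n",
              x$program, length(x$masked), x$upc$n_upc, nrow(x$summary)))
  if (x$program %in% c("slimfinder", "qslimfinder")) {
    if (length(x$query)) cat("  query:", x$query, "\n")
    cat(sprintf("  correction space: %s patterns\n",
                format(x$search_space, big.mark = ",")))
    sig <- x$summary[which(x$summary$signif), , drop = FALSE]
    cat(sprintf("  significant at sig < %g: %d\n", x$config$sig_cutoff, nrow(sig)))
    show <- utils::head(sig, max_rows)
    if (nrow(show))
      print(show[c("rank", "sig", "pattern", "ic", "n_occ", "n_seq", "n_upc")],
            row.names = FALSE, digits = 4)
  } else {
    print(utils::head(x$summary[c("motif", "pattern", "ic", "n_occ", "n_seq",
                                  "n_upc", "e_upc", "p_upc", "p_und_upc")],
                      max_rows),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.slim_result <- function(object, ...) {
  df <- object$summary
  attr(df, "program") <- object$program
  df
}
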