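# Synthetic dataset generation: benchmark fixtures with a known planted motif,
# optional homolog families, disorder tracks, and orthologue alignments.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic protein dataset
#'
#' Builds a fully reproducible benchmark dataset: `n_seq` unrelated base
#' sequences drawn i.i.d. from an amino-acid composition, an exact fraction of
#' which carry one planted instance of a SLiM pattern at a uniformly chosen
#' position. Each base sequence can additionally receive point-substitution
#' homolog copies at a stated identity (no indels, so planted positions are
#' preserved), per-residue disorder tracks (Beta(2,2) baseline with a plateau
#' of high scores across planted instances, mimicking SLiMs residing in
#' disordered regions), and ungapped orthologue alignments in which planted
#' instances are perfectly conserved.
#'
#' @param n_seq number of unrelated base sequences.
#' @param length_range integer vector of length 2; lengths drawn uniformly.
#' @param composition named numeric vector over the 20 amino acids (need not
#'   sum to 1; normalised internally). Default uniform.
#' @param planted_pattern SLiM pattern string planted verbatim (a fixed-length
#'   variant is sampled per instance, class positions sampled uniformly from
#'   the class, wildcard positions from `composition`), or `NULL` for a null
#'   dataset.
#' @param planted_fraction fraction of base sequences receiving one instance;
#'   the planted count is exactly `round(planted_fraction * n_seq)`.
#' @param n_homolog_copies substitution-only mutated copies per base sequence.
#' @param homolog_identity expected per-residue identity of each copy.
#' @param disorder logical; generate disorder tracks.
#' @param n_orthologues orthologue rows per protein (0 = no alignments).
#' @param orthologue_identity expected identity of orthologue rows outside
#'   planted instances (planted spans are copied unchanged).
#' @param seed integer seed; identical seeds give identical datasets. The
#'   caller's RNG state is left untouched.
#' @return a [slim_dataset()] whose `planted` element records the accession,
#'   start, end and matched string of every planted instance.
#' @export
generate_dataset <- function(n_seq,
                             length_range = c(300L, 300L),
                             composition = NULL,
                             planted_pattern = NULL,
                             planted_fraction = 0,
                             n_homolog_copies = 0L,
                             homolog_identity = 0.95,
                             disorder = TRUE,
                             n_orthologues = 0L,
                             orthologue_identity = 0.6,
                             seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_seq >= 1L, planted_fraction >= 0, planted_fraction <= 1,
            length(length_range) == 2L)
  comp <- normalise_composition(composition)
  pat <- if (!is.null(planted_pattern)) parse_motif(planted_pattern)
  if (!is.null(pat)) {
    min_var <- min(lengths(pat$variants))
    if (min_var > min(length_range))
      stop("planted pattern longer than minimum sequence length")
  }
  with_seed(seed, {
    len_pool <- seq(length_range[1L], length_range[2L])
    lens <- len_pool[sample.int(length(len_pool), n_seq, replace = TRUE)]
    base_acc <- sprintf("SYN%04d", seq_len(n_seq))
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = comp), collapse = ""), "")
    names(seqs) <- base_acc

    n_plant <- round(planted_fraction * n_seq)
    planted <- NULL
    if (n_plant > 0L) {
      if (is.null(pat)) stop("planted_fraction > 0 requires a planted_pattern")
      which_plant <- sort(sample.int(n_seq, n_plant))
      rows <- lapply(which_plant, function(i) {
        v <- pat$variants[[sample.int(length(pat$variants), 1L)]]
        inst <- vapply(v, function(allowed) {
          if (is.null(allowed)) sample(AA20, 1L, prob = comp)
          else if (length(allowed) == 1L) allowed
          else sample(allowed, 1L)
        }, "")
        w <- length(inst)
        start <- sample.int(lens[i] - w + 1L, 1L)
        s <- strsplit(seqs[[i]], "")[[1L]]
        s[start:(start + w - 1L)] <- inst
        seqs[[i]] <<- paste(s, collapse = "")
        data.frame(accession = base_acc[i], start = start,
                   end = start + w - 1L,
                   match = paste(inst, collapse = ""),
                   stringsAsFactors = FALSE)
      })
      planted <- do.call(rbind, rows)
    }

    all_acc <- base_acc
    all_seqs <- seqs
    if (n_homolog_copies > 0L) {
      for (i in seq_len(n_seq)) {
        for (h in seq_len(n_homolog_copies)) {
          acc <- sprintf("%sH%d", base_acc[i], h)
          all_acc <- c(all_acc, acc)
          all_seqs[[acc]] <- mutate_sequence(seqs[[i]], 1 - homolog_identity, comp)
        }
      }
    }

    records <- data.frame(accession = all_acc,
                          name = paste0("G", toupper(all_acc)),
                          sequence = unname(all_seqs[all_acc]),
                          length = nchar(unname(all_seqs[all_acc])),
                          stringsAsFactors = FALSE)

    tracks <- NULL
    if (disorder) {
      tracks <- lapply(stats::setNames(records$accession, records$accession),
                       function(a) stats::rbeta(nchar(all_seqs[[a]]), 2, 2))
      if (!is.null(planted)) {
        for (r in seq_len(nrow(planted))) {
          a <- planted$accession[r]
          idx <- planted$start[r]:planted$end[r]
          tracks[[a]][idx] <- stats::runif(length(idx), 0.5, 0.95)
        }
      }
    }

    alignments <- NULL
    if (n_orthologues > 0L) {
      conserved <- lapply(stats::setNames(records$accession, records$accession),
                          function(a) integer(0))
      if (!is.null(planted)) {
        for (r in seq_len(nrow(planted)))
          conserved[[planted$accession[r]]] <-
            c(conserved[[planted$accession[r]]],
              planted$start[r]:planted$end[r])
      }
      alignments <- lapply(stats::setNames(records$accession, records$accession),
                           function(a) {
        self <- all_seqs[[a]]
        rows <- c(stats::setNames(self, a),
                  stats::setNames(vapply(seq_len(n_orthologues), function(k)
                    mutate_sequence(self, 1 - orthologue_identity, comp,
                                    keep = conserved[[a]]), ""),
                    sprintf("%s_ORTH%d", a, seq_len(n_orthologues))))
        rows
      })
    }

    ds <- slim_dataset(records, disorder = tracks, alignments = alignments)
    ds$planted <- planted
    ds$composition <- comp
    ds
  })
}

normalise_composition <- function(composition) {
  if (is.null(composition))
    return(stats::setNames(rep(1 / 20, 20), AA20))
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  if (!setequal(names(composition), AA20))
    stop("composition must be named by the 20 amino acids")
  if (any(composition < 0) || sum(composition) <= 0)
    stop("composition must be a non-negative distribution")
  composition <- composition[AA20]
  composition / sum(composition)
}

# Point substitutions at the given per-residue rate; positions in `keep` are
# never touched. Substituted residues are redrawn from `comp` excluding the
# original letter, so `rate` is the expected divergence.
mutate_sequence <- function(sequence, rate, comp, keep = integer(0)) {
  s <- strsplit(sequence, "")[[1L]]
  hit <- which(stats::runif(length(s)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) {
    pool <- setdiff(AA20, s[i])
    s[i] <- sample(pool, 1L, prob = comp[pool])
  }
  paste(s, collapse = "")
}
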