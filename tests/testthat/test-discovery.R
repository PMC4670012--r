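# Candidate enumeration and the three discovery engines.

test_that("enumeration equals brute force on a toy dataset", {
  # Five short unrelated sequences; brute-force oracle enumerates every
  # defined-position word with exact spacers and filters by UPC support.
  set.seed(6)
  recs <- toy_records(vapply(1:5, function(i) random_seq(25), ""))
  masked <- unmasked_list(recs)
  upc <- singleton_upc(recs)
  cfg <- slim_config(max_defined = 3L, max_wildcard = 1L,
                     min_upc_support = 2L, dismask = FALSE, ftmask_on = FALSE)
  enum <- slimbuild_enumerate(masked, upc, cfg)

  bf_words <- function(s, maxdef, maxw) {
    ch <- strsplit(s, "")[[1L]]
    L <- length(ch)
    words <- character(0)
    for (st in seq_len(L)) {
      grow <- function(key, pos, ndef) {
        words <<- c(words, if (ndef >= 2L) key else character(0))
        if (ndef == maxdef) return()
        for (w in 0:maxw) {
          nxt <- pos + 1L + w
          if (nxt > L) next
          grow(paste0(key, w, ch[nxt]), nxt, ndef + 1L)
        }
      }
      grow(ch[st], st, 1L)
    }
    unique(words)
  }
  per_seq <- lapply(recs$sequence, bf_words, maxdef = 3L, maxw = 1L)
  counts <- table(unlist(lapply(per_seq, unique)))
  expected <- sort(names(counts)[counts >= 2L])
  got <- sort(enum$candidates$key[!grepl("^(rng|amb):", enum$candidates$key)])
  expect_equal(got, expected)
})

test_that("shared words are retained at the support threshold", {
  recs <- toy_records(c("AAADSGAAAKLM", "CCCDSGCCCNQW", "EEEDSGEEEFHY"))
  masked <- unmasked_list(recs)
  upc <- singleton_upc(recs)
  cfg <- slim_config(dismask = FALSE, ftmask_on = FALSE, max_defined = 3L)
  enum <- slimbuild_enumerate(masked, upc, cfg)
  dsg <- enum$candidates[enum$candidates$key == "D0S0G", ]
  expect_equal(nrow(dsg), 1L)
  expect_equal(dsg$support_upc[[1L]], 1:3)
  # max_wildcard = 0 enumerates only ungapped words
  enum0 <- slimbuild_enumerate(masked, upc,
                               slim_config(dismask = FALSE, ftmask_on = FALSE,
                                           max_wildcard = 0L))
  expect_false(any(grepl("[12]", enum0$candidates$key)))
})

test_that("contiguous spacings of identical flanks merge into ranges", {
  # D.T (spacer 1) in P1, D..T (spacer 2) in P2 and P3: same flanks, so the
  # exact words merge into the range candidate D.{1,2}T supported by all 3.
  recs <- toy_records(c("AADKTAA", "CCDWKTCC", "EEDEETEE"))
  masked <- unmasked_list(recs)
  upc <- singleton_upc(recs)
  cfg <- slim_config(dismask = FALSE, ftmask_on = FALSE,
                     min_upc_support = 1L, max_defined = 3L)
  enum <- slimbuild_enumerate(masked, upc, cfg)
  merged <- enum$candidates[grepl("^rng:", enum$candidates$key), ]
  expect_true("D.{1,2}T" %in% merged$pattern)
  one <- merged[merged$pattern == "D.{1,2}T", ]
  expect_equal(length(one$support_upc[[1L]]), 3L)
  expect_equal(nrow(enum$occurrences[enum$occurrences$key == one$key, ]), 3L)
})

test_that("ambiguity generalises positions only when support grows", {
  # DSG in two sequences, DTG in a third: [ST] generalisation lifts support.
  recs <- toy_records(c("AAADSGAAA", "CCCDSGCCC", "EEEDTGEEE"))
  masked <- unmasked_list(recs)
  upc <- singleton_upc(recs)
  cfg <- slim_config(dismask = FALSE, ftmask_on = FALSE, max_defined = 3L,
                     min_upc_support = 2L, ambiguity = TRUE)
  enum <- slimbuild_enumerate(masked, upc, cfg)
  amb <- enum$candidates[grepl("^amb:", enum$candidates$key), ]
  expect_true("D[ST]G" %in% amb$pattern)
  row <- amb[amb$pattern == "D[ST]G", ]
  expect_equal(length(row$support_upc[[1L]]), 3L)
})

test_that("discovery preconditions produce clear errors", {
  recs <- toy_records(c("ACDEFGHIKL", "MNPQRSTVWY"))
  ds <- slim_dataset(recs)
  expect_error(slimfinder(ds), "at least 3")
  ds3 <- generate_dataset(3, length_range = c(60L, 60L), seed = 1)
  cfg <- slim_config(min_upc_support = 5L)
  expect_error(slimfinder(ds3, cfg), "insufficient unrelated")
  # all-masked dataset names masking as the cause
  dsm <- generate_dataset(3, length_range = c(60L, 60L), seed = 2)
  dsm$disorder <- lapply(dsm$disorder, function(x) rep(0, length(x)))
  expect_error(slimfinder(dsm), "masking")
})

test_that("planted-signal runs are deterministic and self-consistent", {
  ds <- generate_dataset(12, length_range = c(150L, 150L),
                         planted_pattern = "DSG", planted_fraction = 0.75,
                         seed = 3)
  r1 <- slimfinder(ds)
  r2 <- slimfinder(ds)
  r1$timestamp <- r2$timestamp <- NULL
  expect_identical(r1, r2)
  # ranks are 1..n without gaps
  expect_equal(r1$summary$rank, seq_len(nrow(r1$summary)))
  r1 <- slimfinder(ds)
  # every reported occurrence re-validates against find_occurrences
  for (i in seq_len(nrow(r1$occurrences))) {
    o <- r1$occurrences[i, ]
    occ <- find_occurrences(o$pattern, r1$masked[[o$accession]])
    expect_true(any(occ$start == o$start & occ$end == o$end))
  }
})

test_that("query restriction shrinks the space and excludes the query UPC", {
  ds <- generate_dataset(12, length_range = c(150L, 150L),
                         planted_pattern = "DSG", planted_fraction = 0.75,
                         seed = 13)
  q <- ds$planted$accession[1L]
  rq <- qslimfinder(ds, q)
  rf <- slimfinder(ds)
  expect_lt(rq$search_space, rf$search_space)
  # every reported candidate occurs in the query
  qocc <- find_occurrences("DSG", rq$masked[[q]])
  expect_gt(nrow(qocc), 0L)
  dsg_q <- rq$summary[rq$summary$pattern == "DSG", ]
  dsg_f <- rf$summary[rf$summary$pattern == "DSG", ]
  expect_equal(dsg_q$n_upc, dsg_f$n_upc - 1L)
  expect_error(qslimfinder(ds, "NOPE"), "not in dataset")
})

test_that("a query with no shared candidate yields an empty result", {
  # Query shares no word with the rest of the dataset at support >= 3.
  recs <- toy_records(c("WWWWYYYYWWWWYYYY",
                        "AAADSGAAAKLMAAAA", "CCCDSGCCCKLMCCCC",
                        "EEEDSGEEEKLMEEEE", "FFFDSGFFFKLMFFFF"))
  ds <- slim_dataset(recs)
  cfg <- slim_config(dismask = FALSE, ftmask_on = FALSE, max_defined = 3L)
  res <- qslimfinder(ds, "P1", cfg)
  expect_equal(nrow(res$summary), 0L)
  expect_equal(nrow(res$occurrences), 0L)
})

test_that("query homologs are excluded with the query's whole UPC", {
  # P1 and P2 are near-identical homologs (one UPC); DSG sits in both plus
  # three unrelated sequences. Statistics must drop the whole query cluster.
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 10), collapse = "")
  p1 <- paste0(substr(base, 1, 100), "DSG", substr(base, 104, 200))
  p2 <- p1
  substr(p2, 50, 50) <- "W"
  others <- vapply(1:4, function(i) {
    set.seed(100 + i)
    s <- random_seq(200)
    paste0(substr(s, 1, 80), "DSG", substr(s, 84, 200))
  }, "")
  recs <- toy_records(c(p1, p2, others))
  ds <- slim_dataset(recs)
  cfg <- slim_config(dismask = FALSE, ftmask_on = FALSE, max_defined = 3L)
  res <- qslimfinder(ds, "P1", cfg)
  expect_equal(res$upc$membership[["P1"]], res$upc$membership[["P2"]])
  dsg <- res$summary[res$summary$pattern == "DSG", ]
  expect_equal(dsg$n_upc, 4L)   # four unrelated clusters outside the query's
  expect_equal(dsg$n_seq, 4L)
})

test_that("known-motif search reports input order without ranks", {
  ds <- generate_dataset(10, length_range = c(200L, 200L),
                         planted_pattern = "DSG.{2,3}[ST]",
                         planted_fraction = 0.5, seed = 6)
  res <- slimprob(ds, "DSG.{2,3}[ST],DSG")
  expect_equal(res$summary$pattern, c("DSG.{2,3}[ST]", "DSG"))
  expect_true(all(is.na(res$summary$rank)))
  expect_true(all(is.na(res$summary$sig)))
  # containment: every ELM-style occurrence contains a DSG occurrence
  long <- res$occurrences[res$occurrences$pattern == "DSG.{2,3}[ST]", ]
  short <- res$occurrences[res$occurrences$pattern == "DSG", ]
  expect_gte(nrow(short), nrow(long))
  for (i in seq_len(nrow(long)))
    expect_true(any(short$accession == long$accession[i] &
                      short$start == long$start[i]))
  expect_error(slimprob(ds, "DS[G"), "unparsable")
})

test_that("absent motifs still get well-formed tail probabilities", {
  ds <- generate_dataset(6, length_range = c(80L, 80L), seed = 8)
  res <- slimprob(ds, "WWWWW")
  s <- res$summary
  expect_equal(s$n_occ, 0L)
  expect_equal(s$n_upc, 0L)
  expect_gte(s$p_und_upc, 1 - s$p_upc)
  expect_equal(s$p_upc, 1)   # P(X >= 0)
})

test_that("homolog copies change neither N_UPC nor cluster-level support", {
  ds0 <- generate_dataset(6, length_range = c(200L, 200L),
                          planted_pattern = "DSG", planted_fraction = 1,
                          seed = 9)
  ds1 <- generate_dataset(6, length_range = c(200L, 200L),
                          planted_pattern = "DSG", planted_fraction = 1,
                          n_homolog_copies = 2L, homolog_identity = 0.95,
                          seed = 9)
  r0 <- slimprob(ds0, "DSG")
  r1 <- slimprob(ds1, "DSG")
  expect_equal(r1$upc$n_upc, 6L)
  expect_equal(r1$summary$n_upc, r0$summary$n_upc)
})

test_that("custom parameter strings update the configuration", {
  cfg <- slim_config()
  cfg2 <- apply_custom_params(cfg, "iucut=0.35 maxwild=1,minupc=4")
  expect_equal(cfg2$iucut, 0.35)
  expect_equal(cfg2$max_wildcard, 1L)
  expect_equal(cfg2$min_upc_support, 4L)
  cfg3 <- apply_custom_params(cfg, "ftmask=DOMAIN,TRANSMEM,ZN_FING dismask=F")
  expect_equal(cfg3$ftmask, c("DOMAIN", "TRANSMEM", "ZN_FING"))
  expect_false(cfg3$dismask)
  expect_error(apply_custom_params(cfg, "orthdb=metazoa"), "out of")
  expect_error(apply_custom_params(cfg, "walltime=3"), "supported keys")
})

test_that("conservation-masked reruns keep planted, conserved occurrences", {
  ds <- generate_dataset(10, length_range = c(200L, 200L),
                         planted_pattern = "DSG", planted_fraction = 1,
                         n_orthologues = 4L, orthologue_identity = 0.5,
                         seed = 21)
  base_cfg <- slim_config()
  cons_cfg <- slim_config(consmask = TRUE)
  r0 <- slimprob(ds, "DSG", base_cfg)
  r1 <- slimprob(ds, "DSG", cons_cfg)
  planted_key <- paste(ds$planted$accession, ds$planted$start)
  k0 <- paste(r0$occurrences$accession, r0$occurrences$start)
  k1 <- paste(r1$occurrences$accession, r1$occurrences$start)
  # every planted instance survives both runs (conserved by construction)
  expect_true(all(planted_key %in% k0))
  expect_true(all(planted_key %in% k1))
  # conservation masking can only remove occurrences, never add
  expect_true(all(k1 %in% k0))
  marked <- mark_conserved(r0, r1)
  expect_true(all(marked$occurrences$conserved[k0 %in% planted_key]))
  expect_equal(sum(marked$occurrences$conserved), length(k1))
})

test_that("UPC-level enrichment grows with the planted fraction", {
  ratio <- vapply(c(0.3, 0.9), function(fr) {
    ds <- generate_dataset(20, length_range = c(200L, 200L),
                           planted_pattern = "DSG", planted_fraction = fr,
                           seed = 31)
    s <- slimprob(ds, "DSG")$summary
    s$n_upc / s$e_upc
  }, 0)
  expect_gt(ratio[1L], 1)
  expect_gt(ratio[2L], ratio[1L])
})
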