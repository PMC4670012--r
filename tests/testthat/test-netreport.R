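# Network I/O, annotation semantics, and result-table output.

test_that("SIF files read into networks with ppi edges", {
  f <- tempfile(fileext = ".sif")
  writeLines(c("Q9UKB1\tpp\tQ9Y297", "Q9UKB1\tpp\tP0AAA1", "LONER"), f)
  net <- read_network(f)
  expect_s3_class(net, "slim_network")
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$nodes$id, c("Q9UKB1", "Q9Y297", "P0AAA1", "LONER"))
  # empty edge file -> node-only network
  f2 <- tempfile(fileext = ".sif")
  writeLines(c("A1", "B2"), f2)
  net2 <- read_network(f2)
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(sort(net2$nodes$id), c("A1", "B2"))
})

test_that("networks round-trip through SIF and GraphML", {
  net <- slim_network(c("A", "B", "C", "D"),
                      data.frame(source = c("A", "B"), target = c("B", "C"),
                                 type = "ppi", stringsAsFactors = FALSE),
                      name = "toy")
  sif <- tempfile(fileext = ".sif")
  write_network(net, sif)
  back <- read_network(sif)
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(nrow(back$edges), 2L)

  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(igraph::ecount(g), 2L)
  expect_true("slim_count" %in% igraph::vertex_attr_names(g))
})

test_that("edge endpoints must exist in the node table", {
  expect_error(slim_network(c("A", "B"),
                            data.frame(source = "A", target = "Z",
                                       type = "ppi")),
               "Z")
})

test_that("shared interactors intersect hub neighbourhoods", {
  edges <- data.frame(
    source = c("H1", "H1", "H1", "H1", "H2", "H2", "H2", "H2"),
    target = c("A", "B", "C", "X", "A", "B", "C", "Y"),
    type = "ppi", stringsAsFactors = FALSE)
  net <- slim_network(unique(c(edges$source, edges$target)), edges)
  expect_equal(shared_interactors(net, c("H1", "H2")), c("A", "B", "C"))
  expect_setequal(shared_interactors(net, "H1"), c("A", "B", "C", "X"))
  expect_error(shared_interactors(net, "H9"), "unknown hub")
  # brute-force adjacency-intersection oracle on random graphs
  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:15, 1L)
    ids <- sprintf("N%02d", 1:n)
    m <- sample(5:25, 1L)
    e <- data.frame(source = sample(ids, m, replace = TRUE),
                    target = sample(ids, m, replace = TRUE),
                    type = "ppi", stringsAsFactors = FALSE)
    e <- e[e$source != e$target, , drop = FALSE]
    net <- slim_network(ids, e)
    hubs <- sample(ids, 2L)
    adj <- function(h) unique(c(e$target[e$source == h], e$source[e$target == h]))
    want <- sort(setdiff(intersect(adj(hubs[1]), adj(hubs[2])), hubs))
    expect_equal(shared_interactors(net, hubs), want)
  }
})

test_that("annotation applies the red-diamond scheme and is idempotent", {
  ds <- generate_dataset(8, length_range = c(150L, 150L),
                         planted_pattern = "DSG.{2,3}[ST]",
                         planted_fraction = 0.75, seed = 10)
  res <- slimprob(ds, "DSG,DSG.{2,3}[ST]")
  net <- slim_network(ds$records$accession)
  net$nodes$color <- "#0000FF"; net$nodes$shape <- "ellipse"
  ann <- annotate_results(net, res)
  counts <- vapply(split(paste(res$occurrences$motif, res$occurrences$pattern),
                         res$occurrences$accession),
                   function(x) length(unique(x)), 0L)
  for (i in seq_len(nrow(ann$nodes))) {
    id <- ann$nodes$id[i]
    k <- if (id %in% names(counts)) counts[[id]] else 0L
    expect_equal(ann$nodes$slim_count[i], k)
    if (k == 0L) {
      expect_equal(ann$nodes$shape[i], "ellipse")
      expect_equal(ann$nodes$color[i], "#0000FF")
    } else {
      expect_equal(ann$nodes$shape[i], "diamond")
      expect_equal(ann$nodes$color[i], if (k >= 2L) "#8B0000" else "#FF0000")
    }
  }
  expect_true(any(ann$nodes$slim_count >= 2L))
  ann2 <- annotate_results(ann, res)
  expect_equal(ann2$nodes, ann$nodes)
  # unmatched accessions are reported, not errors
  small <- slim_network(ds$records$accession[1:2])
  ann3 <- annotate_results(small, res)
  expect_true(all(attr(ann3, "unmatched") %in% ds$records$accession))
})

test_that("homology networks mirror the UPC partition and merge cleanly", {
  ds <- generate_dataset(5, length_range = c(220L, 220L),
                         n_homolog_copies = 1L, seed = 11)
  edges <- pairwise_homology(ds)
  upc <- cluster_upc(ds, edges)
  hnet <- homology_network(upc, ds)
  expect_true(all(hnet$edges$type == "homology"))
  g <- igraph::graph_from_data_frame(hnet$edges[c("source", "target")],
                                     directed = FALSE,
                                     vertices = hnet$nodes$id)
  comp <- igraph::components(g)$membership
  got <- unname(lapply(split(names(comp), comp), sort))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(upc$clusters, paste, collapse = ","))

  pnet <- slim_network(ds$records$accession,
                       data.frame(source = ds$records$accession[1L],
                                  target = ds$records$accession[3L],
                                  type = "ppi", stringsAsFactors = FALSE))
  merged <- merge_networks(pnet, hnet)
  expect_equal(merged$name, "SLiMOutput")
  expect_equal(nrow(merged$edges), nrow(pnet$edges) + nrow(hnet$edges))
  expect_setequal(unique(merged$edges$type), c("ppi", "homology"))
  # disjoint merge is a disjoint union; duplicate-type edges collapse
  merged2 <- merge_networks(merged, merged)
  expect_equal(nrow(merged2$edges), nrow(merged$edges))
})

test_that("result tables have the standard columns and absent fields", {
  ds <- generate_dataset(10, length_range = c(200L, 200L),
                         planted_pattern = "DSG", planted_fraction = 0.7,
                         seed = 12)
  cols <- c("Rank", "Sig", "Motif", "Pattern", "IC", "N_Occ", "N_Seq",
            "N_UPC", "E_UPC", "p_UPC", "pUnd_UPC")

  rf <- slimfinder(ds)
  d1 <- tempfile(); paths <- write_tables(rf, d1)
  main <- read.delim(paths["main"], check.names = FALSE,
                     colClasses = "character")
  expect_identical(colnames(main), cols)
  expect_true(all(main$Motif == ""))
  expect_true(all(main$E_UPC == "" & main$p_UPC == "" & main$pUnd_UPC == ""))
  expect_true(all(main$Rank != "" & main$Sig != ""))
  occ <- read.delim(paths["occ"], check.names = FALSE,
                    colClasses = "character")
  expect_identical(colnames(occ), c("Motif", "Pattern", "Seq", "Start_Pos",
                                    "End_Pos", "Match"))

  rp <- slimprob(ds, "DSG,WWWWW")
  d2 <- tempfile(); paths2 <- write_tables(rp, d2)
  main2 <- read.delim(paths2["main"], check.names = FALSE,
                      colClasses = "character")
  expect_identical(colnames(main2), cols)
  expect_true(all(main2$Rank == "" & main2$Sig == ""))
  expect_true(all(main2$Motif != ""))
  expect_true(all(main2$E_UPC != ""))

  # numeric fields round-trip at the rendered precision
  expect_equal(as.numeric(main2$E_UPC),
               signif(rp$summary$e_upc, 4), tolerance = 1e-9)
  expect_equal(as.numeric(main2$p_UPC),
               signif(rp$summary$p_upc, 4), tolerance = 1e-9)

  # empty results produce header-only files
  null_ds <- generate_dataset(10, length_range = c(200L, 200L), seed = 40)
  r0 <- slimfinder(null_ds)
  d3 <- tempfile(); paths3 <- write_tables(r0, d3)
  main3 <- read.delim(paths3["main"], check.names = FALSE)
  occ3 <- read.delim(paths3["occ"], check.names = FALSE)
  expect_identical(colnames(main3), cols)
  expect_equal(nrow(occ3), 0L)
})
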