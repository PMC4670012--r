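# Network I/O, result-table output, homology networks and node annotation.

#' Construct a protein network
#'
#' @param nodes character vector of node ids (accessions) or a data.frame with
#'   at least an `id` column; optional columns `label`, `shape`, `color`,
#'   `slim_count` are filled with defaults.
#' @param edges data.frame with columns `source`, `target`, `type` (edge type,
#'   e.g. `"ppi"` or `"homology"`); may be empty.
#' @param name network name; merged result networks default to `"SLiMOutput"`.
#' @return object of class `slim_network`.
#' @export
slim_network <- function(nodes, edges = NULL, name = "network") {
  if (is.character(nodes))
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node id(s)")
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (is.null(nodes$shape)) nodes$shape <- "ellipse"
  if (is.null(nodes$color)) nodes$color <- "#A0A0FF"
  if (is.null(nodes$slim_count)) nodes$slim_count <- 0L
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "type") %in% names(edges)))
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling))
    stop("edge endpoint(s) not in node set: ", paste(dangling, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "slim_network")
}

#' @export
print.slim_network <- function(x, ...) {
  cat(sprintf("slim_network %s: %d nodes, %d edges (%s)\n", sQuote(x$name),
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges))
                paste(names(table(x$edges$type)), table(x$edges$type),
                      sep = ":", collapse = ", ") else "no edges"))
  invisible(x)
}

#' Read a network from SIF or node/edge TSV
#'
#' SIF lines are `source<TAB>type<TAB>target` (single-node lines allowed;
#' whitespace-separated also accepted); node ids are treated as accessions and
#' the node set is the union of all endpoints. Alternatively an edge TSV with
#' header `source  target  type` can be given, with an optional companion
#' node TSV (header containing `id`) whose ids must cover every endpoint.
#'
#' @param path SIF or edge-TSV file path.
#' @param nodes_path optional node TSV path.
#' @param name network name.
#' @return `slim_network`.
#' @export
read_network <- function(path, nodes_path = NULL, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  is_tsv <- length(lines) > 0L &&
    grepl("^source[\t ]", tolower(lines[1L]))
  if (is_tsv) {
    parts <- strsplit(lines[-1L], "[\t ]+")
    edges <- if (length(parts))
      data.frame(source = vapply(parts, `[`, "", 1L),
                 target = vapply(parts, `[`, "", 2L),
                 type = vapply(parts, function(p)
                   if (length(p) >= 3L) p[3L] else "ppi", ""),
                 stringsAsFactors = FALSE)
    else data.frame(source = character(0), target = character(0),
                    type = character(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "[\t ]+")
    singles <- vapply(parts, length, 0L) == 1L
    ed <- parts[!singles]
    bad <- vapply(ed, length, 0L) < 3L
    if (any(bad)) stop("malformed SIF line(s): ",
                       paste(lines[!singles][bad], collapse = "; "))
    edges <- if (length(ed))
      data.frame(source = vapply(ed, `[`, "", 1L),
                 type = vapply(ed, `[`, "", 2L),
                 target = vapply(ed, `[`, "", 3L),
                 stringsAsFactors = FALSE)[c("source", "target", "type")]
    else data.frame(source = character(0), target = character(0),
                    type = character(0), stringsAsFactors = FALSE)
    extra_nodes <- unlist(parts[singles])
    node_ids <- unique(c(edges$source, edges$target, extra_nodes))
    return(slim_network(node_ids, edges, name = name))
  }
  if (!is.null(nodes_path)) {
    ndf <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
    names(ndf)[1L] <- "id"
    return(slim_network(ndf, edges, name = name))
  }
  slim_network(unique(c(edges$source, edges$target)), edges, name = name)
}

#' Write a network to GraphML or SIF
#'
#' GraphML output (default) carries all node attributes (`label`, `shape`,
#' `color`, `slim_count`) and the edge `type`, so any graph viewer can map the
#' styling. A `.sif` path writes simple interaction format instead (edges
#' only, plus single-node lines for isolated nodes), which round-trips through
#' [read_network()].
#'
#' @param net a `slim_network`.
#' @param path output path; format chosen by extension (`.sif` vs GraphML).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "slim_network"))
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(net$edges))
      writeLines(paste(net$edges$source, net$edges$type, net$edges$target,
                       sep = "\t"), con)
    isolated <- setdiff(net$nodes$id, c(net$edges$source, net$edges$target))
    if (length(isolated)) writeLines(isolated, con)
    return(invisible(path))
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Nodes interacting with every listed hub
#'
#' Returns the nodes adjacent to all of `hub_ids` (hubs themselves excluded):
#' the shared-interactor reduction used to focus discovery on proteins that
#' bind a common pair of partners.
#'
#' @param net a `slim_network`.
#' @param hub_ids character vector of hub node ids.
#' @return character vector of node ids, sorted.
#' @export
shared_interactors <- function(net, hub_ids) {
  stopifnot(inherits(net, "slim_network"), length(hub_ids) >= 1L)
  unknown <- setdiff(hub_ids, net$nodes$id)
  if (length(unknown)) stop("unknown hub node(s): ",
                            paste(unknown, collapse = ", "))
  neigh <- lapply(hub_ids, function(h)
    unique(c(net$edges$target[net$edges$source == h],
             net$edges$source[net$edges$target == h])))
  out <- Reduce(intersect, neigh)
  sort(setdiff(out, hub_ids))
}

#' Annotate network nodes with motif occurrence results
#'
#' Sets `slim_count` on every node to the number of distinct motifs with at
#' least one occurrence in that protein and applies the standard visual
#' semantics: one motif turns the node into a red diamond, two or more into a
#' dark red diamond, and nodes without occurrences keep their existing
#' styling untouched. Idempotent. Result accessions with no matching node are
#' listed in the `unmatched` attribute of the returned network.
#'
#' @param net a `slim_network` whose node ids are accessions.
#' @param bundle a `slim_result`.
#' @return annotated `slim_network`.
#' @export
annotate_results <- function(net, bundle) {
  stopifnot(inherits(net, "slim_network"), inherits(bundle, "slim_result"))
  occ <- bundle$occurrences
  motif_id <- paste(occ$motif, occ$pattern)
  counts <- vapply(split(motif_id, occ$accession),
                   function(x) length(unique(x)), 0L)
  unmatched <- setdiff(names(counts), net$nodes$id)
  hit <- intersect(names(counts), net$nodes$id)
  idx <- match(hit, net$nodes$id)
  net$nodes$slim_count[idx] <- as.integer(counts[hit])
  one <- idx[counts[hit] == 1L]
  many <- idx[counts[hit] >= 2L]
  net$nodes$shape[c(one, many)] <- "diamond"
  net$nodes$color[one] <- "#FF0000"
  net$nodes$color[many] <- "#8B0000"
  attr(net, "unmatched") <- unmatched
  net
}

#' Homology network of a UPC partition
#'
#' One node per protein record and one edge per retained homology edge
#' (`type = "homology"`). The connected components of this network are, by
#' construction, exactly the Unrelated Protein Clusters.
#'
#' @param upc a `upc_partition`.
#' @param records data.frame of protein records or a `slim_dataset`.
#' @param name network name.
#' @return `slim_network`.
#' @export
homology_network <- function(upc, records, name = "homology") {
  if (inherits(records, "slim_dataset")) records <- records$records
  edges <- data.frame(source = upc$edges$accession_a,
                      target = upc$edges$accession_b,
                      type = rep("homology", nrow(upc$edges)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = records$accession, label = records$name,
                      stringsAsFactors = FALSE)
  slim_network(nodes, edges, name = name)
}

#' Merge two networks
#'
#' Node union (attributes from the first network win for shared nodes) and
#' edge union preserving edge types, so interaction and homology edges
#' coexist; duplicate edges of identical type and endpoints collapse to one.
#'
#' @param net_a,net_b `slim_network` objects.
#' @param name merged network name (default `"SLiMOutput"`).
#' @return `slim_network`.
#' @export
merge_networks <- function(net_a, net_b, name = "SLiMOutput") {
  stopifnot(inherits(net_a, "slim_network"), inherits(net_b, "slim_network"))
  nodes <- rbind(net_a$nodes, net_b$nodes[!net_b$nodes$id %in% net_a$nodes$id, ,
                                          drop = FALSE])
  edges <- rbind(net_a$edges[c("source", "target", "type")],
                 net_b$edges[c("source", "target", "type")])
  ekey <- paste(pmin(edges$source, edges$target),
                pmax(edges$source, edges$target), edges$type)
  edges <- edges[!duplicated(ekey), , drop = FALSE]
  rownames(edges) <- NULL
  slim_network(nodes, edges, name = name)
}

#' Mark occurrences that survive a conservation-masked rerun
#'
#' Given the same search run twice — once with the standard masking and once
#' with conservation masking added — flags every occurrence of the first
#' bundle with `conserved = TRUE` when the identical span (accession, motif,
#' start, end) is still found in the second. The flag is a plain attribute
#' column; how conserved occurrences are drawn (circles, hexagons, ...) is
#' left to the viewer.
#'
#' @param bundle a `slim_result` from the standard run.
#' @param conserved_bundle the matching `slim_result` from the
#'   conservation-masked rerun.
#' @return `bundle` with a logical `conserved` column added to
#'   `$occurrences`.
#' @export
mark_conserved <- function(bundle, conserved_bundle) {
  stopifnot(inherits(bundle, "slim_result"),
            inherits(conserved_bundle, "slim_result"))
  key <- function(o) paste(o$pattern, o$accession, o$start, o$end)
  bundle$occurrences$conserved <-
    key(bundle$occurrences) %in% key(conserved_bundle$occurrences)
  bundle
}

#' Write result tables
#'
#' Writes the two standard result tables to `out_dir`: `main.tsv` (one row per
#' motif: `Rank`, `Sig`, `Motif`, `Pattern`, `IC`, `N_Occ`, `N_Seq`, `N_UPC`,
#' `E_UPC`, `p_UPC`, `pUnd_UPC`) and `occ.tsv` (one row per occurrence:
#' `Motif`, `Pattern`, `Seq`, `Start_Pos`, `End_Pos`, `Match`). Fields that do
#' not apply to the program that produced the bundle are left empty: discovery
#' runs have no `Motif`, `E_UPC`, `p_UPC` or `pUnd_UPC`; known-motif searches
#' have no `Rank` or `Sig`. Floating-point fields are rendered with 4
#' significant digits; row order is deterministic (rank order for discovery,
#' input order for known-motif search).
#'
#' @param bundle a `slim_result`.
#' @param out_dir output directory (created if absent).
#' @param all_candidates for discovery runs, write all scored candidates
#'   (default writes significant candidates only).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_tables <- function(bundle, out_dir, all_candidates = FALSE) {
  stopifnot(inherits(bundle, "slim_result"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory ", out_dir)
  fmt <- function(x) ifelse(is.na(x), "", signif(x, 4))
  s <- bundle$summary
  discovery <- bundle$program %in% c("slimfinder", "qslimfinder")
  if (discovery && !all_candidates)
    s <- s[which(s$signif), , drop = FALSE]
  sblank <- rep("", nrow(s))
  main <- data.frame(
    Rank = if (discovery) s$rank else sblank,
    Sig = if (discovery) fmt(s$sig) else sblank,
    Motif = if (discovery) sblank else s$motif,
    Pattern = s$pattern,
    IC = fmt(s$ic),
    N_Occ = s$n_occ,
    N_Seq = s$n_seq,
    N_UPC = s$n_upc,
    E_UPC = if (discovery) sblank else fmt(s$e_upc),
    p_UPC = if (discovery) sblank else fmt(s$p_upc),
    pUnd_UPC = if (discovery) sblank else fmt(s$p_und_upc),
    stringsAsFactors = FALSE, check.names = FALSE)
  o <- bundle$occurrences
  occ <- data.frame(
    Motif = if (discovery) rep("", nrow(o)) else o$motif,
    Pattern = o$pattern,
    Seq = o$accession,
    Start_Pos = o$start,
    End_Pos = o$end,
    Match = o$match,
    stringsAsFactors = FALSE, check.names = FALSE)
  main_path <- file.path(out_dir, "main.tsv")
  occ_path <- file.path(out_dir, "occ.tsv")
  utils::write.table(main, main_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(occ, occ_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(main = main_path, occ = occ_path))
}
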