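# Interaction-network co-regulation filter.
#
# Graphs are igraph objects built from two-column edge lists of gene/TF
# symbols. All edges are undirected, deduplicated and free of self-loops.

#' Read an undirected interaction edge list
#'
#' Parses a whitespace/tab-separated two-column file of gene or protein
#' symbols into an undirected [igraph] graph. Self-loops are dropped with a
#' warning; duplicate pairs (in either orientation) are collapsed.
#'
#' @param path Edge-list file; `#` comments and blank lines ignored.
#' @return An undirected `igraph` graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(tokens) != 2)
  if (length(bad)) {
    abort(sprintf("Malformed edge at line %d of %s: expected two symbols, got %d.",
                  which(keep)[bad[1]], basename(path), lengths(tokens)[bad[1]]))
  }
  edges <- tibble(
    from = vapply(tokens, `[`, character(1), 1),
    to = vapply(tokens, `[`, character(1), 2)
  )
  interaction_graph(edges)
}

#' Build an undirected interaction graph from an edge data frame
#'
#' @param edges Data frame whose first two columns are interacting symbols.
#' @param nodes Optional extra node symbols to include as isolated vertices.
#' @return An undirected `igraph` graph with no self-loops or multi-edges.
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must be a data frame with two symbol columns.")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  loops <- from == to
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop(s): %s", sum(loops),
                 paste(unique(from[loops]), collapse = ", ")))
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = unique(c(from, to, nodes))
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Induced subnetwork on a set of symbols
#'
#' Returns the subgraph induced by `keep`: all edges of `g` with both ends
#' in `keep`. Symbols in `keep` that are absent from `g` appear as isolated
#' vertices, so a candidate gene missing from the interactome is still
#' represented (with degree 0).
#'
#' @param g An `igraph` graph.
#' @param keep Character vector of symbols.
#' @return An undirected `igraph` graph on `keep`.
#' @export
subnetwork <- function(g, keep) {
  keep <- unique(as.character(keep))
  present <- intersect(keep, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, present)
  absent <- setdiff(keep, present)
  if (length(absent)) sub <- igraph::add_vertices(sub, length(absent), name = absent)
  sub
}

#' Degree (connectivity) of a node
#'
#' Number of distinct neighbors of `node` in `g` — the connectivity grade
#' used to judge how embedded a gene is in the regulatory network.
#'
#' @param g An `igraph` graph.
#' @param node A single symbol present in `g`.
#' @return Integer degree.
#' @export
node_degree <- function(g, node) {
  if (!node %in% igraph::V(g)$name) {
    abort(sprintf("Node %s is not in the graph.", node))
  }
  unname(igraph::degree(g, node))
}

#' Default transcription-factor alias map
#'
#' The breast-cancer TF panel used in the co-regulation filter mixes gene
#' symbols (TP53, MYC, GATA3, ...) with complex or family names (AP1, NFKB,
#' ER, HIF, NOTCH, STAT5). This map expands each entry to the gene symbols
#' an interactome keyed by symbols can contain; every entry also matches its
#' own literal name. Override with a YAML file via [read_tf_aliases()].
#'
#' @return Named list: TF entry -> character vector of gene symbols.
#' @export
default_tf_aliases <- function() {
  path <- system.file("extdata", "tf_aliases.yaml", package = "hkgselect")
  read_tf_aliases(path)
}

#' @rdname default_tf_aliases
#' @param path YAML file mapping TF names to symbol vectors.
#' @export
read_tf_aliases <- function(path) {
  x <- yaml::read_yaml(path)
  lapply(x, as.character)
}

# Expand a TF list through the alias map; literal names always included.
expand_tf_symbols <- function(tfs, aliases) {
  unique(unlist(c(tfs, aliases[intersect(tfs, names(aliases))]), use.names = FALSE))
}

#' Flag candidate reference genes that are network co-regulated
#'
#' A candidate is disqualified as an internal control when the interactome
#' suggests shared regulation: it is adjacent (1-hop) to a breast-cancer
#' transcription factor (`tf_adjacent`), or adjacent to another candidate or
#' to a gene of the traditional reference panel (`panel_adjacent`). A
#' candidate is `retained` only when neither flag is set. Candidates absent
#' from the graph are treated as isolated — retained, with a log message.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param reference_panel Character vector of traditional reference-gene
#'   symbols (may be empty).
#' @param tfs Character vector of transcription-factor names.
#' @param g Interactome graph from [read_edge_list()] or
#'   [interaction_graph()].
#' @param tf_aliases Alias map (see [default_tf_aliases()]).
#' @return A tibble with one row per candidate: `gene_id`, `in_graph`,
#'   `degree`, `tf_adjacent`, `tf_neighbors`, `panel_adjacent`,
#'   `panel_neighbors`, `retained`. Neighbor columns are comma-separated
#'   symbol strings (empty when none).
#' @export
flag_coregulated <- function(candidates, reference_panel = character(0), tfs,
                             g, tf_aliases = default_tf_aliases()) {
  if (!length(candidates)) abort("`candidates` must be non-empty.")
  if (!length(tfs)) abort("`tfs` must be non-empty.")
  tf_symbols <- expand_tf_symbols(tfs, tf_aliases)
  vnames <- igraph::V(g)$name
  absent <- setdiff(candidates, vnames)
  if (length(absent)) {
    inform(sprintf("Candidate(s) absent from the interactome (treated as isolated): %s",
                   paste(absent, collapse = ", ")))
  }
  rows <- purrr::map(candidates, function(cand) {
    if (cand %in% vnames) {
      nbrs <- igraph::neighbors(g, cand)$name
    } else {
      nbrs <- character(0)
    }
    panel <- union(setdiff(candidates, cand), reference_panel)
    tf_n <- intersect(nbrs, tf_symbols)
    panel_n <- intersect(nbrs, panel)
    tibble(
      gene_id = cand,
      in_graph = cand %in% vnames,
      degree = length(nbrs),
      tf_adjacent = length(tf_n) > 0,
      tf_neighbors = paste(tf_n, collapse = ","),
      panel_adjacent = length(panel_n) > 0,
      panel_neighbors = paste(panel_n, collapse = ","),
      retained = length(tf_n) == 0 && length(panel_n) == 0
    )
  })
  dplyr::bind_rows(rows)
}
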