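# Main-compound reaction network and its reduction to the RMS network.
#
# Two reactions are linked by a directed edge when a metabolite that is
# biologically relevant to both within a pathway (the "main compound") is
# a product of the first and a substrate of the second.  Only reactions
# that belong to at least one pathway appear; transport reactions are
# excluded.  Grouping reactions by RMS class and merging their edges
# yields the RMS network with first-order Markov transition
# probabilities.

#' Read a pathway link table
#'
#' TSV with columns `pathway_id`, `type` (one of Biosynthesis,
#' Degradation, Detox, Energy, Other), `from_rxn`, `to_rxn`,
#' `main_compound`; one row per directed main-compound link.
#'
#' @param path file path.
#' @return Tibble of pathway links.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tibble::as_tibble(df[c("pathway_id", "type", "from_rxn", "to_rxn",
                         "main_compound")])
}

#' Build the main-compound reaction network
#'
#' One node per pathway-member, non-transport reaction; one directed edge
#' per ordered reaction pair with at least one supporting pathway link.
#' Parallel support from several pathways collapses into a single edge
#' that records all its supports.  Links whose main compound is not a
#' product of the upstream reaction and a substrate of the downstream
#' reaction are skipped with a warning; links citing unknown reactions
#' are an error.  Links incident to transport reactions are dropped
#' (the translocated substrate is unchanged, so they carry no
#' transformation).
#'
#' @param reactions reaction tibble (see [read_reactions()]).
#' @param pathways pathway link tibble (see [read_pathways()]).
#' @return An object of class `reaction_network`: list with `nodes`
#'   (tibble `reaction_id`) and `edges` (tibble `from`, `to`,
#'   `n_supports`, `supports`), where each support is a
#'   (pathway, main compound) pair.
#' @export
build_reaction_network <- function(reactions, pathways) {
  unknown <- setdiff(unique(c(pathways$from_rxn, pathways$to_rxn)),
                     reactions$reaction_id)
  if (length(unknown))
    stop(sprintf("pathway links cite unknown reactions: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  transport <- reactions$reaction_id[reactions$is_transport]
  links <- pathways[!(pathways$from_rxn %in% transport |
                        pathways$to_rxn %in% transport), , drop = FALSE]
  if (nrow(links)) {
    prod_of <- stats::setNames(lapply(reactions$products, `[[`, "compound"),
                               reactions$reaction_id)
    subs_of <- stats::setNames(lapply(reactions$substrates, `[[`, "compound"),
                               reactions$reaction_id)
    ok <- vapply(seq_len(nrow(links)), function(k) {
      links$main_compound[k] %in% prod_of[[links$from_rxn[k]]] &&
        links$main_compound[k] %in% subs_of[[links$to_rxn[k]]]
    }, logical(1))
    if (any(!ok)) {
      bad <- links[!ok, ]
      rlang::warn(sprintf(
        "skipping %d pathway link(s) whose main compound is not shared product/substrate (e.g. %s -> %s via %s)",
        sum(!ok), bad$from_rxn[1], bad$to_rxn[1], bad$main_compound[1]))
      links <- links[ok, , drop = FALSE]
    }
  }
  nodes <- sort(unique(c(links$from_rxn, links$to_rxn)), method = "radix")
  edges <- links |>
    dplyr::group_by(from = .data$from_rxn, to = .data$to_rxn) |>
    dplyr::summarise(
      n_supports = dplyr::n(),
      supports = {
        pid <- .data$pathway_id
        mc <- .data$main_compound
        list(tibble::tibble(pathway_id = pid, main_compound = mc))
      },
      .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(nodes = tibble::tibble(reaction_id = nodes), edges = edges),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d reaction nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Reduce a reaction network to the RMS network
#'
#' Reactions signed by the same RMS class collapse into one node; a
#' directed edge joins class i to class j (i != j) when at least one
#' reaction edge crosses them, with multiplicity equal to the number of
#' crossing reaction edges.  The transition probability
#' `Pr(RMS_j | RMS_i)` is that count divided by the total number of
#' outgoing reaction edges from members of class i.  The denominator
#' includes within-class reaction edges, which produce no RMS edge
#' (self-loops are avoided), so outgoing probabilities sum to
#' `1 - (within-class outgoing fraction)`.
#'
#' @param net a `reaction_network`.
#' @param cls an `rms_classification`.
#' @param height 1 or 2.
#' @return An object of class `rms_network`: list with `nodes` (tibble
#'   `class_id`, `n_members`, `members`, `n_out_total`, `n_within`),
#'   `edges` (tibble `from`, `to`, `n_edges`, `prob`) and `height`.
#' @export
reduce_to_rms_network <- function(net, cls, height = 1L) {
  lk <- class_lookup(cls, height)
  cl_of <- lk[net$nodes$reaction_id]
  if (anyNA(cl_of)) {
    drop <- net$nodes$reaction_id[is.na(cl_of)]
    rlang::warn(sprintf(
      "dropping %d network reaction(s) not classified at height %d: %s",
      length(drop), height, paste(utils::head(drop, 5), collapse = ", ")))
  }
  keep <- names(cl_of)[!is.na(cl_of)]
  redges <- net$edges[net$edges$from %in% keep & net$edges$to %in% keep, ]
  from_cl <- unname(lk[redges$from])
  to_cl <- unname(lk[redges$to])
  out_total <- table(factor(from_cl, levels = sort(unique(unname(lk[keep])),
                                                   method = "radix")))
  cross <- from_cl != to_cl
  agg <- tibble::tibble(from = from_cl[cross], to = to_cl[cross]) |>
    dplyr::count(.data$from, .data$to, name = "n_edges") |>
    dplyr::arrange(.data$from, .data$to)
  agg$prob <- agg$n_edges / as.numeric(out_total[agg$from])
  members <- split(keep, unname(lk[keep]))
  node_ids <- sort(names(members), method = "radix")
  within <- tibble::tibble(cl = from_cl[!cross]) |> dplyr::count(.data$cl)
  nodes <- tibble::tibble(
    class_id = node_ids,
    n_members = lengths(members)[node_ids],
    members = unname(members[node_ids]),
    n_out_total = as.integer(out_total[node_ids]),
    n_within = ifelse(is.na(match(node_ids, within$cl)), 0L,
                      within$n[match(node_ids, within$cl)]))
  structure(list(nodes = nodes, edges = agg, height = height,
                 n_reaction_edges = nrow(redges)),
            class = "rms_network")
}

#' @export
print.rms_network <- function(x, ...) {
  cat(sprintf("<rms_network> height %d: %d class nodes, %d directed edges (from %d reaction edges)\n",
              x$height, nrow(x$nodes), nrow(x$edges), x$n_reaction_edges))
  invisible(x)
}

#' @method tidy rms_network
#' @export
tidy.rms_network <- function(x, ...) x$edges

#' @method glance rms_network
#' @export
glance.rms_network <- function(x, ...) {
  tibble::tibble(
    height = x$height,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_reaction_edges = x$n_reaction_edges,
    mean_out_degree = if (nrow(x$nodes)) nrow(x$edges) / nrow(x$nodes) else NA_real_)
}

#' Node reduction rate
#'
#' Ratio of RMS node count to reaction node count; 1 for the identity
#' reduction (all singleton classes), smaller when reactions aggregate.
#'
#' @param net a `reaction_network`.
#' @param rmsnet an `rms_network` derived from it.
#' @return Numeric scalar in (0, 1].
#' @export
node_reduction_rate <- function(net, rmsnet) {
  if (nrow(net$nodes) == 0L)
    stop("node reduction rate is undefined for an empty network", call. = FALSE)
  nrow(rmsnet$nodes) / nrow(net$nodes)
}

# igraph view of an RMS network (edge attribute prob, node attr members).
rms_igraph <- function(rmsnet) {
  g <- igraph::graph_from_data_frame(
    rmsnet$edges[c("from", "to", "n_edges", "prob")],
    directed = TRUE,
    vertices = data.frame(name = rmsnet$nodes$class_id,
                          n_members = rmsnet$nodes$n_members))
  g
}

#' Export a network as GraphML
#'
#' Node and edge attributes (member counts, edge multiplicities,
#' transition probabilities) are preserved.
#'
#' @param rmsnet an `rms_network`.
#' @param path output file.
#' @export
export_graphml <- function(rmsnet, path) {
  igraph::write_graph(rms_igraph(rmsnet), path, format = "graphml")
  invisible(path)
}

#' Write a network edge list as TSV
#'
#' @param x a `reaction_network` or `rms_network`.
#' @param path output file.
#' @export
write_edges <- function(x, path) {
  e <- x$edges
  if ("supports" %in% names(e)) e$supports <- NULL
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
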