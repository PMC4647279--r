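# Loop-free paths in the RMS network, the Pathway Conservation Index and
# the three conservation scores.  An RMS path of length L (edges) visits
# L+1 distinct class nodes; its PCI is the number of distinct reaction
# paths inside known pathways that realize it, and a path with PCI >= 2
# is a conserved chemical transformation module.

#' Enumerate loop-free RMS paths
#'
#' Every simple directed path with `min_len` to `max_len` edges, each
#' exactly once, in deterministic lexicographic order of the node-id
#' sequence (depth-first search from each node with bytewise-sorted
#' neighbour exploration).  A node-count cap guards runaway inputs since
#' path counts grow combinatorially.
#'
#' @param rmsnet an `rms_network`.
#' @param min_len,max_len path length range in edges (defaults 1 and 4).
#' @param max_nodes refuse networks larger than this (default 5000).
#' @return Tibble `path_id` (nodes joined by `->`), `nodes`
#'   (list of character vectors), `length`.
#' @export
enumerate_rms_paths <- function(rmsnet, min_len = 1L, max_len = 4L,
                                max_nodes = 5000L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  if (nrow(rmsnet$nodes) > max_nodes)
    stop(sprintf("network has %d nodes, above the enumeration cap (%d)",
                 nrow(rmsnet$nodes), max_nodes), call. = FALSE)
  adj <- split(rmsnet$edges$to, rmsnet$edges$from)
  adj <- lapply(adj, sort, method = "radix")
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 256L)
  acc$n <- 0L
  emit <- function(p) {
    acc$n <- acc$n + 1L
    if (acc$n > length(acc$paths))
      acc$paths <- c(acc$paths, vector("list", length(acc$paths)))
    acc$paths[[acc$n]] <- p
  }
  dfs <- function(path) {
    u <- path[length(path)]
    if (length(path) - 1L >= max_len) return(invisible())
    for (v in adj[[u]]) {
      if (v %in% path) next
      p2 <- c(path, v)
      if (length(p2) - 1L >= min_len) emit(p2)
      dfs(p2)
    }
  }
  for (s in sort(rmsnet$nodes$class_id, method = "radix")) dfs(s)
  paths <- acc$paths[seq_len(acc$n)]
  tibble::tibble(
    path_id = vapply(paths, paste, character(1), collapse = "->"),
    nodes = paths,
    length = lengths(paths) - 1L)
}

# All contiguous reaction paths of `len` edges within each pathway's own
# link graph, with their class sequences.  Windows with a repeated class
# are dropped (consistent with loop-free enumeration); windows touching
# an unclassified reaction are dropped too.
pathway_windows <- function(pathways, cls, height = 1L, lengths = 1:4) {
  lk <- class_lookup(cls, height)
  out <- list()
  for (pw in unique(pathways$pathway_id)) {
    links <- pathways[pathways$pathway_id == pw, ]
    type <- links$type[1]
    adj <- split(links$to_rxn, links$from_rxn)
    adj <- lapply(adj, function(v) sort(unique(v), method = "radix"))
    nodes <- sort(unique(c(links$from_rxn, links$to_rxn)), method = "radix")
    maxL <- max(lengths)
    walk <- function(path) {
      L <- length(path) - 1L
      if (L %in% lengths) {
        clseq <- unname(lk[path])
        if (!anyNA(clseq) && !anyDuplicated(clseq)) {
          out[[length(out) + 1L]] <<- tibble::tibble(
            pathway_id = pw, type = type, length = L,
            rxn_seq = paste(path, collapse = "|"),
            class_seq = paste(clseq, collapse = "->"))
        }
      }
      if (L >= maxL) return(invisible())
      for (v in adj[[path[length(path)]]]) {
        if (v %in% path) next  # reaction paths are simple too
        walk(c(path, v))
      }
    }
    for (s in nodes) walk(s)
  }
  if (!length(out))
    return(tibble::tibble(pathway_id = character(), type = character(),
                          length = integer(), rxn_seq = character(),
                          class_seq = character()))
  dplyr::bind_rows(out)
}

#' Translate a pathway into overlapping RMS paths
#'
#' Every contiguous reaction path of `length` edges inside the pathway's
#' link graph, mapped reaction-wise to RMS class ids; windows containing
#' a repeated class are dropped, mirroring the loop-free path
#' enumeration.
#'
#' @param pathways pathway link tibble (one or several pathways).
#' @param cls an `rms_classification`.
#' @param length window length in edges.
#' @param height 1 or 2.
#' @return Tibble `pathway_id`, `rxn_seq`, `class_seq` (distinct rows).
#' @export
pathway_to_rms_paths <- function(pathways, cls, length = 2L, height = 1L) {
  w <- pathway_windows(pathways, cls, height = height, lengths = length)
  dplyr::distinct(w[c("pathway_id", "rxn_seq", "class_seq")])
}

#' Pathway Conservation Index of an RMS path
#'
#' The number of distinct reaction paths, contiguous within a single
#' known pathway, whose class sequence equals the given RMS path.  A
#' reaction path appearing in several pathways counts once.  The
#' alternative per-edge support rule (`support = "edge"`) only requires
#' each consecutive reaction pair to be linked in some pathway.
#'
#' @param path character vector of class ids (the RMS node sequence).
#' @param pathways pathway link tibble.
#' @param cls an `rms_classification`.
#' @param height 1 or 2.
#' @param support `"pathway"` (default, strict single-pathway
#'   contiguity) or `"edge"`.
#' @return Non-negative integer.
#' @export
compute_pci <- function(path, pathways, cls, height = 1L,
                        support = c("pathway", "edge")) {
  support <- match.arg(support)
  L <- length(path) - 1L
  w <- supporting_windows(pathways, cls, height, lengths = L, support = support)
  key <- paste(path, collapse = "->")
  sum(!duplicated(w$rxn_seq[w$class_seq == key]))
}

# Support windows under either rule, as a tibble rxn_seq/class_seq
# (pathway_id retained under the strict rule).
supporting_windows <- function(pathways, cls, height, lengths,
                               support = "pathway") {
  if (support == "pathway")
    return(pathway_windows(pathways, cls, height = height, lengths = lengths))
  # per-edge rule: walk the union graph of all pathway links
  union_links <- dplyr::distinct(pathways[c("from_rxn", "to_rxn")])
  union_pw <- tibble::tibble(pathway_id = "(any)", type = "(any)",
                             from_rxn = union_links$from_rxn,
                             to_rxn = union_links$to_rxn,
                             main_compound = NA_character_)
  pathway_windows(union_pw, cls, height = height, lengths = lengths)
}

#' Conservation scores of an RMS path
#'
#' The geometric mean, over consecutive node pairs, of the source node's
#' weight times the transition probability to the next node:
#' `score = (prod_{i=s}^{n-1} w(RMS_i) * Pr(RMS_{i+1} | RMS_i))^(1/(n-1))`
#' with `n-1` the edge count; the terminal node's weight is not a
#' factor.  With `kind = "prot"` the score is undefined (`NA`) whenever
#' any factor node's wProt is undefined (orphan enzyme activity).
#'
#' @param path character vector of class ids.
#' @param weights tibble from [compute_node_weights()].
#' @param rmsnet the `rms_network` the path lives in.
#' @param kind `"rea"`, `"pagerank"` or `"prot"`.
#' @return Numeric scalar (possibly `NA` for `"prot"`).
#' @export
score_path <- function(path, weights, rmsnet,
                       kind = c("rea", "pagerank", "prot")) {
  kind <- match.arg(kind)
  L <- length(path) - 1L
  stopifnot(L >= 1L)
  ekey <- paste(rmsnet$edges$from, rmsnet$edges$to, sep = "\r")
  pr <- rmsnet$edges$prob[match(paste(path[-length(path)], path[-1], sep = "\r"),
                                ekey)]
  if (anyNA(pr))
    stop(sprintf("path %s uses a transition absent from the RMS network",
                 paste(path, collapse = "->")), call. = FALSE)
  wcol <- c(rea = "w_rea", pagerank = "w_pagerank", prot = "w_prot")[[kind]]
  w <- weights[[wcol]][match(path[-length(path)], weights$class_id)]
  if (kind == "prot" && anyNA(w)) return(NA_real_)
  exp(mean(log(w * pr)))
}

#' Find conserved chemical transformation modules
#'
#' Enumerates loop-free RMS paths, computes their PCI against the known
#' pathways, keeps paths with `PCI >= min_pci`, attaches the supporting
#' reaction paths and (when weights are given) the three conservation
#' scores.
#'
#' @param rmsnet an `rms_network`.
#' @param pathways pathway link tibble.
#' @param cls an `rms_classification`.
#' @param weights optional tibble from [compute_node_weights()].
#' @param min_pci minimum PCI for a conserved module (default 2).
#' @param min_len,max_len path length range in edges (defaults 1 and 4).
#' @param support PCI support rule, see [compute_pci()].
#' @return A tibble of class `rms_modules`: `path_id`, `nodes`,
#'   `length`, `pci`, `score_rea`, `score_pagerank`, `score_prot`,
#'   `n_supports`, `supports` (list of tibbles `rxn_seq`,
#'   `pathway_ids`).
#' @export
find_conserved_modules <- function(rmsnet, pathways, cls, weights = NULL,
                                   min_pci = 2L, min_len = 1L, max_len = 4L,
                                   support = "pathway") {
  paths <- enumerate_rms_paths(rmsnet, min_len = min_len, max_len = max_len)
  scored <- score_enumerated_paths(paths, rmsnet, pathways, cls, weights,
                                   support = support)
  out <- scored[scored$pci >= min_pci, , drop = FALSE]
  w <- supporting_windows(pathways, cls, rmsnet$height,
                          lengths = min_len:max_len, support = support)
  out$supports <- lapply(out$path_id, function(k) {
    ww <- w[w$class_seq == k, ]
    ww |> dplyr::group_by(rxn_seq = .data$rxn_seq) |>
      dplyr::summarise(pathway_ids = paste(sort(unique(.data$pathway_id),
                                                method = "radix"),
                                           collapse = ";"),
                       .groups = "drop")
  })
  out$n_supports <- vapply(out$supports, nrow, integer(1))
  class(out) <- c("rms_modules", class(out))
  out
}

# PCI + scores for an enumerated path table.
score_enumerated_paths <- function(paths, rmsnet, pathways, cls,
                                   weights = NULL, support = "pathway") {
  if (!nrow(paths)) {
    paths$pci <- integer()
    paths$score_rea <- paths$score_pagerank <- paths$score_prot <- double()
    return(paths)
  }
  w <- supporting_windows(pathways, cls, rmsnet$height,
                          lengths = sort(unique(paths$length)),
                          support = support)
  pci_tbl <- w |> dplyr::distinct(.data$class_seq, .data$rxn_seq) |>
    dplyr::count(.data$class_seq, name = "pci")
  paths$pci <- pci_tbl$pci[match(paths$path_id, pci_tbl$class_seq)]
  paths$pci[is.na(paths$pci)] <- 0L
  if (!is.null(weights)) {
    paths$score_rea <- vapply(paths$nodes, score_path, double(1),
                              weights = weights, rmsnet = rmsnet, kind = "rea")
    paths$score_pagerank <- vapply(paths$nodes, score_path, double(1),
                                   weights = weights, rmsnet = rmsnet,
                                   kind = "pagerank")
    paths$score_prot <- vapply(paths$nodes, score_path, double(1),
                               weights = weights, rmsnet = rmsnet,
                               kind = "prot")
  }
  paths
}

#' Score every enumerated path and mark known metabolic windows
#'
#' Convenience wrapper producing the per-path table behind the
#' score-separation analysis: all loop-free paths with PCI and scores,
#' plus a flag for paths that occur as windows of known pathways.
#'
#' @inheritParams find_conserved_modules
#' @return Tibble like [find_conserved_modules()] (without supports)
#'   plus a logical `known_window`.
#' @export
score_all_paths <- function(rmsnet, pathways, cls, weights,
                            min_len = 1L, max_len = 4L, support = "pathway") {
  paths <- enumerate_rms_paths(rmsnet, min_len = min_len, max_len = max_len)
  scored <- score_enumerated_paths(paths, rmsnet, pathways, cls, weights,
                                   support = support)
  scored$known_window <- scored$pci >= 1L
  scored
}

#' Pathway conservation summary by pathway type
#'
#' Number and fraction of pathways, per type, containing at least one
#' conserved module window of the given length.
#'
#' @param pathways pathway link tibble.
#' @param modules an `rms_modules` tibble (see
#'   [find_conserved_modules()]).
#' @param cls the classification used for the modules.
#' @param height RMS height of the module network.
#' @param length window length in edges (default 2).
#' @param min_pci PCI threshold (default 2).
#' @return Tibble `type`, `n_pathways`, `n_conserved`, `fraction`, with
#'   an `"All"` total row.
#' @export
pathway_conservation_summary <- function(pathways, modules, cls, height = 1L,
                                         length = 2L, min_pci = 2L) {
  mod_keys <- modules$path_id[modules$length == length &
                                modules$pci >= min_pci]
  w <- pathway_windows(pathways, cls, height = height, lengths = length)
  conserved_pw <- unique(w$pathway_id[w$class_seq %in% mod_keys])
  pw <- dplyr::distinct(pathways[c("pathway_id", "type")])
  per_type <- pw |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_pathways = dplyr::n(),
      n_conserved = sum(.data$pathway_id %in% conserved_pw),
      .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_conserved / .data$n_pathways) |>
    dplyr::arrange(.data$type)
  total <- tibble::tibble(
    type = "All", n_pathways = nrow(pw),
    n_conserved = length(conserved_pw),
    fraction = if (nrow(pw)) length(conserved_pw) / nrow(pw) else NA_real_)
  dplyr::bind_rows(per_type, total)
}

#' Write a path/score table as TSV
#'
#' Columns `node_sequence, length, PCI, scoreRea, scorePageRank,
#' scoreProt, n_supports`; undefined scoreProt is written as an empty
#' field, never 0.
#'
#' @param paths tibble from [find_conserved_modules()] or
#'   [score_all_paths()].
#' @param path output file.
#' @export
write_paths <- function(paths, path) {
  df <- data.frame(
    node_sequence = paths$path_id,
    length = paths$length,
    PCI = paths$pci,
    scoreRea = if ("score_rea" %in% names(paths)) paths$score_rea else NA,
    scorePageRank = if ("score_pagerank" %in% names(paths)) paths$score_pagerank else NA,
    scoreProt = if ("score_prot" %in% names(paths)) paths$score_prot else NA,
    n_supports = if ("n_supports" %in% names(paths)) paths$n_supports else NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
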