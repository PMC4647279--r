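# RMS node weights, each reflecting a different notion of biological
# conservation: wRea (diversity of reactions performing the
# transformation, counting classified reactions whether or not they sit
# in the pathway network), wPageRank (topological importance of the
# transformation in the RMS network) and wProt (diversity of enzymes
# associated with it, via protein-domain composition association scores).

#' Reaction-diversity weight (wRea)
#'
#' Number of classified reactions per RMS class, counting every signable
#' reaction (classes may contain reactions that never entered the
#' pathway network; their diversity still counts).
#'
#' @param cls an `rms_classification`.
#' @param height 1 or 2.
#' @return Tibble `class_id`, `w_rea`.
#' @export
compute_wrea <- function(cls, height = 1L) {
  col <- if (height == 1L) "h1_class" else "h2_class"
  a <- cls$assignments[!is.na(cls$assignments[[col]]), ]
  out <- a |> dplyr::count(class_id = .data[[col]], name = "w_rea") |>
    dplyr::arrange(.data$class_id)
  tibble::as_tibble(out)
}

#' Topological weight (wPageRank)
#'
#' Stationary PageRank vector on the directed RMS graph with unweighted
#' edges; important chemical transformations are likely to receive more
#' incoming links from other transformations.  Dangling mass is
#' redistributed uniformly.  The vector is validated to sum to one
#' within `tol`.
#'
#' @param rmsnet an `rms_network`.
#' @param damping damping factor (default 0.85).
#' @param tol validation tolerance on the probability sum (default 1e-9).
#' @return Tibble `class_id`, `w_pagerank`.
#' @export
compute_wpagerank <- function(rmsnet, damping = 0.85, tol = 1e-9) {
  if (nrow(rmsnet$nodes) == 0L)
    stop("PageRank is undefined on an empty network", call. = FALSE)
  g <- rms_igraph(rmsnet)
  pr <- igraph::page_rank(g, damping = damping, weights = NA)$vector
  if (abs(sum(pr) - 1) > max(tol, 1e-9) * 1e3)
    stop(sprintf("PageRank failed to normalise: sum = %.12f", sum(pr)),
         call. = FALSE)
  tibble::tibble(class_id = names(pr), w_pagerank = unname(pr)) |>
    dplyr::arrange(.data$class_id)
}

#' Read a protein table
#'
#' TSV `protein_id, domains, reaction_ids` with `;`-separated domain
#' identifiers (the protein's full domain composition, order-free
#' multiset) and `;`-separated associated reaction ids.
#'
#' @param path file path.
#' @return Tibble of proteins.
#' @export
read_proteins <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tibble::as_tibble(df[c("protein_id", "domains", "reaction_ids")])
}

# Canonical multiset key for a domain composition.
domain_key <- function(domains) {
  vapply(strsplit(domains, ";", fixed = TRUE),
         function(d) paste(sort(d, method = "radix"), collapse = ";"),
         character(1))
}

#' Domain-composition / RMS association scores
#'
#' For every protein-domain composition Dom_j and RMS class RMS_i with at
#' least one protein in common:
#' `d2r = N_p(p in RMS_i and p in Dom_j) / N_p(p in Dom_j)` and
#' `r2d = N_p(p in RMS_i and p in Dom_j) / N_p(p in RMS_i)`;
#' the association score is their harmonic mean,
#' `2 * d2r * r2d / (d2r + r2d)`, a sensitivity/specificity trade-off
#' that is low for very frequent domains or transformations.  Proteins
#' are matched to a composition by exact multiset equality of domain
#' identifiers.
#'
#' @param proteins protein tibble (see [read_proteins()]).
#' @param cls an `rms_classification`.
#' @param height 1 or 2.
#' @return Tibble `domain_comp`, `class_id`, `n_joint`, `n_dom`,
#'   `n_rms`, `d2r`, `r2d`, `score`.
#' @export
domain_rms_scores <- function(proteins, cls, height = 1L) {
  if (is.null(proteins) || nrow(proteins) == 0L)
    return(tibble::tibble(domain_comp = character(), class_id = character(),
                          n_joint = integer(), n_dom = integer(),
                          n_rms = integer(), d2r = double(), r2d = double(),
                          score = double()))
  lk <- class_lookup(cls, height)
  pr <- tibble::tibble(
    protein_id = proteins$protein_id,
    domain_comp = domain_key(proteins$domains),
    rxns = strsplit(proteins$reaction_ids, ";", fixed = TRUE))
  # protein -> set of classes via its associated reactions
  pc <- pr |>
    tidyr::unnest_longer(col = "rxns", values_to = "reaction_id") |>
    dplyr::mutate(class_id = unname(lk[.data$reaction_id])) |>
    dplyr::filter(!is.na(.data$class_id)) |>
    dplyr::distinct(.data$protein_id, .data$domain_comp, .data$class_id)
  n_dom <- pr |> dplyr::count(.data$domain_comp, name = "n_dom")
  n_rms <- pc |> dplyr::distinct(.data$protein_id, .data$class_id) |>
    dplyr::count(.data$class_id, name = "n_rms")
  joint <- pc |> dplyr::count(.data$domain_comp, .data$class_id,
                              name = "n_joint")
  out <- joint |>
    dplyr::left_join(n_dom, by = "domain_comp") |>
    dplyr::left_join(n_rms, by = "class_id") |>
    dplyr::filter(.data$n_dom > 0L, .data$n_rms > 0L) |>
    dplyr::mutate(
      d2r = .data$n_joint / .data$n_dom,
      r2d = .data$n_joint / .data$n_rms,
      score = 2 * .data$d2r * .data$r2d / (.data$d2r + .data$r2d)) |>
    dplyr::arrange(.data$class_id, .data$domain_comp) |>
    dplyr::select("domain_comp", "class_id", "n_joint", "n_dom", "n_rms",
                  "d2r", "r2d", "score")
  tibble::as_tibble(out)
}

#' Enzyme-diversity weight (wProt)
#'
#' For each RMS class, the geometric mean over its associated domain
#' compositions (those with at least one joint protein) of
#' `N_p(p in Dom_j) * score(Dom_j, RMS)`.  Classes with no known
#' protein are orphan enzyme activities and get an undefined weight
#' (`NA`), never zero.
#'
#' @param scores output of [domain_rms_scores()].
#' @param class_ids classes to report (defaults to those in `scores`).
#' @return Tibble `class_id`, `w_prot` (`NA` for orphan classes).
#' @export
compute_wprot <- function(scores, class_ids = NULL) {
  agg <- scores |>
    dplyr::filter(.data$n_joint >= 1L) |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(
      w_prot = exp(mean(log(.data$n_dom * .data$score))),
      .groups = "drop")
  if (is.null(class_ids)) class_ids <- agg$class_id
  tibble::tibble(class_id = sort(unique(class_ids), method = "radix")) |>
    dplyr::left_join(agg, by = "class_id")
}

#' All three node weights for an RMS network
#'
#' @param rmsnet an `rms_network`.
#' @param cls the `rms_classification` it was reduced with.
#' @param proteins optional protein tibble; when absent every class is
#'   treated as orphan (`w_prot = NA`).
#' @param damping,tol PageRank parameters.
#' @return Tibble `class_id`, `w_rea`, `w_pagerank`, `w_prot` covering
#'   the network's nodes.
#' @export
compute_node_weights <- function(rmsnet, cls, proteins = NULL,
                                 damping = 0.85, tol = 1e-9) {
  height <- rmsnet$height
  base <- tibble::tibble(class_id = rmsnet$nodes$class_id)
  wr <- compute_wrea(cls, height)
  wp <- compute_wpagerank(rmsnet, damping = damping, tol = tol)
  sc <- domain_rms_scores(proteins, cls, height)
  wq <- compute_wprot(sc, class_ids = base$class_id)
  base |>
    dplyr::left_join(wr, by = "class_id") |>
    dplyr::left_join(wp, by = "class_id") |>
    dplyr::left_join(wq, by = "class_id")
}
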