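# Canonical atomic signatures.
#
# The atomic signature of height h rooted at an atom is a canonical string
# of the induced ball of radius h around the root.  Atom tokens are
# "[element]" with the charge appended (e.g. "[O-]", "[N+]") and lowercase
# element symbols for aromatic atoms; bond prefixes are "" (single), "=",
# "#", ":".  Sibling branches are ordered so that the concatenation of the
# emitted branch strings is lexicographically minimal, which makes the
# string independent of atom input order.  An atom reachable by two <=h
# paths appears once; the extra edges become SMILES-like ring-closure
# tokens "%n", numbered in order of first appearance in the final string.

bond_token <- function(order) c("", "=", "#", ":")[order]

atom_token <- function(element, charge, aromatic) {
  el <- if (aromatic) tolower(element) else element
  ch <- if (charge == 0L) ""
        else if (charge == 1L) "+"
        else if (charge == -1L) "-"
        else sprintf("%+d", charge)
  paste0("[", el, ch, "]")
}

# Induced ball of radius h around root: atom indices and induced bonds.
sig_ball <- function(m, root, h) {
  n <- nrow(m$atoms)
  dist <- rep(NA_integer_, n)
  dist[root] <- 0L
  frontier <- root
  adj <- vector("list", n)
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  d <- 0L
  while (length(frontier) && d < h) {
    d <- d + 1L
    nxt <- integer()
    for (u in frontier) for (v in adj[[u]]) if (is.na(dist[v])) {
      dist[v] <- d
      nxt <- c(nxt, v)
    }
    frontier <- nxt
  }
  keep <- which(!is.na(dist))
  bonds <- m$bonds[m$bonds$a1 %in% keep & m$bonds$a2 %in% keep, , drop = FALSE]
  list(atoms = keep, bonds = bonds)
}

#' Canonical atomic signature
#'
#' Returns the canonical string of the subgraph of all atoms within `h`
#' bonds of `root`, rooted at `root`.  See the package vignette for the
#' exact canonicalization rules.
#'
#' @param m a standardized `rms_molecule`.
#' @param root atom index.
#' @param h height (neighborhood radius in bonds); the classification
#'   pipeline uses 1 and 2.
#' @return A character scalar.
#' @examples
#' methane <- standardize_molecule(parse_molecule("C", "smiles"))
#' atomic_signature(methane, 1, 1)  # "[C]([H][H][H][H])"
#' @export
atomic_signature <- function(m, root, h) {
  stopifnot(inherits(m, "rms_molecule"))
  if (length(root) != 1L || is.na(root) || root < 1L || root > nrow(m$atoms))
    stop(sprintf("invalid root atom index: %s", root), call. = FALSE)
  if (h < 0L) stop("height must be non-negative", call. = FALSE)
  tokens <- mapply(atom_token, m$atoms$element, m$atoms$charge,
                   m$atoms$aromatic, USE.NAMES = FALSE)
  if (h == 0L) return(tokens[root])
  ball <- sig_ball(m, root, h)
  nb <- length(ball$atoms)
  # adjacency within the ball with bond orders
  adj <- stats::setNames(rep(list(NULL), nb), ball$atoms)
  idx <- stats::setNames(seq_len(nb), ball$atoms)
  ord <- matrix(0L, nb, nb)
  if (nrow(ball$bonds)) {
    for (k in seq_len(nrow(ball$bonds))) {
      i <- idx[[as.character(ball$bonds$a1[k])]]
      j <- idx[[as.character(ball$bonds$a2[k])]]
      o <- ball$bonds$order[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      ord[i, j] <- o; ord[j, i] <- o
    }
  }
  toks <- tokens[ball$atoms]
  r <- idx[[as.character(root)]]
  if (nrow(ball$bonds) == nb - 1L) {
    canon_tree_sig(adj, ord, toks, r)
  } else {
    canon_cyclic_sig(adj, ord, toks, r)
  }
}

# All permutations of seq_len(n), n <= 4 in practice (valence-bounded).
.perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1L) list(1L) else {
      out <- list()
      for (i in seq_len(n)) for (q in Recall(n - 1L)) {
        rest <- seq_len(n)[-i]
        out[[length(out) + 1L]] <- c(i, rest[q])
      }
      out
    }
    cache[[key]] <<- p
    p
  }
})

# Exact canonical string for an acyclic ball: bottom-up, choosing at each
# node the child ordering whose concatenation is lexicographically minimal.
canon_tree_sig <- function(adj, ord, toks, root) {
  rec <- function(u, parent) {
    kids <- setdiff(adj[[u]], parent)
    if (!length(kids)) return(toks[u])
    strs <- vapply(kids, function(v) paste0(bond_token(ord[u, v]), rec(v, u)),
                   character(1))
    if (length(strs) > 1L) {
      best <- NULL
      for (p in .perms(length(strs))) {
        cand <- paste(strs[p], collapse = "")
        if (is.null(best) || cand < best) best <- cand
      }
    } else best <- strs
    paste0(toks[u], "(", best, ")")
  }
  rec(root, 0L)
}

# Canonical string for a cyclic ball: enumerate DFS child orderings with a
# step cap, emit ring closures SMILES-style, keep the lexicographic
# minimum.  Balls are small (radius <= 2), so the enumeration is cheap.
canon_cyclic_sig <- function(adj, ord, toks, root, max_steps = 2e6) {
  n <- length(toks)
  best <- NULL
  steps <- 0L
  visited <- rep(FALSE, n)
  events <- list()
  nev <- 0L
  push <- function(e) { nev <<- nev + 1L; events[[nev]] <<- e }
  closure_seen <- character()

  finish <- function() {
    s <- stringify_events(events[seq_len(nev)], toks, ord)
    if (is.null(best) || s < best) best <<- s
  }
  # process the remaining (unordered) children of u, then call cont();
  # every branch restores the event stack after exploring it
  process <- function(rem, u, cont) {
    steps <<- steps + 1L
    if (steps > max_steps)
      stop("signature canonicalization exceeded the complexity cap",
           call. = FALSE)
    if (!length(rem)) { cont(); return(invisible()) }
    tried_noop <- FALSE
    for (i in seq_along(rem)) {
      c_ <- rem[i]
      rest <- rem[-i]
      if (visited[c_]) {
        key <- paste(min(u, c_), max(u, c_))
        if (key %in% closure_seen) {
          # edge already emitted from the other side: a no-op child slot;
          # taking it in more than one position only duplicates strings
          if (!tried_noop) { tried_noop <- TRUE; process(rest, u, cont) }
        } else {
          mark <- nev
          closure_seen <<- c(closure_seen, key)
          push(list(t = "ring", u = u, v = c_))
          process(rest, u, cont)
          nev <<- mark
          closure_seen <<- setdiff(closure_seen, key)
        }
      } else {
        visited[c_] <<- TRUE
        do_node(c_, u, function() process(rest, u, cont))
        visited[c_] <<- FALSE
      }
    }
  }
  do_node <- function(u, parent, cont) {
    mark <- nev
    push(list(t = "atom", u = u))
    kids <- setdiff(adj[[u]], parent)
    if (!length(kids)) {
      cont()
    } else {
      push(list(t = "open"))
      process(kids, u, function() {
        m2 <- nev
        push(list(t = "close"))
        cont()
        nev <<- m2
      })
    }
    nev <<- mark
  }
  visited[root] <- TRUE
  do_node(root, 0L, finish)
  best
}

# Assemble an event stream into the final string.  Ring-closure tokens are
# attached immediately after the atom tokens of both endpoints and
# numbered in order of first appearance in the string.
stringify_events <- function(events, toks, ord) {
  ring_at <- list()
  ring_bond <- list()
  rid <- 0L
  for (e in events) if (e$t == "ring") {
    rid <- rid + 1L
    ring_at[[as.character(e$u)]] <- c(ring_at[[as.character(e$u)]], rid)
    ring_at[[as.character(e$v)]] <- c(ring_at[[as.character(e$v)]], rid)
    ring_bond[[rid]] <- bond_token(ord[e$u, e$v])
  }
  txt <- character()
  ids <- integer()   # ring event id per emitted piece (0 = plain text)
  emit <- function(s, id = 0L) {
    txt[[length(txt) + 1L]] <<- s
    ids[[length(ids) + 1L]] <<- id
  }
  for (e in events) {
    if (e$t == "atom") {
      emit(toks[e$u])
      for (id in ring_at[[as.character(e$u)]]) {
        emit(ring_bond[[id]])
        emit("", id = id)
      }
    } else if (e$t == "open") emit("(")
    else if (e$t == "close") emit(")")
  }
  if (rid > 0L) {
    seen <- integer()
    for (k in which(ids > 0L)) {
      if (!ids[k] %in% seen) seen <- c(seen, ids[k])
      txt[k] <- paste0("%", match(ids[k], seen))
    }
  }
  paste(txt, collapse = "")
}

#' Molecular signature (multiset of atomic signatures)
#'
#' Every atom of the molecule contributes exactly one rooted signature, so
#' the counts sum to the atom count.
#'
#' @inheritParams atomic_signature
#' @return A tibble with columns `signature` and `count`, plus attributes
#'   `height` and `molecule_id`.  Rows are sorted bytewise by signature.
#' @examples
#' methane <- standardize_molecule(parse_molecule("C", "smiles"))
#' molecular_signature(methane, 1)
#' @export
molecular_signature <- function(m, h) {
  stopifnot(inherits(m, "rms_molecule"))
  if (!isTRUE(m$standardized))
    stop("molecule must be standardized before computing signatures",
         call. = FALSE)
  if (h > 2L)
    rlang::warn(sprintf(
      "height %d signatures are unusually precise; heights 1-2 are typical", h),
      .frequency = "once", .frequency_id = "rmsnet_high_height")
  sigs <- vapply(seq_len(nrow(m$atoms)), function(i) atomic_signature(m, i, h),
                 character(1))
  tab <- table(sigs)
  out <- tibble::tibble(signature = names(tab), count = as.integer(tab))
  out <- out[order(out$signature, method = "radix"), ]
  attr(out, "height") <- h
  attr(out, "molecule_id") <- m$id
  out
}

#' Dump molecular signatures for a set of molecules
#'
#' @param molecules named list of standardized `rms_molecule` objects.
#' @param heights integer vector of heights.
#' @return Tibble with columns `molecule_id`, `height`, `signature`,
#'   `count` (the TSV dump format).
#' @export
signature_table <- function(molecules, heights = c(1L, 2L)) {
  purrr::map_dfr(heights, function(h) {
    purrr::map_dfr(molecules, function(m) {
      s <- molecular_signature(m, h)
      tibble::tibble(molecule_id = m$id, height = h,
                     signature = s$signature, count = s$count)
    })
  })
}
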