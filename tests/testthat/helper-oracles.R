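# Independent oracles, written without reusing the package's internals.

# Brute-force canonical signature for acyclic balls: enumerate the full
# cartesian product of branch orderings at every node and take the
# bytewise minimum of the complete strings.
oracle_signature <- function(m, root, h) {
  n <- nrow(m$atoms)
  adj <- vector("list", n)
  bnd <- matrix(0L, n, n)
  for (k in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    bnd[a, b] <- bnd[b, a] <- m$bonds$order[k]
  }
  tok <- function(i) {
    el <- m$atoms$element[i]
    if (m$atoms$aromatic[i]) el <- tolower(el)
    q <- m$atoms$charge[i]
    ch <- if (q == 0) "" else if (q == 1) "+" else if (q == -1) "-"
          else sprintf("%+d", q)
    paste0("[", el, ch, "]")
  }
  btok <- c("", "=", "#", ":")
  # distances by plain BFS
  dist <- rep(Inf, n); dist[root] <- 0
  queue <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (dist[v] > dist[u] + 1) {
      dist[v] <- dist[u] + 1
      queue <- c(queue, v)
    }
  }
  if (h == 0) return(tok(root))
  inball <- dist <= h
  perms_of <- function(k) {
    if (k == 1) return(list(1L))
    out <- list()
    for (i in seq_len(k)) for (p in perms_of(k - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(k)[-i])[p])
    }
    out
  }
  # all possible strings of the subtree rooted at u
  all_strings <- function(u, parent) {
    kids <- setdiff(adj[[u]][inball[adj[[u]]]], parent)
    if (!length(kids)) return(tok(u))
    kid_strs <- lapply(kids, function(v)
      paste0(btok[bnd[u, v]], all_strings(v, u)))
    out <- character()
    for (p in perms_of(length(kids))) {
      grids <- expand.grid(kid_strs[p], stringsAsFactors = FALSE)
      out <- c(out, paste0(tok(u), "(",
                           apply(grids, 1, paste, collapse = ""), ")"))
    }
    unique(out)
  }
  min(all_strings(root, 0L))
}

# Naive signed multiset subtraction: expand each side into a bag of
# signature strings, cancel pairwise, count what remains.
oracle_rms_diff <- function(prod_sigs, sub_sigs) {
  expand <- function(lst) {
    unlist(lapply(lst, function(x) rep(rep(x$sig$signature, x$sig$count),
                                       x$coeff)))
  }
  bag_p <- expand(prod_sigs)
  bag_s <- expand(sub_sigs)
  for (s in unique(bag_p)) {
    np <- sum(bag_p == s); ns <- sum(bag_s == s)
    k <- min(np, ns)
    if (k > 0) {
      bag_p <- bag_p[-utils::head(which(bag_p == s), k)]
      bag_s <- bag_s[-utils::head(which(bag_s == s), k)]
    }
  }
  cp <- table(bag_p); cs <- table(bag_s)
  sigs <- sort(unique(c(names(cp), names(cs))), method = "radix")
  counts <- vapply(sigs, function(s) {
    as.integer(sum(bag_p == s)) - as.integer(sum(bag_s == s))
  }, integer(1))
  tibble::tibble(signature = sigs, count = unname(counts))
}

# Plain power-iteration PageRank with uniform dangling redistribution.
oracle_pagerank <- function(nodes, edges, damping = 0.85, iters = 500) {
  n <- length(nodes)
  pr <- rep(1 / n, n)
  names(pr) <- nodes
  out <- split(edges$to, edges$from)
  for (it in seq_len(iters)) {
    nxt <- rep((1 - damping) / n, n)
    names(nxt) <- nodes
    for (u in nodes) {
      tgts <- out[[u]]
      if (is.null(tgts) || !length(tgts)) {
        nxt <- nxt + damping * pr[[u]] / n
      } else {
        for (v in tgts) nxt[[v]] <- nxt[[v]] + damping * pr[[u]] / length(tgts)
      }
    }
    if (max(abs(nxt - pr)) < 1e-14) { pr <- nxt; break }
    pr <- nxt
  }
  pr
}

# Brute-force simple-path enumeration over an edge list.
oracle_simple_paths <- function(nodes, edges, min_len, max_len) {
  out <- character()
  succ <- split(edges$to, edges$from)
  grow <- function(path) {
    if (length(path) - 1 >= min_len)
      out[[length(out) + 1]] <<- paste(path, collapse = "->")
    if (length(path) - 1 >= max_len) return()
    for (v in succ[[path[length(path)]]]) {
      if (!v %in% path) grow(c(path, v))
    }
  }
  for (s in nodes) grow(s)
  sort(out)
}

# O(n^2) pair-counting Rand index.
oracle_rand <- function(la, lb) {
  n <- length(la)
  conc <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- la[i] == la[j]
    same_b <- lb[i] == lb[j]
    if (same_a == same_b) conc <- conc + 1L
  }
  conc / choose(n, 2)
}

# Textbook dynamic-programming Levenshtein distance.
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x); d[1, ] <- 0:length(y)
  for (i in seq_along(x)) for (j in seq_along(y)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  }
  d[length(x) + 1, length(y) + 1]
}

# Random valence-correct acyclic molecule with 2-5 heavy atoms (about
# 12 atoms once hydrogens are explicit).  Uses the caller's RNG stream.
random_molecule <- function(id = "rand") {
  caps <- c(C = 4L, N = 3L, O = 2L)
  nh <- sample(2:5, 1)
  el <- sample(names(caps), nh, replace = TRUE)
  left <- unname(caps[el])
  a1 <- integer(); a2 <- integer(); ord <- integer()
  n_used <- 1L
  for (i in 2:nh) {
    cand <- which(left[seq_len(n_used)] >= 1L)
    if (!length(cand)) break  # no free valence anywhere: stop growing
    j <- if (length(cand) == 1L) cand else sample(cand, 1)
    o <- if (left[j] >= 2L && left[i] >= 2L && stats::runif(1) < 0.25) 2L else 1L
    a1 <- c(a1, j); a2 <- c(a2, i); ord <- c(ord, o)
    left[j] <- left[j] - o; left[i] <- left[i] - o
    n_used <- i
  }
  new_molecule(
    tibble::tibble(element = el[seq_len(n_used)], charge = 0L,
                   aromatic = FALSE),
    tibble::tibble(a1 = a1, a2 = a2, order = ord), id = id)
}

# Class sequences realized by the planted (main-chain) pathways.
planted_window_ids <- function(run, fx, height = 1L) {
  main <- fx$pathways[grepl("_main$", fx$pathways$pathway_id), ]
  unique(unlist(lapply(1:4, function(L)
    pathway_to_rms_paths(main, run$classification, length = L,
                         height = height)$class_seq)))
}
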