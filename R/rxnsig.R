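# Reaction Molecular Signatures: the signed multiset of atomic signatures
# obtained as (products - substrates), stoichiometry-weighted.  Reactions
# sharing an RMS perform the same chemical transformation; strictly
# opposite multisets (the two directions of one transformation) are merged
# into a single canonical key.

#' Read a reaction table
#'
#' TSV with columns `reaction_id`, `substrates`, `products`, `ec`,
#' `is_transport`.  Sides are written `compound:coeff;compound:coeff`;
#' coefficients are positive integers.  `ec` may hold several
#' `;`-separated EC numbers or be empty.
#'
#' @param path file path.
#' @return Tibble with list-columns `substrates` and `products`, each a
#'   tibble of `compound`, `coeff`.
#' @export
read_reactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tibble::tibble(
    reaction_id = as.character(df$reaction_id),
    substrates = lapply(df$substrates, parse_side),
    products = lapply(df$products, parse_side),
    ec = ifelse(is.na(df$ec) | df$ec == "", NA_character_, as.character(df$ec)),
    is_transport = as.logical(df$is_transport))
}

parse_side <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble::tibble(
    compound = vapply(kv, `[`, character(1), 1),
    coeff = as.integer(vapply(kv, function(x) if (length(x) > 1) x[2] else "1",
                              character(1))))
}

format_side <- function(side) {
  paste(sprintf("%s:%d", side$compound, side$coeff), collapse = ";")
}

#' Check the elemental and charge balance of reactions
#'
#' Element deltas are products minus substrates, weighted by
#' stoichiometry; a reaction is balanced iff every element delta and the
#' charge delta is zero.  Reactions referencing a compound without a
#' structure are flagged `"structure unavailable"` (they cannot be signed,
#' mirroring the filtering of reactions without proper Molfile
#' structures).
#'
#' @param reactions reaction tibble (see [read_reactions()]).
#' @param molecules named list of `rms_molecule` objects; standardized
#'   on the fly when needed.
#' @return Tibble with one row per reaction: `reaction_id`, `status`
#'   (`"ok"` or `"structure unavailable"`), `balanced`, `charge_delta`,
#'   and list-column `element_deltas` (named integer vectors).
#' @export
check_balance <- function(reactions, molecules) {
  molecules <- standardize_all(molecules)
  rows <- lapply(seq_len(nrow(reactions)), function(i) {
    rx <- reactions[i, ]
    cpds <- c(rx$substrates[[1]]$compound, rx$products[[1]]$compound)
    missing <- setdiff(cpds, names(molecules))
    if (length(missing)) {
      return(tibble::tibble(reaction_id = rx$reaction_id,
                            status = "structure unavailable",
                            balanced = NA, charge_delta = NA_integer_,
                            element_deltas = list(NULL)))
    }
    acc <- function(side, sign) {
      out <- integer(); chg <- 0L
      for (k in seq_len(nrow(side))) {
        f <- mol_formula(molecules[[side$compound[k]]])
        w <- sign * side$coeff[k]
        for (el in names(f)) out[el] <- (if (is.na(out[el])) 0L else out[el]) + w * f[[el]]
        chg <- chg + w * attr(f, "charge")
      }
      list(el = out, chg = chg)
    }
    p <- acc(rx$products[[1]], 1L)
    s <- acc(rx$substrates[[1]], -1L)
    els <- union(names(p$el), names(s$el))
    delta <- stats::setNames(vapply(els, function(e) {
      (if (is.na(p$el[e])) 0L else p$el[[e]]) +
        (if (is.na(s$el[e])) 0L else s$el[[e]])
    }, integer(1)), els)
    delta <- delta[delta != 0L]
    chg <- p$chg + s$chg
    tibble::tibble(reaction_id = rx$reaction_id, status = "ok",
                   balanced = length(delta) == 0L && chg == 0L,
                   charge_delta = chg, element_deltas = list(delta))
  })
  dplyr::bind_rows(rows)
}

standardize_all <- function(molecules) {
  lapply(molecules, function(m) if (isTRUE(m$standardized)) m
         else standardize_molecule(m))
}

#' Raw reaction molecular signature
#'
#' The signed multiset of atomic signatures of height `h`:
#' for every signature, `count = sum over products of coeff * count -
#' sum over substrates of coeff * count`.  Signatures of atoms whose
#' environment is unchanged cancel, so only the reaction center (and, at
#' height 2, its surroundings) remains.
#'
#' @param rx one row of a reaction tibble (a data frame with one row).
#' @param h signature height.
#' @param molecules named list of standardized `rms_molecule` objects.
#' @param sig_cache optional environment used to memoize molecular
#'   signatures across reactions (keyed `<compound>@<height>`).
#' @return Tibble `signature`, `count` (non-zero, sorted bytewise) with
#'   attributes `height` and `reaction_id`; zero rows for a chemically
#'   null transformation at this height.
#' @export
reaction_signature <- function(rx, h, molecules, sig_cache = NULL) {
  stopifnot(nrow(rx) == 1L)
  get_sig <- function(cpd) {
    key <- paste0(cpd, "@", h)
    if (!is.null(sig_cache) && !is.null(sig_cache[[key]])) return(sig_cache[[key]])
    m <- molecules[[cpd]]
    if (is.null(m))
      stop(sprintf("structure unavailable for compound '%s' (reaction %s)",
                   cpd, rx$reaction_id), call. = FALSE)
    s <- molecular_signature(m, h)
    if (!is.null(sig_cache)) sig_cache[[key]] <- s
    s
  }
  counts <- new.env(parent = emptyenv())
  add <- function(side, sign) {
    for (k in seq_len(nrow(side))) {
      s <- get_sig(side$compound[k])
      w <- sign * side$coeff[k]
      for (j in seq_len(nrow(s))) {
        sig <- s$signature[j]
        counts[[sig]] <- (counts[[sig]] %||% 0L) + w * s$count[j]
      }
    }
  }
  add(rx$products[[1]], 1L)
  add(rx$substrates[[1]], -1L)
  sigs <- ls(counts, sorted = FALSE)
  vals <- vapply(sigs, function(s) counts[[s]], integer(1))
  keep <- vals != 0L
  out <- tibble::tibble(signature = sigs[keep], count = unname(vals[keep]))
  out <- out[order(out$signature, method = "radix"), ]
  attr(out, "height") <- h
  attr(out, "reaction_id") <- rx$reaction_id
  out
}

negate_rms <- function(raw) {
  raw$count <- -raw$count
  raw
}

#' Serialize a raw RMS as a reproducible string
#'
#' Entries are written `±count:signature`, sorted bytewise, joined by
#' `|`.  The serialization alphabet is fixed so string distances are
#' reproducible run to run.
#'
#' @param raw a raw RMS tibble (`signature`, `count`).
#' @return Character scalar (empty string for a null transformation).
#' @export
serialize_rms <- function(raw) {
  if (!nrow(raw)) return("")
  ent <- sprintf("%+d:%s", raw$count, raw$signature)
  paste(sort(ent, method = "radix"), collapse = "|")
}

#' Canonical, orientation-merged RMS key
#'
#' The two directions of one transformation have strictly opposite signed
#' multisets; both serializations are computed and the bytewise smaller
#' one is the key, so `canonical_rms(RMS(r))` and
#' `canonical_rms(RMS(reverse(r)))` give the same key with opposite
#' orientation flags.
#'
#' @param raw non-empty raw RMS tibble.
#' @return List with `key`, `orientation` (`"forward"` if the reaction as
#'   written was kept, `"reversed"` otherwise) and `height`.
#' @export
canonical_rms <- function(raw) {
  if (!nrow(raw))
    stop("cannot canonicalize a null transformation (empty RMS)", call. = FALSE)
  fwd <- serialize_rms(raw)
  rev <- serialize_rms(negate_rms(raw))
  if (identical(fwd, rev))
    stop("self-inverse RMS encountered; impossible for a non-empty signed multiset",
         call. = FALSE)
  if (fwd <= rev) list(key = fwd, orientation = "forward",
                       height = attr(raw, "height"))
  else list(key = rev, orientation = "reversed", height = attr(raw, "height"))
}

#' Edit distance between serialized signatures
#'
#' Plain Levenshtein distance (insertions, deletions, substitutions all
#' cost 1) over the serialized height-2 RMS strings; symmetric and zero
#' iff the strings are equal.
#'
#' @param a,b character vectors of serialized RMS strings.
#' @return Numeric scalar when both are length 1, otherwise the distance
#'   matrix.
#' @export
signature_distance <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1L && length(b) == 1L) as.numeric(d) else d
}

#' Refine a height-1 class into height-2 sub-classes
#'
#' Pairwise Levenshtein distances between the members' serialized
#' height-2 RMS strings are clustered with the Ward algorithm and the
#' tree is cut at a cophenetic distance threshold (default 90, on the raw
#' edit-distance scale).  Members with identical strings always
#' co-cluster; a singleton input yields one sub-class.
#'
#' @param strings serialized height-2 RMS strings of the class members.
#' @param threshold cophenetic cut height.
#' @param linkage `hclust` method; `"ward.D"` by default.
#' @return Integer vector of sub-class indices (numbered by the bytewise
#'   smallest member string of each sub-class).
#' @export
refine_h2 <- function(strings, threshold = 90, linkage = "ward.D") {
  n <- length(strings)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  d <- utils::adist(strings)
  if (all(d == 0)) return(rep(1L, n))
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  cl <- stats::cutree(hc, h = threshold)
  renumber_clusters(cl, strings)
}

renumber_clusters <- function(cl, strings) {
  reps <- vapply(split(strings, cl), function(s) sort(s, method = "radix")[1],
                 character(1))
  newid <- match(as.character(cl), names(reps)[order(reps, method = "radix")])
  as.integer(newid)
}

#' Classify reactions by their Reaction Molecular Signatures
#'
#' Computes raw RMS at the requested heights, merges opposite
#' orientations into canonical keys, groups reactions by exact height-1
#' key equality, and refines each height-1 class into height-2
#' sub-classes by Ward clustering of Levenshtein distances (see
#' [refine_h2()]).  Transport reactions, reactions with missing
#' structures, unbalanced reactions and chemically null transformations
#' are excluded and reported with a reason, mirroring the filtering
#' applied to curated reaction databases.
#'
#' @param reactions reaction tibble (see [read_reactions()]).
#' @param molecules named list of `rms_molecule` objects.
#' @param heights heights to classify; `c(1, 2)` by default.
#' @param h2_threshold cophenetic cut for the height-2 refinement.
#' @param h2_linkage `hclust` linkage for the refinement.
#' @return An object of class `rms_classification`: a list with
#'   `assignments` (tibble `reaction_id`, `h1_class`, `h2_class`,
#'   `orientation`, `excluded_reason`), `classes` (tibble `class_id`,
#'   `height`, `key`, `n_members`, `members`), `h2_strings` (serialized
#'   height-2 RMS per classified reaction, orientation-aligned) and
#'   `params`.
#' @export
rms_classify <- function(reactions, molecules, heights = c(1L, 2L),
                         h2_threshold = 90, h2_linkage = "ward.D") {
  stopifnot(1L %in% heights)
  molecules <- standardize_all(molecules)
  bal <- check_balance(reactions, molecules)
  sig_cache <- new.env(parent = emptyenv())
  n <- nrow(reactions)
  excluded <- rep(NA_character_, n)
  key1 <- rep(NA_character_, n)
  orient <- rep(NA_character_, n)
  s2 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rx <- reactions[i, ]
    if (isTRUE(rx$is_transport)) { excluded[i] <- "transport"; next }
    if (bal$status[i] != "ok") { excluded[i] <- bal$status[i]; next }
    if (!isTRUE(bal$balanced[i])) { excluded[i] <- "unbalanced"; next }
    raw1 <- reaction_signature(rx, 1L, molecules, sig_cache)
    if (!nrow(raw1)) { excluded[i] <- "null transformation at height 1"; next }
    cr <- canonical_rms(raw1)
    key1[i] <- cr$key
    orient[i] <- cr$orientation
    if (2L %in% heights) {
      raw2 <- reaction_signature(rx, 2L, molecules, sig_cache)
      if (cr$orientation == "reversed") raw2 <- negate_rms(raw2)
      s2[i] <- serialize_rms(raw2)
    }
  }
  ok <- is.na(excluded)
  keys <- sort(unique(key1[ok]), method = "radix")
  h1_class <- rep(NA_character_, n)
  h1_class[ok] <- sprintf("H1.%04d", match(key1[ok], keys))
  h2_class <- rep(NA_character_, n)
  if (2L %in% heights && any(ok)) {
    for (cl in unique(h1_class[ok])) {
      idx <- which(!is.na(h1_class) & h1_class == cl)
      sub <- refine_h2(s2[idx], threshold = h2_threshold, linkage = h2_linkage)
      h2_class[idx] <- sprintf("%s.%d", cl, sub)
    }
  }
  assignments <- tibble::tibble(
    reaction_id = reactions$reaction_id,
    h1_class = h1_class, h2_class = h2_class,
    orientation = orient, excluded_reason = excluded)
  class_rows <- function(col, hh) {
    a <- assignments[!is.na(assignments[[col]]), ]
    sp <- split(a$reaction_id, a[[col]])
    key_col <- if (hh == 1L)
      keys[match(names(sp), sprintf("H1.%04d", seq_along(keys)))]
    else rep(NA_character_, length(sp))
    tibble::tibble(
      class_id = names(sp), height = hh, key = key_col,
      n_members = lengths(sp), members = unname(sp))
  }
  classes <- class_rows("h1_class", 1L)
  if (2L %in% heights) classes <- dplyr::bind_rows(classes, class_rows("h2_class", 2L))
  structure(list(
    assignments = assignments, classes = classes,
    h2_strings = stats::setNames(s2, reactions$reaction_id),
    params = list(heights = heights, h2_threshold = h2_threshold,
                  h2_linkage = h2_linkage)),
    class = "rms_classification")
}

#' @export
print.rms_classification <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("<rms_classification> %d reactions: %d classified, %d excluded\n",
              nrow(a), sum(!is.na(a$h1_class)), sum(!is.na(a$excluded_reason))))
  for (h in x$params$heights) {
    cl <- x$classes[x$classes$height == h, ]
    if (nrow(cl))
      cat(sprintf("  height %d: %d classes, %.2f reactions/class on average\n",
                  h, nrow(cl), mean(cl$n_members)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy rms_classification
#' @export
tidy.rms_classification <- function(x, ...) x$assignments

#' @method glance rms_classification
#' @export
glance.rms_classification <- function(x, ...) {
  a <- x$assignments
  h1 <- x$classes[x$classes$height == 1L, ]
  h2 <- x$classes[x$classes$height == 2L, ]
  tibble::tibble(
    n_reactions = nrow(a),
    n_classified = sum(!is.na(a$h1_class)),
    n_excluded = sum(!is.na(a$excluded_reason)),
    n_h1_classes = nrow(h1),
    n_h2_classes = nrow(h2),
    mean_members_h1 = if (nrow(h1)) mean(h1$n_members) else NA_real_,
    mean_members_h2 = if (nrow(h2)) mean(h2$n_members) else NA_real_)
}

#' Lookup of reaction to class id at one height
#'
#' @param cls an `rms_classification`.
#' @param height 1 or 2.
#' @return Named character vector (reaction id -> class id; `NA` for
#'   excluded reactions).
#' @export
class_lookup <- function(cls, height = 1L) {
  col <- if (height == 1L) "h1_class" else "h2_class"
  stats::setNames(cls$assignments[[col]], cls$assignments$reaction_id)
}

#' Write the classification table
#'
#' TSV `reaction_id, h1_class, h2_class, orientation, excluded_reason`.
#'
#' @param cls an `rms_classification`.
#' @param path file path.
#' @export
write_classification <- function(cls, path) {
  utils::write.table(cls$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
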