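# Agreement between the automated RMS classification and the
# human-curated EC hierarchy, measured with the Rand index over the
# third-level EC sub-subclasses.

#' Third-level EC sub-subclass
#'
#' Extracts the first three fields of an EC number (e.g. `"4.2.1.48"`
#' becomes `"4.2.1"`); the trailing level may be `"-"` or absent.
#'
#' @param ec character vector of EC numbers.
#' @return Character vector of sub-subclass labels.
#' @export
ec_subsubclass <- function(ec) {
  ok <- grepl("^[0-9]+\\.[0-9]+\\.[0-9]+(\\.([0-9]+|-))?$", ec)
  if (any(!ok))
    stop(sprintf("malformed EC number(s): %s",
                 paste(utils::head(ec[!ok], 5), collapse = ", ")),
         call. = FALSE)
  vapply(strsplit(ec, ".", fixed = TRUE),
         function(p) paste(p[1:3], collapse = "."), character(1))
}

#' Rand index between two partitions
#'
#' Fraction of concordant unordered item pairs (together in both
#' partitions or apart in both).  Items are matched by name; items
#' lacking a label in either partition are excluded before computation
#' (their count is reported as an attribute), mirroring the restriction
#' to reactions linked both to an EC number and to an RMS.
#'
#' @param a,b named character vectors (item -> class label); `NA`
#'   labels count as missing.
#' @return Numeric scalar in `[0, 1]` with attributes `n_items` and
#'   `n_excluded`.
#' @export
rand_index <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("partitions must be named vectors (item -> label)", call. = FALSE)
  universe <- union(names(a), names(b))
  shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  n <- length(shared)
  if (n < 2L)
    stop("Rand index needs at least 2 items labeled in both partitions",
         call. = FALSE)
  la <- a[shared]
  lb <- b[shared]
  ct <- table(la, lb)
  s_ij <- sum(choose(ct, 2))
  s_a <- sum(choose(rowSums(ct), 2))
  s_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  ri <- (tot + 2 * s_ij - s_a - s_b) / tot
  structure(ri, n_items = n, n_excluded = length(universe) - n)
}

#' Compare the RMS classification with the EC hierarchy
#'
#' Restricts to reactions carrying both an EC number and an RMS class,
#' partitions them by EC sub-subclass and by RMS class, and reports the
#' Rand index.  Reactions with several EC numbers use the first listed
#' by default; `multi_ec = "exclude"` drops them instead.
#'
#' @param cls an `rms_classification`.
#' @param reactions reaction tibble with an `ec` column
#'   (`;`-separated EC numbers or `NA`).
#' @param height 1 or 2.
#' @param multi_ec `"first"` (default) or `"exclude"`.
#' @return An object of class `ec_comparison`: list with `rand_index`,
#'   `n_items`, `n_excluded`, `n_ec_classes`, `n_rms_classes`,
#'   `height`, `multi_ec`.
#' @export
compare_with_ec <- function(cls, reactions, height = 1L,
                            multi_ec = c("first", "exclude")) {
  multi_ec <- match.arg(multi_ec)
  lk <- class_lookup(cls, height)
  ecs <- strsplit(ifelse(is.na(reactions$ec), "", reactions$ec), ";",
                  fixed = TRUE)
  ec1 <- vapply(ecs, function(e) {
    e <- e[nzchar(e)]
    if (!length(e)) NA_character_
    else if (length(e) > 1L && multi_ec == "exclude") NA_character_
    else e[1]
  }, character(1))
  has_ec <- !is.na(ec1)
  ec_part <- stats::setNames(rep(NA_character_, nrow(reactions)),
                             reactions$reaction_id)
  ec_part[has_ec] <- ec_subsubclass(ec1[has_ec])
  rms_part <- lk[reactions$reaction_id]
  ri <- rand_index(ec_part, rms_part)
  shared <- names(ec_part)[!is.na(ec_part) & !is.na(rms_part)]
  structure(list(
    rand_index = as.numeric(ri),
    n_items = attr(ri, "n_items"),
    n_excluded = attr(ri, "n_excluded"),
    n_ec_classes = length(unique(ec_part[shared])),
    n_rms_classes = length(unique(rms_part[shared])),
    height = height, multi_ec = multi_ec),
    class = "ec_comparison")
}

#' @export
print.ec_comparison <- function(x, ...) {
  cat(sprintf(
    "<ec_comparison> height %d: Rand index %.4f over %d reactions (%d EC sub-subclasses vs %d RMS classes; %d excluded)\n",
    x$height, x$rand_index, x$n_items, x$n_ec_classes, x$n_rms_classes,
    x$n_excluded))
  invisible(x)
}

#' @method glance ec_comparison
#' @export
glance.ec_comparison <- function(x, ...) {
  tibble::tibble(rand_index = x$rand_index, n_items = x$n_items,
                 n_excluded = x$n_excluded, n_ec_classes = x$n_ec_classes,
                 n_rms_classes = x$n_rms_classes, height = x$height)
}

#' Write an EC-comparison report as JSON
#'
#' @param x an `ec_comparison`.
#' @param path output file.
#' @export
write_ec_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
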