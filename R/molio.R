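#' Molecule objects
#'
#' A molecule is stored as an explicit chemical graph: a tibble of atoms
#' (element, formal charge, aromatic flag) and a tibble of bonds
#' (`a1`, `a2`, `order` with 1 = single, 2 = double, 3 = triple,
#' 4 = aromatic).  Atom indices are row numbers of the atom table.
#' Molecules produced by [standardize_molecule()] carry all hydrogens as
#' explicit atoms, so every atom contributes one rooted signature.
#'
#' @param atoms tibble with columns `element` (character), `charge`
#'   (integer) and `aromatic` (logical).
#' @param bonds tibble with integer columns `a1`, `a2`, `order`.
#' @param id compound identifier.
#' @param standardized logical, whether hydrogens are explicit and
#'   aromaticity has been perceived.
#' @param arom_model name of the aromaticity model applied (signature
#'   strings depend on it, so it is recorded on the object).
#' @return An object of class `rms_molecule`.
#' @export
new_molecule <- function(atoms, bonds, id = "mol", standardized = FALSE,
                         arom_model = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("element", "charge", "aromatic") %in% names(atoms)),
            all(c("a1", "a2", "order") %in% names(bonds)))
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n))
      stop("bond refers to an atom index outside the atom table", call. = FALSE)
    if (any(bonds$a1 == bonds$a2))
      stop("a bond must connect two distinct atoms", call. = FALSE)
    if (!all(bonds$order %in% 1:4))
      stop("bond order must be 1, 2, 3 or 4 (aromatic)", call. = FALSE)
  }
  structure(list(atoms = atoms, bonds = bonds, id = id,
                 standardized = standardized, arom_model = arom_model),
            class = "rms_molecule")
}

#' @export
print.rms_molecule <- function(x, ...) {
  cat(sprintf("<rms_molecule> %s: %d atoms, %d bonds%s\n", x$id,
              nrow(x$atoms), nrow(x$bonds),
              if (isTRUE(x$standardized)) " (standardized)" else ""))
  invisible(x)
}

#' Parse a molecule structure
#'
#' Reads one structure from a SMILES string or an MDL Molfile (V2000)
#' record.  SMILES interpretation is delegated to OpenBabel (via
#' \pkg{ChemmineOB}); the resulting V2000 block is decoded in-package so
#' that formal charges (atom-line codes and `M  CHG` properties) and
#' bond-less single-atom records survive intact.  The returned molecule is
#' *not* standardized; see [standardize_molecule()].
#'
#' @param text the structure: a SMILES string or the full Molfile text.
#' @param format `"smiles"` or `"molfile"`.
#' @param id compound identifier; defaults to the Molfile title line when
#'   present, otherwise `"mol"`.
#' @return An `rms_molecule`.
#' @examples
#' parse_molecule("CCO", "smiles", id = "ethanol")
#' @export
parse_molecule <- function(text, format = c("smiles", "molfile"), id = NULL) {
  format <- match.arg(format)
  if (format == "smiles") {
    mf <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", source = text),
      error = function(e) "")
    if (!grepl("V2000", mf, fixed = TRUE))
      stop(sprintf("SMILES parse failure for record '%s': %s",
                   id %||% text, text), call. = FALSE)
    m <- parse_v2000(mf, id = id %||% "mol")
    if (nrow(m$atoms) == 0L)
      stop(sprintf("SMILES parse failure for record '%s': %s",
                   id %||% text, text), call. = FALSE)
    m
  } else {
    parse_v2000(text, id = id)
  }
}

# Decode one MDL Molfile V2000 block into an rms_molecule.
parse_v2000 <- function(text, id = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  if (length(lines) < 4L)
    stop("malformed Molfile: fewer than 4 header lines", call. = FALSE)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb)
    stop(sprintf("malformed Molfile counts line in record '%s'",
                 id %||% trimws(lines[1])), call. = FALSE)
  title <- trimws(lines[1])
  if (is.null(id)) id <- if (nzchar(title)) title else "mol"
  if (na == 0L) {
    return(new_molecule(
      tibble::tibble(element = character(), charge = integer(),
                     aromatic = logical()),
      tibble::tibble(a1 = integer(), a2 = integer(), order = integer()),
      id = id))
  }
  al <- lines[5:(4 + na)]
  element <- trimws(substr(al, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(al, 37, 39)))
  chg_code[is.na(chg_code)] <- 0L
  # old-style atom-line charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3
  charge <- ifelse(chg_code %in% 1:3, 4L - chg_code,
                   ifelse(chg_code %in% 5:7, 4L - chg_code, 0L))
  if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- tibble::tibble(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds))
      stop(sprintf("malformed Molfile bond block in record '%s'", id),
           call. = FALSE)
  } else {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  # M  CHG properties override the atom-line codes
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (cl in chg_lines) {
      vals <- suppressWarnings(as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))),
                                                   "[[:space:]]+")[[1]]))
      npair <- vals[1]
      for (k in seq_len(npair)) {
        charge[vals[2 * k]] <- vals[2 * k + 1]
      }
    }
  }
  new_molecule(
    tibble::tibble(element = element, charge = as.integer(charge),
                   aromatic = FALSE),
    bonds, id = id)
}

#' Read molecules from a SMILES file
#'
#' One record per line, `SMILES<TAB>id`.
#'
#' @param path file path.
#' @return Named list of `rms_molecule` objects keyed by compound id.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mols <- lapply(parts, function(p) {
    id <- if (length(p) >= 2) p[2] else NULL
    parse_molecule(p[1], "smiles", id = id)
  })
  stats::setNames(mols, vapply(mols, function(m) m$id, character(1)))
}

#' Read molecules from an SDF / Molfile
#'
#' Multi-record SDF files (records separated by `$$$$`) are accepted.
#'
#' @param path file path.
#' @return Named list of `rms_molecule` objects.
#' @export
read_sdf <- function(path) {
  txt <- readLines(path)
  idx <- cumsum(c(TRUE, grepl("^\\$\\$\\$\\$", utils::head(txt, -1))))
  recs <- split(txt, idx)
  mols <- list()
  for (r in recs) {
    r <- r[!grepl("^\\$\\$\\$\\$", r)]
    if (!any(nzchar(trimws(r)))) next
    m <- parse_v2000(paste(r, collapse = "\n"))
    mols[[m$id]] <- m
  }
  mols
}

# Allowed valences by element; S and P may expand.
.valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L)

# Target valence for an atom given charge and current bond-order sum.
target_valence <- function(element, charge, bondsum) {
  v <- .valences[[element]]
  if (is.null(v))
    return(NA_integer_)
  # protonation/deprotonation shifts the bonding capacity of heteroatoms;
  # carbanions/carbocations lose one bond
  v <- if (element %in% c("N", "O", "P", "S")) v + charge
       else if (element %in% c("C", "B")) v - abs(charge)
       else v
  v <- v[v >= bondsum]
  if (!length(v)) NA_integer_ else min(v)
}

#' Standardize a molecule
#'
#' Makes every hydrogen an explicit atom (implicit counts are filled from a
#' valence model with charge adjustment) and perceives aromatic rings with a
#' simple Hueckel-style model (rings of size 3--7 whose atoms are all
#' sp2-compatible and whose pi-electron count is 4k+2), so that Kekule
#' variants of the same ring map to one graph.  The operation is
#' idempotent.  The aromaticity model name is recorded in `arom_model`
#' because signature strings depend on it.
#'
#' @param m an `rms_molecule`.
#' @return A standardized `rms_molecule`.
#' @examples
#' standardize_molecule(parse_molecule("C", "smiles", id = "methane"))
#' @export
standardize_molecule <- function(m) {
  stopifnot(inherits(m, "rms_molecule"))
  atoms <- m$atoms
  bonds <- m$bonds
  n <- nrow(atoms)
  ordsum <- rep(0, n)
  if (nrow(bonds)) {
    w <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      ordsum[bonds$a1[k]] <- ordsum[bonds$a1[k]] + w[k]
      ordsum[bonds$a2[k]] <- ordsum[bonds$a2[k]] + w[k]
    }
  }
  # implicit hydrogen complements
  addh <- integer(n)
  for (i in seq_len(n)) {
    if (atoms$aromatic[i]) next  # already standardized atom
    v <- target_valence(atoms$element[i], atoms$charge[i], ceiling(ordsum[i]))
    if (is.na(v))
      stop(sprintf("unresolvable valence at atom %d (%s, charge %+d, bonds %.1f)",
                   i, atoms$element[i], atoms$charge[i], ordsum[i]),
           call. = FALSE)
    deficit <- v - ordsum[i]
    if (deficit > 0 && abs(deficit - round(deficit)) < 1e-9)
      addh[i] <- as.integer(round(deficit))
  }
  if (sum(addh) > 0L) {
    hn <- sum(addh)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = rep("H", hn), charge = 0L, aromatic = FALSE))
    newb <- tibble::tibble(
      a1 = rep(seq_len(n), addh),
      a2 = n + seq_len(hn),
      order = 1L)
    bonds <- dplyr::bind_rows(bonds, newb)
  }
  out <- new_molecule(atoms, bonds, id = m$id, standardized = TRUE,
                      arom_model = "huckel-simple")
  perceive_aromaticity(out)
}

# Simple Hueckel-style aromatic perception on rings of size 3-7.
perceive_aromaticity <- function(m) {
  atoms <- m$atoms
  bonds <- m$bonds
  if (!nrow(bonds)) return(m)
  heavy <- which(atoms$element != "H")
  cycles <- find_rings(bonds, heavy, max_size = 7L)
  if (!length(cycles)) return(m)
  bkey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  border <- stats::setNames(bonds$order, bkey)
  dbl_at <- unique(c(bonds$a1[bonds$order == 2L], bonds$a2[bonds$order == 2L]))
  for (ring in cycles) {
    k <- length(ring)
    nxt <- c(ring[-1], ring[1])
    rkeys <- paste(pmin(ring, nxt), pmax(ring, nxt))
    if (any(border[rkeys] == 4L)) {  # already aromatic ring: keep flags
      atoms$aromatic[ring] <- TRUE
      next
    }
    pi_e <- 0L
    ok <- TRUE
    for (i in seq_len(k)) {
      a <- ring[i]
      has_dbl <- a %in% dbl_at
      ring_dbl <- any(border[rkeys] == 2L & (ring == a | nxt == a))
      if (ring_dbl) {
        pi_e <- pi_e + 1L           # one electron per atom of an in-ring double bond
      } else if (has_dbl) {
        ok <- FALSE; break          # exocyclic double bond blocks aromaticity
      } else if (atoms$element[a] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L           # lone-pair donor
      } else {
        ok <- FALSE; break          # sp3 carbon
      }
    }
    if (ok && pi_e %% 4L == 2L) {
      atoms$aromatic[ring] <- TRUE
      idx <- match(rkeys, bkey)
      bonds$order[idx] <- 4L
      border[rkeys] <- 4L
    }
  }
  new_molecule(atoms, bonds, id = m$id, standardized = TRUE,
               arom_model = m$arom_model)
}

# Enumerate simple cycles up to max_size among the given atoms; returns a
# list of atom-index vectors, deduplicated by atom set.
find_rings <- function(bonds, atoms_keep, max_size = 7L) {
  adj <- lapply(seq_len(max(c(bonds$a1, bonds$a2, 0))), function(i) integer())
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    if (a %in% atoms_keep && b %in% atoms_keep) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- character()
  out <- list()
  path <- integer()
  dfs <- function(start, u, prev) {
    path[[length(path) + 1L]] <<- u
    for (v in adj[[u]]) {
      if (v == prev) next
      if (v == start && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) {
          seen[[length(seen) + 1L]] <<- key
          out[[length(out) + 1L]] <<- path
        }
      } else if (!(v %in% path) && length(path) < max_size && v > start) {
        dfs(start, v, u)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in sort(atoms_keep)) dfs(s, s, 0L)
  # prefer small rings first so fused systems are handled ring by ring
  out[order(lengths(out))]
}

#' Write a molecule as an MDL Molfile (V2000)
#'
#' Aromatic bonds are written with bond type 4; formal charges are written
#' as `M  CHG` properties.
#'
#' @param m an `rms_molecule`.
#' @param path optional file path; when `NULL` the Molfile text is returned.
#' @return The Molfile text, invisibly when `path` is given.
#' @export
write_molfile <- function(m, path = NULL) {
  stopifnot(inherits(m, "rms_molecule"))
  na <- nrow(m$atoms); nb <- nrow(m$bonds)
  hdr <- c(m$id, "  rmsnet", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, m$atoms$element)
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        m$bonds$a1, m$bonds$a2, m$bonds$order) else character()
  chg <- which(m$atoms$charge != 0L)
  cl <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, m$atoms$charge[chg]), collapse = ""))
  } else character()
  txt <- paste(c(hdr, al, bl, cl, "M  END", ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Molecular formula of a molecule
#'
#' @param m an `rms_molecule` (standardized molecules count explicit H).
#' @return Named integer vector of element counts with an attribute
#'   `charge` carrying the net formal charge.
#' @export
mol_formula <- function(m) {
  cnt <- table(m$atoms$element)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  attr(out, "charge") <- sum(m$atoms$charge)
  out
}

#' Relabel the atoms of a molecule by a permutation
#'
#' Utility for invariance checks: signatures must not depend on atom input
#' order.
#'
#' @param m an `rms_molecule`.
#' @param perm integer permutation of `seq_len(nrow(m$atoms))`; `perm[i]`
#'   is the new index of old atom `i`.
#' @return The relabeled `rms_molecule`.
#' @export
permute_atoms <- function(m, perm) {
  stopifnot(length(perm) == nrow(m$atoms), !anyDuplicated(perm))
  inv <- order(perm)
  atoms <- m$atoms[inv, ]
  bonds <- m$bonds
  if (nrow(bonds)) {
    bonds$a1 <- perm[bonds$a1]
    bonds$a2 <- perm[bonds$a2]
  }
  new_molecule(atoms, bonds, id = m$id, standardized = m$standardized,
               arom_model = m$arom_model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
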