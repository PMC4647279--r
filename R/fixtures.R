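# Synthetic study-condition generator.  Emulates a curated pathway
# database at desk scale: families of valence-correct small molecules
# share a reaction center but vary in the periphery, a fixed three-step
# operator chain (alcohol -> aldehyde -> imine -> amine) is applied to
# every family (the planted conserved module), and optional background
# chains, each used by a single family, add non-conserved edges.  All
# reactions are balanced by construction and every compound has a
# generated SMILES structure, so the whole pipeline runs without any
# download.

# Operator definitions: head-group graph edits with balancing side
# compounds.  from/to are family compound states; sides are global.
.fixture_ops <- list(
  O1  = list(ec = "1.1.1.1",    from = "alc", to = "ald",
             sub_side = c(),                  prod_side = c(side_h2 = 1L)),
  O2  = list(ec = "4.3.1.9",    from = "ald", to = "imi",
             sub_side = c(side_nh3 = 1L),     prod_side = c(side_h2o = 1L)),
  O3  = list(ec = "1.5.1.1",    from = "imi", to = "amn",
             sub_side = c(side_h2 = 1L),      prod_side = c()),
  # background danglers, consuming a planted intermediate
  O4  = list(ec = "1.1.1.71",   from = "ald", to = "acd",
             sub_side = c(side_h2o2 = 1L),    prod_side = c(side_h2o = 1L)),
  O6  = list(ec = "2.1.2.3",    from = "amn", to = "fam",
             sub_side = c(side_formate = 1L), prod_side = c(side_h2o = 1L)),
  O8  = list(ec = "1.14.13.68", from = "imi", to = "ntr",
             sub_side = c(side_h2o2 = 1L),    prod_side = c(side_h2o = 2L)),
  # background feeders, producing a planted intermediate
  O13 = list(ec = "3.1.1.1",    from = "est", to = "alc",
             sub_side = c(side_h2o = 1L),     prod_side = c(side_formate = 1L)),
  O15 = list(ec = "1.4.3.4",    from = "amn", to = "imi",
             sub_side = c(side_h2o2 = 1L),    prod_side = c(side_h2o = 2L)),
  O16 = list(ec = "4.2.1.103",  from = "gdi", to = "ald",
             sub_side = c(),                  prod_side = c(side_h2o = 1L)))

# Head-group SMILES per state, appended to the family tail (which ends
# at the attachment carbon).
.state_smiles <- c(
  alc = "CO", ald = "C=O", imi = "C=N", amn = "CN", acd = "C(O)=O",
  fam = "CNC=O", ntr = "C#N", est = "COC=O", gdi = "C(O)O")

.side_smiles <- c(
  side_h2 = "[H][H]", side_h2o = "O", side_nh3 = "N", side_h2o2 = "OO",
  side_co2 = "O=C=O", side_formate = "OC=O")

# Background chains: one feeder into a planted step plus one dangler off
# a planted intermediate.  Each chain is assigned to at most one family,
# so its windows are never conserved (PCI stays 1); feeders give the
# planted transformation classes the extra incoming links expected of
# chemical hubs.
.bg_chains <- list(list(feeder = "O13", dangler = "O4"),
                   list(feeder = "O15", dangler = "O6"),
                   list(feeder = "O16", dangler = "O8"))

#' Fixture configuration
#'
#' Defaults define the study conditions used throughout the package's
#' tests and the reproduction script: 6 compound families carrying a
#' 3-step planted module, half the families with a decorated tail
#' (height-2 heterogeneity), half with one unique background chain, and
#' two mid-chain operators left orphan (no protein rows).
#'
#' @param seed integer seed; the seed fully determines the bundle.
#' @param n_families number of compound families (>= 2).
#' @param bg_fraction fraction of families carrying a background chain
#'   (at most 3 such families; each uses a distinct chain).
#' @param decorated_fraction fraction of families whose tail carries a
#'   2-hydroxyisopropyl decoration on the attachment carbon, visible at
#'   height 2 but not at height 1.
#' @param orphan_frac fraction of instantiated operators left without
#'   protein associations (orphan enzyme activities), mid-chain
#'   operators first.
#' @param n_promiscuous number of extra proteins with a shared
#'   two-domain composition linked to both first-step operators.
#' @param include_transport,include_null include a transport reaction
#'   (linked into a pathway, later excluded from the network) and a
#'   chemically null reaction.
#' @param min_tail minimum tail length in carbons.  Must be >= 2 so the
#'   attachment carbon keeps a carbon neighbour; the default 3 also makes
#'   the height-2 ball of the reaction center identical across tail
#'   lengths, so within-group h2 strings are exactly equal.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_families = 6L, bg_fraction = 0.5,
                           decorated_fraction = 0.5, orphan_frac = 0.25,
                           n_promiscuous = 3L, include_transport = TRUE,
                           include_null = TRUE, min_tail = 3L) {
  if (n_families < 2L)
    stop("need at least 2 families to plant a conserved module", call. = FALSE)
  if (min_tail < 2L)
    stop(paste("operator O1 is inapplicable to a methyl scaffold:",
               "tails must keep a carbon neighbour on the attachment",
               "carbon (min_tail >= 2)"), call. = FALSE)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 bg_fraction = bg_fraction,
                 decorated_fraction = decorated_fraction,
                 orphan_frac = orphan_frac,
                 n_promiscuous = as.integer(n_promiscuous),
                 include_transport = include_transport,
                 include_null = include_null, min_tail = as.integer(min_tail)),
            class = "fixture_config")
}

family_tail <- function(f, decorated, min_tail) {
  base <- strrep("C", min_tail + (f - 1L))
  if (decorated) paste0(base, "(C(C)(C)O)") else base
}

#' Generate a synthetic fixture bundle
#'
#' Emits molecules (SMILES), a reaction table, a pathway link table and
#' a protein table, together with a ground-truth record (planted module
#' windows with their expected PCI, expected class count per operator,
#' orphan classes, expected pathway-type summary).  The same seed gives
#' a byte-identical bundle.
#'
#' @param cfg a [fixture_config()].
#' @param dir optional output directory; when given, writes
#'   `molecules.smi`, `reactions.tsv`, `pathways.tsv`, `proteins.tsv`,
#'   `truth.json` and `manifest.json`.
#' @return List with tibbles `molecules`, `reactions`, `pathways`,
#'   `proteins`, the named molecule list `structures`, and `truth`.
#' @export
generate_fixture <- function(cfg = fixture_config(), dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  nf <- cfg$n_families
  n_dec <- round(cfg$decorated_fraction * nf)
  decorated <- rep(FALSE, nf)
  if (n_dec > 0L) decorated[sample(nf, n_dec)] <- TRUE
  n_bg <- min(round(cfg$bg_fraction * nf), length(.bg_chains))
  bg_family <- if (n_bg > 0L) sort(sample(nf, n_bg)) else integer()

  planted <- c("O1", "O2", "O3")
  types_cycle <- c("Biosynthesis", "Degradation", "Energy")

  mol_rows <- list()
  seen_cpd <- character()
  add_cpd <- function(id, smiles) {
    if (!id %in% seen_cpd) {
      seen_cpd <<- c(seen_cpd, id)
      mol_rows[[length(mol_rows) + 1L]] <<- tibble::tibble(
        compound_id = id, smiles = smiles)
    }
    id
  }
  for (s in names(.side_smiles)) add_cpd(s, .side_smiles[[s]])

  rx_rows <- list()
  pw_rows <- list()
  op_used <- character()
  op_rxns <- list()
  state_cpd <- function(f, state) {
    tail <- family_tail(f, decorated[f], cfg$min_tail)
    sm <- paste0(tail, .state_smiles[[state]])
    add_cpd(sprintf("F%d_%s", f, state), sm)
  }
  add_rx <- function(id, op, f, ec) {
    o <- .fixture_ops[[op]]
    subs <- tibble::tibble(
      compound = c(state_cpd(f, o$from), names(o$sub_side)),
      coeff = c(1L, unname(o$sub_side)))
    prods <- tibble::tibble(
      compound = c(state_cpd(f, o$to), names(o$prod_side)),
      coeff = c(1L, unname(o$prod_side)))
    rx_rows[[length(rx_rows) + 1L]] <<- tibble::tibble(
      reaction_id = id, substrates = list(subs), products = list(prods),
      ec = ec, is_transport = FALSE)
    op_used <<- union(op_used, op)
    op_rxns[[op]] <<- c(op_rxns[[op]], id)
    id
  }
  add_link <- function(pw, type, from, to, main) {
    pw_rows[[length(pw_rows) + 1L]] <<- tibble::tibble(
      pathway_id = pw, type = type, from_rxn = unname(from),
      to_rxn = unname(to), main_compound = unname(main))
  }

  for (f in seq_len(nf)) {
    type <- types_cycle[(f - 1L) %% length(types_cycle) + 1L]
    rids <- character(length(planted))
    for (k in seq_along(planted)) {
      op <- planted[k]
      ec <- .fixture_ops[[op]]$ec
      if (op == "O2" && f %% 2L == 0L) ec <- "3.5.99.7"   # same RMS, other EC branch
      if (op == "O1" && f == 1L) ec <- paste0(ec, ";1.1.1.284")
      rids[k] <- add_rx(sprintf("R_F%d_%s", f, op), op, f, ec)
    }
    pwid <- sprintf("PW_F%d_main", f)
    add_link(pwid, type, rids[1], rids[2],
             sprintf("F%d_%s", f, .fixture_ops[[planted[1]]]$to))
    add_link(pwid, type, rids[2], rids[3],
             sprintf("F%d_%s", f, .fixture_ops[[planted[2]]]$to))
  }
  for (j in seq_along(bg_family)) {
    f <- bg_family[j]
    chain <- .bg_chains[[j]]
    r_feed <- add_rx(sprintf("R_F%d_%s", f, chain$feeder), chain$feeder, f,
                     .fixture_ops[[chain$feeder]]$ec)
    r_dang <- add_rx(sprintf("R_F%d_%s", f, chain$dangler), chain$dangler, f,
                     .fixture_ops[[chain$dangler]]$ec)
    pwid <- sprintf("PW_F%d_bg", f)
    # feeder -> the planted reaction consuming the feeder's product
    feed_state <- .fixture_ops[[chain$feeder]]$to
    feed_into <- planted[vapply(planted, function(p)
      .fixture_ops[[p]]$from == feed_state, logical(1))]
    add_link(pwid, "Other", r_feed, sprintf("R_F%d_%s", f, feed_into),
             sprintf("F%d_%s", f, feed_state))
    # planted producer of the dangler's substrate -> dangler
    dang_state <- .fixture_ops[[chain$dangler]]$from
    dang_from <- planted[vapply(planted, function(p)
      .fixture_ops[[p]]$to == dang_state, logical(1))]
    add_link(pwid, "Other", sprintf("R_F%d_%s", f, dang_from), r_dang,
             sprintf("F%d_%s", f, dang_state))
  }
  if (cfg$include_transport) {
    c1 <- state_cpd(1L, "alc")
    rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
      reaction_id = "T_F1_import",
      substrates = list(tibble::tibble(compound = c1, coeff = 1L)),
      products = list(tibble::tibble(compound = c1, coeff = 1L)),
      ec = NA_character_, is_transport = TRUE)
    add_link("PW_F1_main", types_cycle[1], "T_F1_import", "R_F1_O1", c1)
  }
  if (cfg$include_null) {
    c1 <- state_cpd(1L, "ald")
    rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
      reaction_id = "X_null",
      substrates = list(tibble::tibble(compound = c1, coeff = 1L)),
      products = list(tibble::tibble(compound = c1, coeff = 1L)),
      ec = NA_character_, is_transport = FALSE)
  }

  # orphan operators: feeders first (they appear as path factor nodes,
  # so orphanhood propagates into undefined scoreProt), then danglers
  orphan_pref <- c("O13", "O16", "O15", "O4", "O8", "O6")
  n_orphan <- max(1L, round(cfg$orphan_frac * length(op_used)))
  orphan_ops <- utils::head(intersect(orphan_pref, op_used), n_orphan)

  prot_rows <- list()
  opv <- sort(setdiff(op_used, orphan_ops), method = "radix")
  for (k in seq_along(opv)) {
    op <- opv[k]
    n_prot <- 4L + (k %% 4L)
    rxs <- op_rxns[[op]]
    for (p in seq_len(n_prot)) {
      assoc <- sort(sample(rxs, min(2L, length(rxs))))
      prot_rows[[length(prot_rows) + 1L]] <- tibble::tibble(
        protein_id = sprintf("P_%s_%02d", op, p),
        domains = sprintf("Dom_%s", op),
        reaction_ids = paste(assoc, collapse = ";"))
    }
  }
  if (cfg$n_promiscuous > 0L && all(c("O1", "O2") %in% opv)) {
    for (p in seq_len(cfg$n_promiscuous)) {
      assoc <- c(sample(op_rxns[["O1"]], 1L), sample(op_rxns[["O2"]], 1L))
      prot_rows[[length(prot_rows) + 1L]] <- tibble::tibble(
        protein_id = sprintf("P_pro_%02d", p),
        domains = "Dom_O1;Dom_O2",
        reaction_ids = paste(sort(assoc), collapse = ";"))
    }
  }

  molecules <- dplyr::bind_rows(mol_rows)
  reactions <- dplyr::bind_rows(rx_rows)
  pathways <- dplyr::bind_rows(pw_rows)
  proteins <- if (length(prot_rows)) dplyr::bind_rows(prot_rows)
    else tibble::tibble(protein_id = character(), domains = character(),
                        reaction_ids = character())

  pw_main <- unique(pathways$pathway_id[grepl("_main$", pathways$pathway_id)])
  type_of <- dplyr::distinct(pathways[c("pathway_id", "type")])
  truth <- list(
    planted_ops = planted,
    module_windows = list(
      list(ops = planted[1:2], length = 1L, expected_pci = nf),
      list(ops = planted[2:3], length = 1L, expected_pci = nf),
      list(ops = planted, length = 2L, expected_pci = nf)),
    expected_n_h1_classes = length(op_used),
    op_of_reaction = stats::setNames(
      rep(names(op_rxns), lengths(op_rxns)), unlist(op_rxns)),
    orphan_ops = orphan_ops,
    decorated_families = which(decorated),
    bg_families = bg_family,
    n_main_pathways = length(pw_main),
    pathway_types = stats::setNames(type_of$type, type_of$pathway_id))

  out <- list(molecules = molecules, reactions = reactions,
              pathways = pathways, proteins = proteins,
              structures = NULL, truth = truth, config = cfg)
  out$structures <- stats::setNames(
    lapply(seq_len(nrow(molecules)), function(i)
      parse_molecule(molecules$smiles[i], "smiles",
                     id = molecules$compound_id[i])),
    molecules$compound_id)
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

#' Write a fixture bundle to disk
#'
#' Plain-text formats only: SMILES, TSV, JSON (plus a manifest naming
#' the files and the generating configuration).
#'
#' @param fx output of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sprintf("%s\t%s", fx$molecules$smiles, fx$molecules$compound_id),
             file.path(dir, "molecules.smi"))
  rx <- data.frame(
    reaction_id = fx$reactions$reaction_id,
    substrates = vapply(fx$reactions$substrates, format_side, character(1)),
    products = vapply(fx$reactions$products, format_side, character(1)),
    ec = ifelse(is.na(fx$reactions$ec), "", fx$reactions$ec),
    is_transport = fx$reactions$is_transport)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fx$pathways), file.path(dir, "pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fx$proteins), file.path(dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fx$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    files = c("molecules.smi", "reactions.tsv", "pathways.tsv",
              "proteins.tsv", "truth.json"),
    config = unclass(fx$config),
    format = list(
      molecules = "SMILES<TAB>compound_id",
      reactions = "reaction_id, substrates, products (compound:coeff;...), ec, is_transport",
      pathways = "pathway_id, type, from_rxn, to_rxn, main_compound",
      proteins = "protein_id, domains (;-sep), reaction_ids (;-sep)"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle back from disk
#'
#' @param dir directory written by [write_fixture()].
#' @return List with `molecules`, `reactions`, `pathways`, `proteins`,
#'   `structures`.
#' @export
read_fixture <- function(dir) {
  lines <- readLines(file.path(dir, "molecules.smi"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  molecules <- tibble::tibble(
    compound_id = vapply(parts, `[`, character(1), 2),
    smiles = vapply(parts, `[`, character(1), 1))
  structures <- stats::setNames(
    lapply(seq_len(nrow(molecules)), function(i)
      parse_molecule(molecules$smiles[i], "smiles",
                     id = molecules$compound_id[i])),
    molecules$compound_id)
  list(molecules = molecules,
       reactions = read_reactions(file.path(dir, "reactions.tsv")),
       pathways = read_pathways(file.path(dir, "pathways.tsv")),
       proteins = read_proteins(file.path(dir, "proteins.tsv")),
       structures = structures)
}
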