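# Shared in-code fixtures.  The generated bundle is cached per test run
# because signature computation dominates the suite's cost.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 42L, ...) {
  key <- paste0("fx_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fixture(fixture_config(seed = seed, ...))
  .fixture_cache[[key]]
}

cached_run <- function(seed = 42L) {
  key <- paste0("run_", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed)
    .fixture_cache[[key]] <- run_rms_pipeline(fx$reactions, fx$pathways,
                                              fx$structures, fx$proteins)
  }
  .fixture_cache[[key]]
}

std_smiles <- function(smiles, id = "mol") {
  standardize_molecule(parse_molecule(smiles, "smiles", id = id))
}

# Ethanol dehydrogenation toy reaction set.
toy_molecules <- function() {
  list(h2 = parse_molecule("[H][H]", "smiles", id = "h2"),
       water = parse_molecule("O", "smiles", id = "water"),
       o2 = parse_molecule("O=O", "smiles", id = "o2"),
       ethanol = parse_molecule("CCO", "smiles", id = "ethanol"),
       acetaldehyde = parse_molecule("CC=O", "smiles", id = "acetaldehyde"))
}

one_reaction <- function(id, subs, prods, ec = NA_character_,
                         transport = FALSE) {
  tibble::tibble(
    reaction_id = id,
    substrates = list(tibble::tibble(compound = names(subs),
                                     coeff = as.integer(subs))),
    products = list(tibble::tibble(compound = names(prods),
                                   coeff = as.integer(prods))),
    ec = ec, is_transport = transport)
}

reverse_reaction <- function(rx) {
  tmp <- rx$substrates
  rx$substrates <- rx$products
  rx$products <- tmp
  rx
}

# Compounds of the lactam-formation worked example, built from the named
# standard structures (constitution only, no stereochemistry).
lactam_molecules <- function() {
  list(
    d_glutamate = parse_molecule("NC(CCC(O)=O)C(O)=O", "smiles",
                                 id = "d_glutamate"),
    oxoproline = parse_molecule("O=C1CCC(C(O)=O)N1", "smiles",
                                id = "oxoproline"),
    water = parse_molecule("O", "smiles", id = "water"),
    l_lysine = parse_molecule("NCCCCC(N)C(O)=O", "smiles", id = "l_lysine"),
    lysine_lactam = parse_molecule("O=C1NCCCCC1N", "smiles",
                                   id = "lysine_lactam"))
}

lactam_reactions <- function() {
  dplyr::bind_rows(
    one_reaction("glutamate_cyclase", c(d_glutamate = 1),
                 c(oxoproline = 1, water = 1), ec = "4.2.1.48"),
    one_reaction("lysine_lactamase", c(lysine_lactam = 1, water = 1),
                 c(l_lysine = 1), ec = "3.5.2.11"))
}

# Hand-built RMS network with chosen nodes and edge counts, for tests
# that need full control over the topology and probabilities.
manual_rms_network <- function(nodes, edges, height = 1L,
                               n_reaction_edges = sum(edges$n_edges)) {
  structure(list(
    nodes = tibble::tibble(class_id = nodes,
                           n_members = 1L,
                           members = as.list(nodes),
                           n_out_total = vapply(nodes, function(u)
                             sum(edges$n_edges[edges$from == u]), integer(1)),
                           n_within = 0L),
    edges = edges, height = height, n_reaction_edges = n_reaction_edges),
    class = "rms_network")
}
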