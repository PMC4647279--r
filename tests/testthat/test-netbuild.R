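# Hand-built reaction/pathway fixtures: compounds a, b, c, d chained by
# reactions; structures are unneeded for network construction itself.

linear_pathway_fixture <- function() {
  rxns <- dplyr::bind_rows(
    one_reaction("r1", c(a = 1), c(b = 1)),
    one_reaction("r2", c(b = 1), c(c = 1)),
    one_reaction("r3", c(c = 1), c(d = 1)),
    one_reaction("t1", c(b = 1), c(b = 1), transport = TRUE))
  links <- tibble::tibble(
    pathway_id = c("P1", "P1"), type = "Biosynthesis",
    from_rxn = c("r1", "r2"), to_rxn = c("r2", "r3"),
    main_compound = c("b", "c"))
  list(reactions = rxns, pathways = links)
}

test_that("the reaction network links reactions through main compounds", {
  fx <- linear_pathway_fixture()
  net <- build_reaction_network(fx$reactions, fx$pathways)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$from, c("r1", "r2"))

  # duplicated support in a second pathway collapses into one edge
  links2 <- dplyr::bind_rows(fx$pathways, tibble::tibble(
    pathway_id = "P2", type = "Degradation",
    from_rxn = "r1", to_rxn = "r2", main_compound = "b"))
  net2 <- build_reaction_network(fx$reactions, links2)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$edges$n_supports[net2$edges$from == "r1"], 2L)
  expect_equal(nrow(net2$edges$supports[[1]]), 2L)

  # transport reactions are omitted along with their incident links
  links3 <- dplyr::bind_rows(fx$pathways, tibble::tibble(
    pathway_id = "P1", type = "Biosynthesis",
    from_rxn = "t1", to_rxn = "r2", main_compound = "b"))
  net3 <- build_reaction_network(fx$reactions, links3)
  expect_false("t1" %in% net3$nodes$reaction_id)
  expect_equal(nrow(net3$edges), 2L)

  # unknown reactions are an error; bad main compounds a warning + skip
  expect_error(build_reaction_network(
    fx$reactions, dplyr::mutate(fx$pathways, to_rxn = c("r2", "zz"))),
    "unknown")
  expect_warning(
    net4 <- build_reaction_network(
      fx$reactions, dplyr::mutate(fx$pathways,
                                  main_compound = c("b", "a"))),
    "main compound")
  expect_equal(nrow(net4$edges), 1L)
})

# Classification stub: assign reactions to classes by a named vector.
stub_classification <- function(map) {
  structure(list(
    assignments = tibble::tibble(
      reaction_id = names(map), h1_class = unname(map),
      h2_class = NA_character_, orientation = "forward",
      excluded_reason = NA_character_),
    classes = tibble::tibble(),
    h2_strings = character(), params = list(heights = 1L)),
    class = "rms_classification")
}

test_that("reduction reproduces the worked transition-probability example", {
  # class A members have five outgoing reaction edges, two of them into
  # class B members: Pr(B|A) must be 2/5 = 0.4
  rxns <- dplyr::bind_rows(lapply(paste0("r", 1:8), function(id)
    one_reaction(id, c(x = 1), c(y = 1))))
  links <- tibble::tibble(
    pathway_id = "P", type = "Other",
    from_rxn = c("r1", "r1", "r2", "r2", "r2"),
    to_rxn = c("r3", "r4", "r5", "r6", "r7"),
    main_compound = "y")
  # y must be substrate of downstream reactions for the link check
  rxns$substrates[3:8] <- list(tibble::tibble(compound = "y", coeff = 1L))
  rxns$products[3:8] <- list(tibble::tibble(compound = "z", coeff = 1L))
  net <- build_reaction_network(rxns, links)
  cmap <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B", r5 = "C", r6 = "C",
            r7 = "D")
  rms <- reduce_to_rms_network(net, stub_classification(cmap), 1L)
  e <- rms$edges
  expect_equal(e$prob[e$from == "A" & e$to == "B"], 0.4)
  expect_equal(e$prob[e$from == "A" & e$to == "C"], 0.4)
  expect_equal(e$prob[e$from == "A" & e$to == "D"], 0.2)
  expect_equal(rms$nodes$n_out_total[rms$nodes$class_id == "A"], 5L)
})

test_that("within-class edges feed the denominator but create no self-loop", {
  rxns <- dplyr::bind_rows(
    one_reaction("r1", c(x = 1), c(y = 1)),
    one_reaction("r2", c(y = 1), c(z = 1)),
    one_reaction("r3", c(z = 1), c(w = 1)))
  links <- tibble::tibble(
    pathway_id = "P", type = "Other",
    from_rxn = c("r1", "r2"), to_rxn = c("r2", "r3"),
    main_compound = c("y", "z"))
  net <- build_reaction_network(rxns, links)
  cmap <- c(r1 = "A", r2 = "A", r3 = "B")   # r1 -> r2 is within-class
  rms <- reduce_to_rms_network(net, stub_classification(cmap), 1L)
  expect_false(any(rms$edges$from == rms$edges$to))
  expect_equal(nrow(rms$edges), 1L)
  expect_equal(rms$edges$prob, 0.5)  # 1 crossing / 2 outgoing from A members
  expect_equal(rms$nodes$n_within[rms$nodes$class_id == "A"], 1L)
})

test_that("edge conservation and probability deficits hold on fixtures", {
  run <- cached_run()
  net <- run$reaction_network
  for (h in c("h1", "h2")) {
    rms <- run$heights[[h]]$rms_network
    # crossing + within-class edges account for every reaction edge
    expect_equal(sum(rms$edges$n_edges) + sum(rms$nodes$n_within),
                 rms$n_reaction_edges)
    expect_equal(rms$n_reaction_edges, nrow(net$edges))
    # per-node probability sums are exactly 1 - within fraction
    for (i in seq_len(nrow(rms$nodes))) {
      nd <- rms$nodes[i, ]
      psum <- sum(rms$edges$prob[rms$edges$from == nd$class_id])
      if (nd$n_out_total > 0)
        expect_equal(psum, 1 - nd$n_within / nd$n_out_total)
    }
  }
})

test_that("singleton classes give the identity reduction", {
  fx <- linear_pathway_fixture()
  net <- build_reaction_network(fx$reactions, fx$pathways)
  cmap <- c(r1 = "C1", r2 = "C2", r3 = "C3")
  rms <- reduce_to_rms_network(net, stub_classification(cmap), 1L)
  expect_equal(nrow(rms$nodes), nrow(net$nodes))
  expect_equal(nrow(rms$edges), nrow(net$edges))
  expect_true(all(rms$edges$prob == 1))
  expect_equal(node_reduction_rate(net, rms), 1.0)

  # 10 reactions in 4 classes -> 0.4 (counting, not topology)
  fake_net <- structure(list(
    nodes = tibble::tibble(reaction_id = paste0("r", 1:10)),
    edges = tibble::tibble()), class = "reaction_network")
  fake_rms <- structure(list(nodes = tibble::tibble(class_id = paste0("c", 1:4))),
                        class = "rms_network")
  expect_equal(node_reduction_rate(fake_net, fake_rms), 0.4)
  empty <- structure(list(nodes = tibble::tibble(reaction_id = character()),
                          edges = tibble::tibble()),
                     class = "reaction_network")
  expect_error(node_reduction_rate(empty, fake_rms), "undefined")
})

test_that("refining the classification never decreases node count", {
  run <- cached_run()
  expect_gte(nrow(run$heights$h2$rms_network$nodes),
             nrow(run$heights$h1$rms_network$nodes))
})
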