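test_that("path enumeration matches hand counts and the brute-force oracle", {
  g <- manual_rms_network(
    c("A", "B", "C"),
    tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C"),
                   n_edges = 1L, prob = c(0.5, 1, 0.5)))
  p <- enumerate_rms_paths(g, 1L, 4L)
  expect_equal(p$path_id[p$length == 1L], c("A->B", "A->C", "B->C"))
  expect_equal(p$path_id[p$length == 2L], "A->B->C")

  # directed 3-cycle: no path revisits a node
  cyc <- manual_rms_network(
    c("A", "B", "C"),
    tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "A"),
                   n_edges = 1L, prob = 1))
  pc <- enumerate_rms_paths(cyc, 1L, 3L)
  expect_equal(sum(pc$length == 1L), 3L)
  expect_equal(sum(pc$length == 2L), 3L)
  expect_equal(sum(pc$length == 3L), 0L)   # closing the cycle would repeat
  expect_false(any(vapply(pc$nodes, anyDuplicated, integer(1)) > 0))

  # random digraphs vs brute-force oracle (exact set equality)
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    ee <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    ee <- ee[ee$from != ee$to & stats::runif(nrow(ee)) < 0.2, ]
    net <- manual_rms_network(nodes, tibble::tibble(
      from = ee$from, to = ee$to, n_edges = 1L, prob = 1))
    lens <- sort(sample(1:4, 2))
    got <- enumerate_rms_paths(net, lens[1], lens[2])
    expect_identical(sort(got$path_id),
                     oracle_simple_paths(nodes, net$edges, lens[1], lens[2]))
    # deterministic lexicographic emission order
    expect_identical(got$path_id, sort(got$path_id))
  }
  # empty graph
  empty <- manual_rms_network(character(), tibble::tibble(
    from = character(), to = character(), n_edges = integer(),
    prob = double()))
  expect_equal(nrow(enumerate_rms_paths(empty)), 0L)
})

test_that("pathways translate into overlapping windows of class sequences", {
  links <- tibble::tibble(
    pathway_id = "P", type = "Energy",
    from_rxn = c("r1", "r2"), to_rxn = c("r2", "r3"),
    main_compound = "m")
  cmap <- c(r1 = "A", r2 = "B", r3 = "C")
  cls <- structure(list(
    assignments = tibble::tibble(
      reaction_id = names(cmap), h1_class = unname(cmap),
      h2_class = NA_character_, orientation = "forward",
      excluded_reason = NA_character_),
    classes = tibble::tibble(), h2_strings = character(),
    params = list(heights = 1L)), class = "rms_classification")
  w1 <- pathway_to_rms_paths(links, cls, length = 1L)
  expect_setequal(w1$class_seq, c("A->B", "B->C"))
  w2 <- pathway_to_rms_paths(links, cls, length = 2L)
  expect_equal(w2$class_seq, "A->B->C")
  expect_equal(nrow(pathway_to_rms_paths(links, cls, length = 3L)), 0L)
  # consecutive reactions falling in one class are dropped (self-loop rule)
  cmap2 <- c(r1 = "A", r2 = "A", r3 = "C")
  cls2 <- cls
  cls2$assignments$h1_class <- unname(cmap2[cls2$assignments$reaction_id])
  expect_equal(pathway_to_rms_paths(links, cls2, length = 1L)$class_seq,
               "A->C")
})

test_that("PCI counts distinct supporting reaction paths once", {
  links <- tibble::tibble(
    pathway_id = c("P1", "P2", "P3"), type = "Other",
    from_rxn = c("r1", "r3", "r3"), to_rxn = c("r2", "r4", "r4"),
    main_compound = "m")
  cmap <- c(r1 = "A", r2 = "B", r3 = "A", r4 = "B")
  cls <- structure(list(
    assignments = tibble::tibble(
      reaction_id = names(cmap), h1_class = unname(cmap),
      h2_class = NA_character_, orientation = "forward",
      excluded_reason = NA_character_),
    classes = tibble::tibble(), h2_strings = character(),
    params = list(heights = 1L)), class = "rms_classification")
  # (r1,r2) in P1 and (r3,r4) in P2 and P3: two distinct reaction paths
  expect_equal(compute_pci(c("A", "B"), links, cls), 2L)
  expect_equal(compute_pci(c("B", "A"), links, cls), 0L)
})

test_that("path scores follow the geometric-mean formula", {
  net <- manual_rms_network(
    c("A", "B", "C"),
    tibble::tibble(from = c("A", "B"), to = c("B", "C"), n_edges = 1L,
                   prob = c(0.5, 0.5)))
  w <- tibble::tibble(class_id = c("A", "B", "C"),
                      w_rea = c(4, 9, 1000),
                      w_pagerank = c(0.2, 0.3, 0.5),
                      w_prot = c(10, NA, 5))
  # one factor: 4 * 0.5 = 2
  expect_equal(score_path(c("A", "B"), w, net, "rea"), 2.0)
  # two factors: sqrt(4*0.5 * 9*0.5) = 3; terminal node weight unused
  expect_equal(score_path(c("A", "B", "C"), w, net, "rea"), 3.0)
  # undefined wProt on a factor node -> NA; on the terminal node it is
  # not a factor, so the score stays defined
  expect_true(is.na(score_path(c("A", "B", "C"), w, net, "prot")))
  expect_equal(score_path(c("A", "B"), w, net, "prot"), 5.0)
  expect_error(score_path(c("A", "C"), w, net, "rea"), "absent")
})

test_that("conserved modules recover the planted truth", {
  # without background chains the module set is exactly the planted one
  fx0 <- cached_fixture(seed = 7L, bg_fraction = 0)
  run0 <- run_rms_pipeline(fx0$reactions, fx0$pathways, fx0$structures,
                           fx0$proteins)
  mods <- run0$heights$h1$modules
  lk <- class_lookup(run0$classification, 1L)
  op_class <- unname(lk[names(fx0$truth$op_of_reaction)[
    match(fx0$truth$planted_ops, fx0$truth$op_of_reaction)]])
  expected <- c(paste(op_class[1:2], collapse = "->"),
                paste(op_class[2:3], collapse = "->"),
                paste(op_class, collapse = "->"))
  expect_setequal(mods$path_id, expected)
  expect_true(all(mods$pci == fx0$config$n_families))
  # supports map node-wise onto the path and lie within one pathway each
  for (i in seq_len(nrow(mods))) {
    sup <- mods$supports[[i]]
    expect_equal(nrow(sup), mods$pci[i])
    for (rs in strsplit(sup$rxn_seq, "|", fixed = TRUE)) {
      expect_equal(unname(lk[rs]), mods$nodes[[i]])
    }
  }
  # PCI >= 1 windows are a subset of enumerated paths
  paths0 <- run0$heights$h1$paths
  expect_true(all(paths0$pci[paths0$known_window] >= 1))

  # lowering min_pci only adds paths
  m1 <- find_conserved_modules(run0$heights$h1$rms_network, fx0$pathways,
                               run0$classification,
                               run0$heights$h1$weights, min_pci = 1L)
  expect_true(all(mods$path_id %in% m1$path_id))
})

test_that("planted pathway windows score above the all-paths average", {
  run <- cached_run()   # default fixture has background chains
  fx <- cached_fixture()
  for (h in c(1L, 2L)) {
    paths <- run$heights[[paste0("h", h)]]$paths
    planted <- paths$path_id %in% planted_window_ids(run, fx, h)
    expect_gt(sum(planted), 0L)
    expect_gt(mean(paths$score_rea[planted]), mean(paths$score_rea))
    expect_gt(mean(paths$score_pagerank[planted]),
              mean(paths$score_pagerank))
  }
  # scoreProt is NA exactly when an orphan class is a factor node
  lk <- class_lookup(run$classification, 1L)
  orphan_classes <- unique(unname(
    lk[names(fx$truth$op_of_reaction)[fx$truth$op_of_reaction %in%
                                        fx$truth$orphan_ops]]))
  p1 <- run$heights$h1$paths
  factor_orphan <- vapply(p1$nodes, function(nd)
    any(utils::head(nd, -1) %in% orphan_classes), logical(1))
  expect_identical(is.na(p1$score_prot), factor_orphan)
})

test_that("the pathway-type summary counts pathways with a conserved window", {
  links <- tibble::tibble(
    pathway_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
    type = "Biosynthesis",
    from_rxn = paste0("r", c(1, 2, 4, 5, 7, 8, 10, 11)),
    to_rxn = paste0("r", c(2, 3, 5, 6, 8, 9, 11, 12)),
    main_compound = "m")
  # P1 and P2 realize A->B->C; P3 and P4 use private classes
  cmap <- c(r1 = "A", r2 = "B", r3 = "C", r4 = "A", r5 = "B", r6 = "C",
            r7 = "D", r8 = "E", r9 = "F", r10 = "G", r11 = "H", r12 = "I")
  cls <- structure(list(
    assignments = tibble::tibble(
      reaction_id = names(cmap), h1_class = unname(cmap),
      h2_class = NA_character_, orientation = "forward",
      excluded_reason = NA_character_),
    classes = tibble::tibble(), h2_strings = character(),
    params = list(heights = 1L)), class = "rms_classification")
  mods <- tibble::tibble(path_id = "A->B->C", length = 2L, pci = 2L)
  s <- pathway_conservation_summary(links, mods, cls, length = 2L)
  bio <- s[s$type == "Biosynthesis", ]
  expect_equal(bio$n_pathways, 4L)
  expect_equal(bio$n_conserved, 2L)
  expect_equal(bio$fraction, 0.5)
  expect_equal(s$fraction[s$type == "All"], 0.5)
  # no modules -> all zero
  s0 <- pathway_conservation_summary(links, mods[0, ], cls, length = 2L)
  expect_true(all(s0$n_conserved == 0L))
})
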