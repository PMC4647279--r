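test_that("wRea counts every classified reaction, in or out of the network", {
  run <- cached_run()
  wr <- compute_wrea(run$classification, 1L)
  a <- tidy(run$classification)
  expect_equal(sum(wr$w_rea), sum(!is.na(a$h1_class)))
  # per class it equals the membership count
  cl <- run$classification$classes
  cl <- cl[cl$height == 1L, ]
  expect_equal(wr$w_rea[match(cl$class_id, wr$class_id)], unname(cl$n_members))
})

test_that("PageRank is uniform on rings and matches power iteration", {
  ring <- manual_rms_network(
    LETTERS[1:5],
    tibble::tibble(from = LETTERS[1:5], to = LETTERS[c(2:5, 1)],
                   n_edges = 1L, prob = 1))
  pr <- compute_wpagerank(ring)
  expect_equal(pr$w_pagerank, rep(0.2, 5), tolerance = 1e-9)
  expect_equal(sum(pr$w_pagerank), 1, tolerance = 1e-6)

  two <- manual_rms_network(
    c("A", "B"),
    tibble::tibble(from = c("A", "B"), to = c("B", "A"), n_edges = 1L,
                   prob = 1))
  expect_equal(compute_wpagerank(two)$w_pagerank, c(0.5, 0.5),
               tolerance = 1e-9)

  # star with all edges into the hub: hub strictly greatest, and the
  # whole vector matches an independent power iteration
  star <- manual_rms_network(
    c("HUB", "S1", "S2", "S3"),
    tibble::tibble(from = c("S1", "S2", "S3"), to = "HUB", n_edges = 1L,
                   prob = 1))
  pr2 <- compute_wpagerank(star)
  expect_true(all(pr2$w_pagerank[pr2$class_id == "HUB"] >
                    pr2$w_pagerank[pr2$class_id != "HUB"]))
  orac <- oracle_pagerank(star$nodes$class_id, star$edges)
  expect_equal(pr2$w_pagerank, unname(orac[pr2$class_id]), tolerance = 1e-8)

  # invariance under node relabeling
  star2 <- star
  relab <- c(HUB = "Z9", S1 = "A1", S2 = "A2", S3 = "A3")
  star2$nodes$class_id <- unname(relab[star2$nodes$class_id])
  star2$edges$from <- unname(relab[star2$edges$from])
  star2$edges$to <- unname(relab[star2$edges$to])
  pr3 <- compute_wpagerank(star2)
  expect_equal(sort(pr3$w_pagerank), sort(pr2$w_pagerank), tolerance = 1e-9)
})

test_that("domain association ratios and scores follow their definitions", {
  # 10 proteins share composition DomX; 5 of them hit class K1 (which
  # has no other proteins): d2r = 0.5, r2d = 1, harmonic mean = 2/3
  cls <- structure(list(
    assignments = tibble::tibble(
      reaction_id = c("k1", "k2"), h1_class = c("K1", "K2"),
      h2_class = NA_character_, orientation = "forward",
      excluded_reason = NA_character_),
    classes = tibble::tibble(), h2_strings = character(),
    params = list(heights = 1L)), class = "rms_classification")
  prot <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:10),
    domains = "DomX",
    reaction_ids = c(rep("k1", 5), rep("k2", 5)))
  sc <- domain_rms_scores(prot, cls, 1L)
  r1 <- sc[sc$class_id == "K1", ]
  expect_equal(r1$n_joint, 5L)
  expect_equal(r1$n_dom, 10L)
  expect_equal(r1$n_rms, 5L)
  expect_equal(r1$d2r, 0.5)
  expect_equal(r1$r2d, 1.0)
  expect_equal(r1$score, 2 / 3)
  # perfect association scores 1
  prot2 <- tibble::tibble(protein_id = "q", domains = "DomY",
                          reaction_ids = "k1")
  sc2 <- domain_rms_scores(prot2, cls, 1L)
  expect_equal(sc2$score[sc2$domain_comp == "DomY"], 1.0)
  # harmonic-mean bounds on the fixture
  run <- cached_run()
  fx <- cached_fixture()
  scf <- domain_rms_scores(fx$proteins, run$classification, 1L)
  expect_true(all(scf$score >= 0 & scf$score <= 1))
  expect_true(all(scf$score <= 2 * pmin(scf$d2r, scf$r2d)))
  expect_true(all(scf$n_joint > 0))
})

test_that("wProt is the geometric mean of domain counts times scores", {
  mk <- function(n_dom, score)
    tibble::tibble(domain_comp = sprintf("D%d", seq_along(n_dom)),
                   class_id = "K", n_joint = 1L, n_dom = n_dom,
                   n_rms = 1L, d2r = 1, r2d = 1, score = score)
  expect_equal(compute_wprot(mk(100L, 0.5))$w_prot, 50)
  expect_equal(compute_wprot(mk(c(100L, 400L), c(0.5, 0.2)))$w_prot,
               sqrt(50 * 80), tolerance = 1e-9)
  # orphan class -> undefined marker, not zero
  out <- compute_wprot(mk(100L, 0.5), class_ids = c("K", "ORPHAN"))
  expect_true(is.na(out$w_prot[out$class_id == "ORPHAN"]))
  # scale monotonicity: raising any domain count never lowers wProt
  base <- compute_wprot(mk(c(100L, 400L), c(0.5, 0.2)))$w_prot
  up <- compute_wprot(mk(c(150L, 400L), c(0.5, 0.2)))$w_prot
  expect_gte(up, base)
})

test_that("the weight table covers the network and flags orphans", {
  run <- cached_run()
  fx <- cached_fixture()
  w <- run$heights$h1$weights
  expect_setequal(w$class_id, run$heights$h1$rms_network$nodes$class_id)
  expect_equal(sum(w$w_pagerank), 1, tolerance = 1e-6)
  # orphan operators (no protein rows) are exactly the NA wProt classes
  lk <- class_lookup(run$classification, 1L)
  orphan_classes <- unique(unname(
    lk[names(fx$truth$op_of_reaction)[fx$truth$op_of_reaction %in%
                                        fx$truth$orphan_ops]]))
  expect_setequal(w$class_id[is.na(w$w_prot)], orphan_classes)
})
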