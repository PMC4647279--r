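test_that("balance checking computes stoichiometric element and charge deltas", {
  mols <- toy_molecules()
  rxns <- dplyr::bind_rows(
    one_reaction("knallgas", c(h2 = 2, o2 = 1), c(water = 2)),
    one_reaction("short", c(h2 = 1, o2 = 1), c(water = 1)),
    one_reaction("ghost", c(nothere = 1), c(water = 1)))
  bal <- check_balance(rxns, mols)
  expect_true(bal$balanced[1])
  expect_equal(bal$element_deltas[[1]], stats::setNames(integer(), character()))
  expect_false(bal$balanced[2])
  expect_equal(bal$element_deltas[[2]][["O"]], -1L)
  expect_equal(bal$status[3], "structure unavailable")
  expect_true(is.na(bal$balanced[3]))
})

test_that("reaction signatures are the signed multiset difference", {
  mols <- standardize_all(toy_molecules())
  rx <- one_reaction("dehyd", c(ethanol = 1), c(acetaldehyde = 1, h2 = 1))
  for (h in 1:2) {
    raw <- reaction_signature(rx, h, mols)
    # independent naive multiset subtraction
    sig <- function(id) molecular_signature(mols[[id]], h)
    exp_raw <- oracle_rms_diff(
      list(list(sig = sig("acetaldehyde"), coeff = 1), list(sig = sig("h2"), coeff = 1)),
      list(list(sig = sig("ethanol"), coeff = 1)))
    expect_equal(raw$signature, exp_raw$signature)
    expect_equal(raw$count, exp_raw$count)
  }
  # unchanged atoms cancel: at h=1 the methyl H environment is untouched
  raw1 <- reaction_signature(rx, 1L, mols)
  expect_false("[H]([C]([C][H][H]))" %in% raw1$signature)
  expect_true(sum(abs(raw1$count)) < sum(molecular_signature(mols$ethanol, 1)$count) * 2)

  # doubling stoichiometry doubles every count
  rx2 <- one_reaction("dehyd2", c(ethanol = 2), c(acetaldehyde = 2, h2 = 2))
  raw2 <- reaction_signature(rx2, 1L, mols)
  expect_equal(raw2$signature, raw1$signature)
  expect_equal(raw2$count, 2L * raw1$count)

  # identity reaction is a null transformation
  ident <- one_reaction("ident", c(water = 1), c(water = 1))
  expect_equal(nrow(reaction_signature(ident, 1L, mols)), 0L)
})

test_that("orientation merging gives one key per transformation", {
  mols <- standardize_all(toy_molecules())
  rx <- one_reaction("dehyd", c(ethanol = 1), c(acetaldehyde = 1, h2 = 1))
  rev <- reverse_reaction(rx)
  raw_f <- reaction_signature(rx, 1L, mols)
  raw_r <- reaction_signature(rev, 1L, mols)
  # exact negation
  expect_equal(raw_f$signature, raw_r$signature)
  expect_equal(raw_f$count, -raw_r$count)
  kf <- canonical_rms(raw_f)
  kr <- canonical_rms(raw_r)
  expect_identical(kf$key, kr$key)
  expect_false(kf$orientation == kr$orientation)
  expect_error(canonical_rms(raw_f[0, ]), "null transformation")
})

test_that("height-1 classification groups by exact key equality", {
  mols <- standardize_all(c(toy_molecules(), list(
    propanol = parse_molecule("CCCO", "smiles", id = "propanol"),
    propanal = parse_molecule("CCC=O", "smiles", id = "propanal"))))
  rxns <- dplyr::bind_rows(
    one_reaction("r1", c(ethanol = 1), c(acetaldehyde = 1, h2 = 1)),
    one_reaction("r2", c(propanol = 1), c(propanal = 1, h2 = 1)),
    one_reaction("r3", c(h2 = 2, o2 = 1), c(water = 2)),
    one_reaction("ident", c(water = 1), c(water = 1)),
    one_reaction("pump", c(water = 1), c(water = 1), transport = TRUE))
  cls <- rms_classify(rxns, mols, heights = 1L)
  a <- tidy(cls)
  # same transformation on different substrates -> one class of size 2
  expect_equal(a$h1_class[1], a$h1_class[2])
  expect_false(a$h1_class[1] == a$h1_class[3])
  expect_equal(a$excluded_reason[4], "null transformation at height 1")
  expect_equal(a$excluded_reason[5], "transport")
  g <- glance(cls)
  expect_equal(g$n_h1_classes, 2L)
  expect_equal(g$n_classified, 3L)
})

test_that("signature distance is a Levenshtein metric", {
  expect_equal(signature_distance("abc", "abc"), 0)
  expect_equal(signature_distance("abc", "abd"), 1)
  set.seed(31)
  rstr <- function() paste(sample(letters[1:4], sample(3:12, 1), TRUE),
                           collapse = "")
  for (i in 1:30) {
    a <- rstr(); b <- rstr(); c <- rstr()
    dab <- signature_distance(a, b)
    expect_equal(dab, oracle_levenshtein(a, b))
    expect_equal(dab, signature_distance(b, a))
    expect_lte(dab, signature_distance(a, c) + signature_distance(c, b))
  }
})

test_that("height-2 refinement cuts the Ward tree at the cophenetic threshold", {
  # all members identical -> one sub-class
  expect_equal(refine_h2(rep("xxx", 4)), rep(1L, 4))
  # singleton -> one sub-class
  expect_equal(refine_h2("x"), 1L)
  # two groups of identical strings separated far above the cut -> two
  g1 <- strrep("a", 10)
  g2 <- strrep("b", 150)  # length difference alone exceeds 90
  cl <- refine_h2(c(g1, g1, g2, g2), threshold = 90)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  # members with identical strings always co-cluster, whatever the cut
  cl2 <- refine_h2(c(g1, g2, g1, g2), threshold = 0.5)
  expect_equal(cl2[1], cl2[3])
  expect_equal(cl2[2], cl2[4])
})

test_that("h2 classes nest inside h1 classes on the generated fixture", {
  run <- cached_run()
  a <- tidy(run$classification)
  a <- a[!is.na(a$h1_class), ]
  # every h2 class maps to exactly one h1 class (its prefix)
  expect_true(all(startsWith(a$h2_class, a$h1_class)))
  nest <- table(a$h2_class, a$h1_class)
  expect_true(all(rowSums(nest > 0) == 1))
  # classes aggregate more reactions at h1 than at h2
  g <- glance(run$classification)
  expect_gt(g$mean_members_h1, g$mean_members_h2)
})
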