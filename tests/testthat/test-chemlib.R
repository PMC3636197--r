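# molecule ingestion, normalization, descriptors, drug-likeness

fixtures <- gen_molecule_fixtures()
fixture_desc <- compute_descriptors(stats::setNames(fixtures$smiles, fixtures$id))

test_that("library reading counts records and skips malformed entries", {
  p <- write_smiles_file(c("CCO", "c1ccccc1", "CC(=O)O"),
                         c("m1", "m2", "m3"))
  lib <- read_library(p)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$id, c("m1", "m2", "m3"))

  p2 <- write_smiles_file(c("CCO", "C1CC", "CCN"), c("ok1", "bad", "ok2"))
  expect_warning(lib2 <- read_library(p2), "unparsable")
  expect_equal(nrow(lib2), 2)
  expect_equal(lib2$id, c("ok1", "ok2"))
  expect_equal(attr(lib2, "n_skipped"), 1)

  expect_error(read_library(tempfile()), "not found")
  p3 <- write_smiles_file("C1CC", "allbad")
  expect_error(suppressWarnings(read_library(p3)), "no parsable")
})

test_that("SDF and SMILES encodings of one structure share a canonical key", {
  smi <- "CC(=O)Oc1ccccc1C(=O)O"
  p_smi <- write_smiles_file(smi, "aspirin")
  sdf <- ChemmineR::smiles2sdf(c(aspirin = smi))
  p_sdf <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, p_sdf)
  lib_smi <- read_library(p_smi, format = "smiles")
  lib_sdf <- read_library(p_sdf, format = "sdf")
  expect_equal(lib_smi$key, lib_sdf$key)
})

test_that("largest fragment keeps the heavy-atom-richest component", {
  expect_equal(largest_fragment("CC(=O)[O-].[Na+]"),
               canonical_smiles("CC(=O)[O-]"))
  expect_equal(largest_fragment("c1ccccc1"), "c1ccccc1")
  # equal heavy-atom counts: ethanethiol (62.1 Da) outweighs ethanol (46.1 Da)
  expect_equal(largest_fragment("CCO.CCS"), canonical_smiles("CCS"))
  lib <- data.frame(id = "x", smiles = "CC(=O)[O-].[Na+]",
                    key = "CC(=O)[O-].[Na+]", stringsAsFactors = FALSE)
  out <- largest_fragment(lib)
  expect_equal(out$key, canonical_smiles("CC(=O)[O-]"))
})

test_that("deduplication is stereo-aware, order-stable and idempotent", {
  p <- write_smiles_file(c("OCC", "CCO", "C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"),
                         c("a", "b", "r_ala", "s_ala"))
  lib <- read_library(p)
  dd <- deduplicate(lib)
  # the two ethanol writings collapse; the enantiomer pair survives
  expect_equal(dd$library$id, c("a", "r_ala", "s_ala"))
  expect_equal(dd$duplicates$kept_id, "a")
  expect_equal(dd$duplicates$removed_id, "b")

  dd2 <- deduplicate(dd$library)
  expect_identical(dd2$library, dd$library)
  expect_equal(nrow(dd2$duplicates), 0)

  uniq <- read_library(write_smiles_file(c("CCO", "CCN"), c("u1", "u2")))
  expect_equal(deduplicate(uniq)$library$id, c("u1", "u2"))
})

test_that("descriptor panel matches hand-verified fixture values", {
  d <- fixture_desc
  for (col in c("mw", "hba", "hbd", "n_rings", "n_rotatable",
                "n_carbon", "n_chiral_c")) {
    truth <- fixtures[[col]]
    ok <- !is.na(truth)
    expect_equal(unname(d[[col]][ok]), unname(truth[ok]),
                 tolerance = if (col == "mw") 1e-3 else 0,
                 label = paste("descriptor", col))
  }
  # aromatic-ring perception on unambiguous aromatics
  arom <- stats::setNames(d$n_aromatic_rings, fixtures$name)
  expect_equal(unname(arom["benzene"]), 1L)
  expect_equal(unname(arom["naphthalene"]), 2L)
  expect_gte(unname(arom["quercetin"]), 2L)
  expect_equal(unname(arom["ethanol"]), 0L)
})

test_that("additive AlogP tracks measured octanol-water partitioning", {
  # experimental logP values; the atom-contribution estimate is asserted
  # to land within +/- 1 log unit
  exp_logp <- c(ethanol = -0.31, benzene = 2.13, aspirin = 1.19,
                ibuprofen = 3.97, caffeine = -0.07)
  d <- stats::setNames(fixture_desc$alogp, fixtures$name)
  for (nm in names(exp_logp)) {
    expect_lt(abs(d[[nm]] - exp_logp[[nm]]), 1.0, label = nm)
  }
})

test_that("descriptor invariants hold on all fixtures", {
  d <- fixture_desc
  expect_true(all(d$mw > 0))
  expect_true(all(d[c("n_rotatable", "n_rings", "n_aromatic_rings",
                      "hba", "hbd", "n_chiral_c")] >= 0))
  expect_true(all(d$n_aromatic_rings <= d$n_rings))
  expect_true(all(d$n_chiral_c <= d$n_carbon))
  expect_true(all(d$fpsa >= 0 & d$fpsa <= 1))
  expect_equal(d$f_chirality, d$n_chiral_c / d$n_carbon)
})

test_that("F-chirality counts assigned carbon stereocenters", {
  expect_equal(f_chirality("CCO"), 0)
  expect_equal(f_chirality("OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O"),
               5 / 6, tolerance = 1e-12)
  # one stereocenter among four carbons
  expect_equal(f_chirality("C[C@H](O)CC"), 0.25)
  achiral <- fixtures$smiles[fixtures$n_chiral_c == 0]
  expect_true(all(f_chirality(achiral) == 0))
  expect_warning(v <- f_chirality("O"), "undefined")
  expect_true(is.na(v))
})

test_that("rule-of-five flags use strict inequalities", {
  # library medians of a natural-product collection satisfy all four
  med <- data.frame(mw = 406.5, hba = 6, hbd = 2, alogp = 2.710)
  r <- ro5_evaluate(med)
  expect_equal(r$n_satisfied, 4)
  expect_true(r$pass_strict && r$pass_relaxed)

  worst <- data.frame(mw = 600, hba = 12, hbd = 6, alogp = 6)
  expect_equal(ro5_evaluate(worst)$n_satisfied, 0)

  edge <- data.frame(mw = 500, hba = 6, hbd = 2, alogp = 2.7)
  r3 <- ro5_evaluate(edge)
  expect_false(r3$flag_mw)
  expect_equal(r3$n_satisfied, 3)
  expect_false(r3$pass_strict)
  expect_true(r3$pass_relaxed)
})

test_that("summary categories count the stated combinations", {
  two <- data.frame(mw = c(300, 650), hba = c(5, 5), hbd = c(2, 2),
                    alogp = c(2, 2))
  s <- library_summary(two)
  expect_equal(unname(s$ro5_categories["all_satisfied"]), 1)
  expect_equal(unname(s$ro5_categories["except_mw"]), 2)
  expect_equal(unname(s$ro5_categories["at_least_three"]), 2)

  same <- data.frame(mw = rep(300, 5), hba = rep(5, 5), hbd = rep(2, 5),
                     alogp = rep(2, 5))
  expect_true(all(library_summary(same)$ro5_categories == 5))

  expect_error(library_summary(two[0, ]), "empty")
})

test_that("every single-criterion failure lands in exactly one except bin", {
  set.seed(71)
  desc <- data.frame(mw = stats::runif(300, 100, 900),
                     hba = sample(0:15, 300, TRUE),
                     hbd = sample(0:8, 300, TRUE),
                     alogp = stats::rnorm(300, 3, 2.5))
  r <- ro5_evaluate(desc)
  s <- library_summary(desc)$ro5_categories
  expect_true(all(s[c("except_mw", "except_acceptors", "except_donors",
                      "except_alogp")] >= s["all_satisfied"]))
  expect_gte(s[["at_least_three"]], s[["all_satisfied"]])
  one_fail <- which(r$n_satisfied == 3)
  # each such molecule is in precisely one except category
  in_cat <- cbind(r$flag_hba & r$flag_hbd & r$flag_alogp,
                  r$flag_mw & r$flag_hbd & r$flag_alogp,
                  r$flag_mw & r$flag_hba & r$flag_alogp,
                  r$flag_mw & r$flag_hba & r$flag_hbd)
  expect_true(all(rowSums(in_cat[one_fail, , drop = FALSE]) == 1))
  # strict passers are in all categories
  expect_true(all(rowSums(in_cat[r$pass_strict, , drop = FALSE]) == 4))
})
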