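test_that("percent activity is the normalised control-referenced ratio", {
  expect_equal(percent_activity(5, 5, 25), 0)
  expect_equal(percent_activity(25, 5, 25), 100)
  expect_equal(percent_activity(15, 5, 25), 50)
  # affine invariance: shifting all three signals changes nothing
  for (shift in c(-3, 0.7, 120)) {
    expect_equal(percent_activity(15 + shift, 5 + shift, 25 + shift), 50)
  }
  expect_error(percent_activity(1, 5, 5), "degenerate")
})

test_that("activity-score labeling matches the 0/1-39/40-100 classing", {
  expect_equal(assign_label(40), "active")
  expect_equal(assign_label(39), "inactive")
  expect_equal(assign_label(0), "inactive")
  expect_equal(assign_label(100), "active")
  expect_equal(assign_label(39, mode = "ternary"), "inconclusive")
  expect_equal(assign_label(c(0, 1, 39.5, 40), mode = "ternary"),
               c("inactive", "inconclusive", "inconclusive", "active"))
  expect_error(assign_label(101), "within")
  expect_error(assign_label(-0.5), "within")
})

test_that("curation collapses consistent duplicates and keeps source ids", {
  recs <- data.frame(
    record_id = c("a", "b"),
    smiles = c("c1ccccc1O", "Oc1ccccc1"),   # same structure, two notations
    activity_score = c(55, 80), stringsAsFactors = FALSE)
  out <- curate(recs)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$records$label, "active")
  expect_setequal(out$records$source_ids[[1]], c("a", "b"))
  expect_equal(nrow(out$report), 0L)
})

test_that("curation drops conflicting-label duplicates entirely", {
  recs <- data.frame(
    record_id = c("a", "b", "c"),
    smiles = c("c1ccccc1O", "Oc1ccccc1", "CCO"),
    activity_score = c(0, 80, 10), stringsAsFactors = FALSE)
  out <- curate(recs)
  expect_equal(out$records$smiles, canonical_smiles("CCO"))
  expect_setequal(out$report$record_id, c("a", "b"))
  expect_true(all(out$report$reason == "conflicting label"))
})

test_that("nonorganic and unparseable records are dropped with reasons", {
  recs <- data.frame(
    record_id = c("org", "inorg", "junk"),
    smiles = c("CCO", "O=S(=O)(O)O", "not_a_smiles(("),
    activity_score = c(50, 50, 50), stringsAsFactors = FALSE)
  out <- curate(recs)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$report$reason[out$report$record_id == "inorg"],
               "nonorganic")
  expect_equal(out$report$reason[out$report$record_id == "junk"],
               "unparseable structure")
})

test_that("salt stripping keys duplicates on the largest organic fragment", {
  recs <- data.frame(
    record_id = c("salt", "parent"),
    smiles = c("CC(=O)[O-].[Na+]", "CC(=O)[O-]"),
    activity_score = c(60, 70), stringsAsFactors = FALSE)
  out <- curate(recs)
  expect_equal(nrow(out$records), 1L)
  expect_setequal(out$records$source_ids[[1]], c("salt", "parent"))
})

test_that("curation is idempotent and never grows the record set", {
  lib <- make_toy_library(n = 12, active_fraction = 0.5, seed = 2,
                          include_extras = TRUE)
  out1 <- curate(lib)
  expect_lte(nrow(out1$records), nrow(lib))
  # every dropped record appears exactly once in the report
  expect_equal(anyDuplicated(out1$report$record_id), 0L)
  expect_equal(nrow(out1$records) + length(unique(out1$report$record_id)),
               nrow(lib))
  again <- data.frame(record_id = paste0("r", seq_len(nrow(out1$records))),
                      smiles = out1$records$smiles,
                      activity_score = out1$records$activity_score,
                      stringsAsFactors = FALSE)
  out2 <- curate(again)
  expect_setequal(out2$records$structure_key, out1$records$structure_key)
  expect_equal(out2$records$label[order(out2$records$structure_key)],
               out1$records$label[order(out1$records$structure_key)])
})

test_that("neutralize wash removes charges wherever valence rules permit", {
  # acetate anion -> neutral acetic acid
  m <- wash("CC(=O)[O-]", wash_spec("neutralize", "depict2d"), seed = 1)
  expect_equal(sum(m$formal_charges), 0L)
  expect_true(all(m$formal_charges == 0L))
  # one H gained by the carboxylate oxygen
  expect_equal(sum(m$elements == "H"), 4L)
  # ammonium cation -> neutral amine (loses one H)
  m2 <- wash("CC[NH3+]", wash_spec("neutralize", "depict2d"), seed = 1)
  expect_true(all(m2$formal_charges == 0L))
  expect_equal(sum(m2$elements == "H"), 7L)
  # zwitterion fully neutralised, atom by atom
  m3 <- wash("C(C(=O)[O-])[NH3+]", wash_spec("neutralize", "depict2d"),
             seed = 1)
  expect_true(all(m3$formal_charges == 0L))
})

test_that("dominant protonation applies the pH-7 acid/base rule table", {
  # carboxylic acid deprotonated
  m <- wash("CC(=O)O", wash_spec("dominant", "depict2d"), seed = 1)
  expect_equal(sum(m$formal_charges), -1L)
  # aliphatic amine protonated
  m2 <- wash("CCN", wash_spec("dominant", "depict2d"), seed = 1)
  expect_equal(sum(m2$formal_charges), 1L)
  # amide nitrogen untouched
  m3 <- wash("CC(=O)N", wash_spec("dominant", "depict2d"), seed = 1)
  expect_equal(sum(m3$formal_charges[m3$elements == "N"]), 0L)
})

test_that("3D washes are reproducible bit-for-bit and non-planar", {
  sp <- wash_spec("none", "corina_like")
  a <- wash("CCCCO", sp, seed = 7, mol_id = "x")
  b <- wash("CCCCO", sp, seed = 7, mol_id = "x")
  expect_identical(a$coords, b$coords)
  # a genuinely 3D embedding: thickness along the thinnest principal axis
  sv <- svd(scale(a$coords, scale = FALSE))$d
  expect_gt(sv[3], 0.1)
  # depict2d stays planar
  flat <- wash("CCCCO", wash_spec("none", "depict2d"), seed = 7)
  expect_equal(max(abs(flat$coords[, 3])), 0)
})

test_that("chained wash applies both stages in order", {
  sp <- wash_spec("neutralize", "rebuild3d",
                  chained = wash_spec("neutralize", "corina_like"))
  m <- wash("CC(=O)[O-]", sp, seed = 3, mol_id = "chain1")
  expect_true(all(m$formal_charges == 0L))
  sv <- svd(scale(m$coords, scale = FALSE))$d
  expect_gt(sv[3], 0.05)
})

test_that("washed SDF round-trips through write/read", {
  sp <- wash_spec("none", "corina_like")
  mols <- list(wash("CCO", sp, seed = 1, mol_id = "a"),
               wash("CC(=O)[O-]", sp, seed = 1, mol_id = "b"))
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, tf, fields = data.frame(label = c("active", "inactive")))
  back <- read_sdf_mols(tf)
  expect_equal(length(back$mols), 2L)
  expect_equal(back$mols[[1]]$elements, mols[[1]]$elements)
  expect_equal(back$mols[[2]]$formal_charges, mols[[2]]$formal_charges)
  expect_equal(back$mols[[1]]$coords, mols[[1]]$coords, tolerance = 1e-3)
  expect_equal(as.character(back$fields$label), c("active", "inactive"))
})

test_that("SMILES tables parse from CSV and TSV with flexible headers", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,score", "r1,CCO,55", "r2,CCN,10"), tf)
  t1 <- read_smiles_table(tf)
  expect_equal(t1$record_id, c("r1", "r2"))
  expect_equal(t1$activity_score, c(55, 10))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\tSMILES\tactivity_score", "a\tCCO\t99"), tf2)
  t2 <- read_smiles_table(tf2)
  expect_equal(t2$smiles, "CCO")
})
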