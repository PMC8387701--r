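# Structure curation: standardization, element filtering, deduplication.

test_that("standardization handles organics, salts and rejections", {
  cases <- list(
    list(smiles = "CCO", status = "accepted", curated = "CCO"),
    list(smiles = "O=S(=O)(O)O", status = "rejected_inorganic"),
    list(smiles = "CC[Pb](CC)(CC)CC", status = "rejected_inorganic"),
    list(smiles = "CCO.CCC", status = "rejected_mixture"),
    list(smiles = "not-a-smiles", status = "rejected_no_unique_structure"),
    list(smiles = "C1CC", status = "rejected_no_unique_structure"))
  for (cs in cases) {
    r <- standardize_structure(cs$smiles)
    expect_identical(r$status, cs$status, label = cs$smiles)
    if (!is.null(cs$curated)) {
      expect_identical(r$curated_smiles, cs$curated)
    } else {
      expect_true(is.na(r$curated_smiles))
    }
  }
})

test_that("a sodium salt neutralizes to the toolkit's canonical free acid", {
  r <- standardize_structure("[Na+].[O-]C(=O)c1ccccc1")
  expect_identical(r$status, "accepted")
  # oracle: the backend's own canonicalization of neutral benzoic acid
  oracle <- trimws(ChemmineOB::convertFormat("SMI", "CAN",
                                             "OC(=O)c1ccccc1"))
  expect_identical(r$curated_smiles, oracle)
  expect_false(grepl("Na", r$curated_smiles))
})

test_that("standardization is idempotent on accepted structures", {
  for (smi in c("CCO", "[Na+].[O-]C(=O)c1ccccc1", "CC(N)C(=O)O",
                "Clc1ccc(O)cc1", "O=c1cccc[nH]1")) {
    r1 <- standardize_structure(smi)
    expect_identical(r1$status, "accepted", label = smi)
    r2 <- standardize_structure(r1$curated_smiles)
    expect_identical(r2$curated_smiles, r1$curated_smiles, label = smi)
    expect_identical(r2$inchi, r1$inchi, label = smi)
  }
})

test_that("element filter matches the whitelist exactly", {
  expect_true(filter_elements("CC(N)C(=O)O"))
  expect_true(filter_elements("ClC(Br)(I)F"))
  expect_true(filter_elements("CP(=O)(O)OCS"))
  expect_false(filter_elements("CC[Se]CC"))
  expect_false(filter_elements("c1ccccc1[Si](C)(C)C"))
  expect_false(filter_elements("B(O)(O)c1ccccc1"))
  # filter agrees with the standardization status on a mixed panel
  panel <- c("CCO", "CC[Se]CC", "CCN", "c1ccccc1[Si](C)(C)C")
  flags <- filter_elements(panel)
  statuses <- vapply(panel, function(s) standardize_structure(s)$status, "")
  expect_identical(unname(flags), unname(statuses != "rejected_element"))
})

test_that("tautomers hash to one structure for deduplication", {
  a <- standardize_structure("Oc1ccccn1")    # 2-hydroxypyridine
  b <- standardize_structure("O=c1cccc[nH]1")  # 2-pyridone
  expect_identical(a$inchi, b$inchi)
})

test_that("deduplication merges concordant and removes contradictory groups", {
  rec <- synth_smiles_table()
  out <- curate_structures(rec)
  # every input id appears exactly once
  expect_identical(sort(out$id), sort(rec$id))
  # concordant pair: one kept, one merged away
  pair <- out[out$smiles == "Oc1ccccc1", ]
  expect_identical(pair$status, rep("merged_duplicate", 2))
  expect_identical(sum(pair$kept), 1L)
  # contradictory pair: both removed, no curated smiles
  bad <- out[out$smiles == "Nc1ccccc1", ]
  expect_identical(bad$status, rep("removed_contradictory_duplicate", 2))
  expect_false(any(bad$kept))
  expect_true(all(is.na(bad$curated_smiles)))
  # kept records never share a structure
  kept <- out[out$kept, ]
  expect_false(anyDuplicated(kept$inchi) > 0)
  # three distinct singles pass through untouched
  singles <- out[out$id %in% c("S01", "S02", "S12"), ]
  expect_true(all(singles$status %in% c("accepted")))
  expect_true(all(singles$kept))
})

test_that("category-level conflict rule is stricter than the binary rule", {
  rep0 <- data.frame(
    id = c("a", "b"), smiles = c("x", "x"), category = c("HSE", "LSE"),
    status = "accepted", curated_smiles = "CCO",
    inchi = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", notes = "",
    stringsAsFactors = FALSE)
  bin <- deduplicate_structures(rep0, conflict_on = "binary")
  expect_identical(sum(bin$kept), 1L)  # both active: merged
  cat <- deduplicate_structures(rep0, conflict_on = "category")
  expect_identical(sum(cat$kept), 0L)  # HSE vs LSE: contradictory
})

test_that("structure tables round-trip through files", {
  dir <- withr::local_tempdir()
  st <- synth_smiles_table()
  write.table(st[, c("id", "smiles")], file.path(dir, "smiles.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  back <- read_structures(file.path(dir, "smiles.tsv"))
  expect_identical(back$smiles, st$smiles)
  out <- curate_structures(st)
  write_curation_report(out, file.path(dir, "report.csv"))
  rep <- read.csv(file.path(dir, "report.csv"), stringsAsFactors = FALSE)
  expect_identical(names(rep), c("id", "status", "curated_smiles", "notes"))
  expect_identical(nrow(rep), nrow(st))
})
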