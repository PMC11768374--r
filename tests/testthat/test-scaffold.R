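test_that("most-central-ring extraction handles the canonical cases", {
  # single-ring molecules return that ring's canonical key
  benzene_key <- extractMostCentralRing("c1ccccc1")
  expect_identical(extractMostCentralRing("Cc1ccccc1"), benzene_key)
  expect_identical(extractMostCentralRing("CCc1ccccc1CC"), benzene_key)
  # acyclic molecules have no scaffold
  expect_true(is.na(extractMostCentralRing("CCCCCC")))
  # biphenyl: two equivalent ring systems tie; tie-break keeps a benzene key
  expect_identical(extractMostCentralRing("c1ccc(-c2ccccc2)cc1"), benzene_key)
  # pyridine differs from benzene
  expect_false(identical(extractMostCentralRing("c1ccncc1"), benzene_key))
  # a fused system is a single ring system, not two
  naph <- extractMostCentralRing("c1ccc2ccccc2c1")
  expect_false(identical(naph, benzene_key))
  expect_error(extractMostCentralRing("not_a_smiles"), "invalid")
})

test_that("scaffold assignment honours external tables", {
  lib <- smallLibrary()
  asn_ext <- scaffoldAssignments(lib, external = truthAssignments(lib))
  expect_identical(asn_ext$scaffold_id,
                   libraryRecords(lib)$scaffold_family)
  # direct extraction runs on a few molecules and yields character keys
  sub <- CompoundLibrary(libraryRecords(lib)[1:5, ],
                         name = "sub")
  asn <- scaffoldAssignments(sub)
  expect_equal(nrow(asn), 5L)
  expect_type(asn$scaffold_id, "character")
})

test_that("grouping applies merges and the minimum-count rule", {
  asn <- data.frame(
    compound_id = sprintf("C%02d", 1:10),
    scaffold_id = c("a", "a", "a", "b", "b", "c", "d", NA, "e", "e"),
    stringsAsFactors = FALSE)
  g <- groupScaffolds(asn, min_count = 2L)
  expect_true(all(g$analyzed[g$group_id %in% c("a", "b", "e")], na.rm = TRUE))
  expect_false(any(g$analyzed[g$scaffold_id %in% c("c", "d")]))
  expect_false(g$analyzed[8])                      # unassigned never analysed
  # bioisostere merge rescues the singletons
  g2 <- groupScaffolds(asn, min_count = 2L, merge_map = c(c = "cd", d = "cd"))
  expect_true(all(g2$analyzed[g2$scaffold_id %in% c("c", "d")]))
  expect_identical(unique(g2$group_id[g2$scaffold_id %in% c("c", "d")]), "cd")
  expect_error(groupScaffolds(asn, merge_map = c(zzz = "x")), "unknown")
})

test_that("enrichment factor follows its definition", {
  # 6 of 20 potent carry the scaffold; 12 of 80 compounds carry it
  expect_equal(enrichmentFactor(6, 20, 12, 80), (6 / 20) / (12 / 80))
  expect_equal(enrichmentFactor(0, 20, 12, 80), 0)
  expect_error(enrichmentFactor(1, 0, 5, 10), "positive")
})

test_that("scaffold statistics recover the planted enriched family", {
  lib <- smallLibrary()
  rec <- libraryRecords(lib)
  grouped <- groupScaffolds(scaffoldAssignments(lib, external = truthAssignments(lib)))
  out <- scaffoldSummaries(grouped, rec$pic50, potency_cutoff = 6.5)
  s <- out$summary
  expect_true("quinazoline" %in% s$scaffold_id)
  q <- s[s$scaffold_id == "quinazoline", ]
  expect_gt(q$EF, 1)
  expect_gt(q$mean_pic50, q$mean_out)
  expect_true(q$relevant)
  # chi-square residual of the planted family is in the potent direction
  expect_gt(q$std_residual, 0)
  # summaries line up with the chi-square table's groups
  expect_setequal(s$scaffold_id, rownames(out$chi_square$expected))
})

test_that("relevance gating needs both enrichment and significance", {
  base <- data.frame(EF = c(1.5, 0.8, 1.5, 1.5),
                     mw_p = c(0.01, 0.01, 0.50, 0.50),
                     mean_pic50 = c(7, 7, 7, 7),
                     mean_out = c(6, 6, 6, 6),
                     std_residual = c(0.5, 3.0, 3.0, 0.5))
  out <- selectRelevantScaffolds(base)
  expect_identical(out$relevant, c(TRUE, FALSE, TRUE, FALSE))
  # a significant Mann-Whitney with a LOWER mean does not qualify
  low <- data.frame(EF = 2, mw_p = 0.001, mean_pic50 = 5, mean_out = 7,
                    std_residual = 0)
  expect_false(selectRelevantScaffolds(low)$relevant)
})

test_that("one-hot scaffold bits have row sums of zero or one", {
  lib <- smallLibrary()
  grouped <- groupScaffolds(scaffoldAssignments(lib, external = truthAssignments(lib)))
  bits <- oneHotScaffolds(grouped, c("quinazoline", "pyridine"))
  expect_equal(dim(bits), c(nrow(grouped), 2L))
  expect_true(all(rowSums(bits) %in% c(0, 1)))
  expect_identical(rownames(bits), grouped$compound_id)
  expect_equal(sum(bits[, "quinazoline"]),
               sum(grouped$group_id == "quinazoline", na.rm = TRUE))
  expect_error(oneHotScaffolds(grouped, "no_such_scaffold"), "unknown")
})
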