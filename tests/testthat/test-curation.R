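# Curation rules: filtering, pH selection, duplicate merging, task table.

test_that("filterRecords keeps crystalline uncensored records of free bases/acids", {
  recs <- rbind(makeRecord("a", 7, -5),
                makeRecord("a", 7, -5.1, solid = "amorphous"),
                makeRecord("a", 7, -5.2, solid = "unknown"),
                makeRecord("b", 2, -3.3, censored = "above_hi"),
                makeRecord("c", 2, -6))
  cmps <- rbind(makeCompound("a"), makeCompound("b"),
                makeCompound("c", is_salt = TRUE))
  out <- filterRecords(recs, cmps)
  expect_equal(nrow(out), 1)
  expect_equal(out$compound_id, "a")
  expect_equal(nrow(filterRecords(recs[0, ], cmps)), 0)
})

test_that("derivation pH follows the acid/base/ampholyte rules", {
  recs <- rbind(makeRecord("x", 2, -4), makeRecord("x", 7, -4.5))
  cfg <- curationConfig()
  # acid-only -> pH 2
  sel <- selectDerivationRecord(IonizationModel(acidic = 5.1), recs, cfg)
  expect_equal(sel$ph, 2)
  # base-only -> pH 7
  sel <- selectDerivationRecord(IonizationModel(basic = 6), recs, cfg)
  expect_equal(sel$ph, 7)
  # ampholyte with gap 4.5 > 2: midpoint 5.25 is nearer pH 7
  sel <- selectDerivationRecord(IonizationModel(acidic = 7.5, basic = 3.0),
                                recs, cfg)
  expect_equal(sel$action, "derive")
  expect_equal(sel$ph, 7)
  # gap 1.0 <= 2: zwitterion, discarded
  sel <- selectDerivationRecord(IonizationModel(acidic = 5, basic = 4),
                                recs, cfg)
  expect_equal(sel$action, "discard")
  expect_equal(sel$reason, "zwitterion")
  # no pKa: measured value is S0 directly
  sel <- selectDerivationRecord(IonizationModel(), recs, cfg)
  expect_equal(sel$action, "direct")
  expect_equal(nrow(sel$records), 2)
  # required record missing -> discard with reason
  sel <- selectDerivationRecord(IonizationModel(acidic = 5),
                                makeRecord("x", 7, -4.5), cfg)
  expect_equal(sel$action, "discard")
  expect_match(sel$reason, "ph2")
  # more than 3 relevant pKa's at the chosen pH -> discard
  sel <- selectDerivationRecord(IonizationModel(basic = c(8, 8.5, 9, 9.5)),
                                recs, cfg)
  expect_equal(sel$action, "discard")
  expect_equal(sel$reason, "too_many_relevant_pkas")
})

test_that("deriveS0 back-calculates through the speciation model", {
  # base pKa 9 measured at pH 7
  expect_equal(deriveS0(IonizationModel(basic = 9), makeRecord("x", 7, -4)),
               -4 - log10(1 + 100), tolerance = 1e-9)
  # acid pKa 8 measured at pH 2 is essentially unionized; the relevance
  # filter drops the group entirely
  expect_equal(deriveS0(IonizationModel(acidic = 8), makeRecord("x", 2, -5)),
               -5, tolerance = 1e-6)
  expect_equal(deriveS0(IonizationModel(), makeRecord("x", 7, -5.2),
                        direct = TRUE), -5.2)
})

test_that("duplicate rule keeps the smaller solubility under 0.7 log units", {
  expect_equal(mergeDuplicates(c(-5.0, -5.5)), list(value = -5.5, dropped = FALSE))
  expect_true(mergeDuplicates(c(-5.0, -6.0))$dropped)
  expect_equal(mergeDuplicates(-4.2)$value, -4.2)
  # boundary: difference exactly at the threshold drops
  expect_true(mergeDuplicates(c(-5.0, -5.7))$dropped)
  # retained value is never above the smallest input
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(sample(2:4, 1), -5, 0.2)
    m <- mergeDuplicates(v)
    if (!m$dropped) expect_lte(m$value, min(v))
  }
})

test_that("high-quality flag requires crystalline, uncensored, tight replicates", {
  expect_true(flagHighQuality(makeRecord("a", 2, -5, spread = 0.1)))
  expect_false(flagHighQuality(makeRecord("a", 2, -5, spread = 0.9)))
  expect_false(flagHighQuality(makeRecord("a", 2, -5, solid = "amorphous")))
  expect_false(flagHighQuality(makeRecord("a", 2, -5)[0, ]))
})

test_that("task table is an outer union with an exact observation mask", {
  tt <- buildTaskTable(list(
    S0 = data.frame(compound_id = c("a", "b"), value = c(-5, -6),
                    high_quality = c(TRUE, FALSE)),
    logP = data.frame(compound_id = "b", value = 2.5)))
  expect_equal(nrow(taskValues(tt)), 2)
  expect_equal(sum(observedMask(tt)), 3)
  expect_equal(highQuality(tt), c(TRUE, FALSE))
  expect_true(all(is.finite(taskValues(tt)[observedMask(tt)])))
  # compound in no task never appears; duplicate within a task errors
  expect_error(buildTaskTable(list(
    S0 = data.frame(compound_id = c("a", "a"), value = c(-5, -5.1)))),
    "duplicate")
})

test_that("curation pipeline is deterministic and order-invariant", {
  set.seed(21)
  sim <- simulateDataset(generatorConfig(nCompounds = 60, seed = 5))
  a <- curateS0(sim$records, sim$compounds)
  perm <- sample(nrow(sim$records))
  b <- curateS0(sim$records[perm, ], sim$compounds)
  expect_equal(a$s0, b$s0)
  # no zwitterion (gap <= 2) survives curation
  zw <- sim$compounds$compound_id[sim$compounds$class == "zwitterion"]
  expect_length(intersect(a$s0$compound_id, zw), 0)
})

test_that("assay CSV round-trips through the curation dialect", {
  sim <- simulateDataset(generatorConfig(nCompounds = 25, seed = 9))
  path <- tempfile(fileext = ".csv")
  writeAssayCsv(sim, path)
  back <- readAssayCsv(path)
  direct <- curateS0(sim$records, sim$compounds)
  viaCsv <- curateS0(back$records, back$compounds)
  expect_equal(viaCsv$s0$log_s0_molar, direct$s0$log_s0_molar, tolerance = 1e-9)
  # micromolar input converts at the boundary
  p2 <- tempfile(fileext = ".csv")
  df <- utils::read.csv(path)
  df$solubility_uM <- 10^df$log_s_molar * 1e6
  df$log_s_molar <- NULL
  utils::write.csv(df, p2, row.names = FALSE)
  expect_equal(readAssayCsv(p2)$records$log_s, back$records$log_s,
               tolerance = 1e-9)
  expect_error(readAssayCsv({
    p3 <- tempfile(fileext = ".csv")
    utils::write.csv(df[setdiff(names(df), "smiles")], p3, row.names = FALSE)
    p3
  }), "smiles")
})

test_that("task table CSV round-trips including the observation mask", {
  sim <- simulateDataset(generatorConfig(nCompounds = 30, seed = 2))
  cur <- curateS0(sim$records, sim$compounds)
  tt <- buildTaskTable(c(list(S0 = data.frame(
    compound_id = cur$s0$compound_id, value = cur$s0$log_s0_molar,
    high_quality = cur$s0$high_quality)), sim$taskSets))
  path <- tempfile(fileext = ".csv")
  writeTaskTableCsv(tt, path)
  back <- readTaskTableCsv(path)
  expect_equal(observedMask(back), observedMask(tt))
  expect_equal(taskValues(back)[observedMask(back)],
               taskValues(tt)[observedMask(tt)], tolerance = 1e-9)
  expect_equal(highQuality(back), highQuality(tt))
})
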