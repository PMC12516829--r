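# Synthetic-data generator: class structure, censoring, reproducibility,
# and end-to-end recovery through the curation pipeline.

test_that("compound generation respects the class mix exactly", {
  cfg <- generatorConfig(nCompounds = 200, seed = 0,
                         classMix = c(neutral = 0.3, acid = 0.2, base = 0.2,
                                      ampholyte = 0.1, zwitterion = 0.2))
  gen <- generateCompounds(cfg)
  expect_equal(as.vector(table(gen$compounds$class)[c("neutral", "acid", "base",
                                                      "ampholyte", "zwitterion")]),
               c(60L, 40L, 40L, 20L, 40L))
  # neutral compounds carry no pKa's; zwitterions have gap <= 2
  neutral <- gen$compounds[gen$compounds$class == "neutral", ]
  expect_true(all(neutral$acidic_pkas == "" & neutral$basic_pkas == ""))
  zw <- gen$compounds[gen$compounds$class == "zwitterion", ]
  gaps <- vapply(seq_len(nrow(zw)), function(i) {
    m <- compoundIonization(zw[i, ])
    min(acidicPkas(m)) - max(basicPkas(m))
  }, numeric(1))
  expect_true(all(gaps <= 2))
  amp <- gen$compounds[gen$compounds$class == "ampholyte", ]
  gapsA <- vapply(seq_len(nrow(amp)), function(i) {
    m <- compoundIonization(amp[i, ])
    min(acidicPkas(m)) - max(basicPkas(m))
  }, numeric(1))
  expect_true(all(gapsA > 2))
  # reproducibility and structural uniqueness
  gen2 <- generateCompounds(cfg)
  expect_identical(gen, gen2)
  expect_equal(anyDuplicated(gen$compounds$smiles), 0)
  # every generated SMILES parses
  expect_silent(for (s in unique(gen$compounds$smiles)) buildGraph(s))
})

test_that("noise-free measurements lie exactly on the speciation curve", {
  cfg <- generatorConfig(nCompounds = 40, seed = 3, noiseSd = 0,
                         duplicateRate = 0, amorphousRate = 0)
  gen <- generateCompounds(cfg)
  recs <- simulateMeasurements(gen$compounds, gen$trueS0, cfg)
  expect_equal(nrow(recs), 80)   # one record per compound-pH
  for (i in seq_len(nrow(recs))) {
    cmp <- gen$compounds[gen$compounds$compound_id == recs$compound_id[i], ]
    truth <- gen$trueS0[[recs$compound_id[i]]] +
      GraphSol:::.cappedLogPhi(compoundIonization(cmp), recs$ph[i])
    if (recs$censored[i] == "none")
      expect_equal(recs$log_s[i], truth, tolerance = 1e-12)
    expect_equal(recs$replicate_spread[i], 0)
  }
})

test_that("censoring follows the assay dynamic range", {
  cfg <- generatorConfig(nCompounds = 1, seed = 1, noiseSd = 0,
                         classMix = c(neutral = 1, acid = 0, base = 0,
                                      ampholyte = 0, zwitterion = 0))
  gen <- generateCompounds(cfg)
  # a neutral compound with true S0 above the 600 uM ceiling censors high
  recs <- simulateMeasurements(gen$compounds,
                               setNames(-3.0, gen$compounds$compound_id), cfg)
  expect_true(all(recs$censored == "above_hi"))
  expect_equal(unique(recs$log_s), log10(600e-6), tolerance = 1e-12)
  recsLo <- simulateMeasurements(gen$compounds,
                                 setNames(-8.5, gen$compounds$compound_id), cfg)
  expect_true(all(recsLo$censored == "below_lo"))
  # censoring becomes more frequent as true S0 rises toward the ceiling
  frac <- vapply(c(-6, -4.5, -3.4), function(mu) {
    c2 <- generatorConfig(nCompounds = 150, seed = 5, s0Mean = mu, s0Sd = 0.6)
    g <- generateCompounds(c2)
    r <- simulateMeasurements(g$compounds, g$trueS0, c2)
    mean(r$censored != "none")
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("planted task sets hit the configured sparsity exactly", {
  cfg <- generatorConfig(nCompounds = 100, seed = 8)
  sim <- simulateDataset(cfg)
  for (nm in names(cfg$taskSparsity))
    expect_equal(nrow(sim$taskSets[[nm]]),
                 round(100 * cfg$taskSparsity[[nm]]))
  tt <- buildTaskTable(sim$taskSets)
  for (nm in names(cfg$taskSparsity))
    expect_equal(sum(observedMask(tt)[, nm]),
                 round(100 * cfg$taskSparsity[[nm]]))
  # duplicate injection at the configured rate produces extra records
  cfgDup <- generatorConfig(nCompounds = 60, seed = 2, duplicateRate = 1)
  simDup <- simulateDataset(cfgDup)
  expect_equal(nrow(simDup$records), 240)   # two records per compound-pH
})

test_that("curation recovers the generator's truth", {
  # zero noise: exact recovery for every retained compound
  cfg0 <- generatorConfig(nCompounds = 120, seed = 4, noiseSd = 0)
  sim0 <- simulateDataset(cfg0)
  cur0 <- curateS0(sim0$records, sim0$compounds)
  expect_gt(nrow(cur0$s0), 40)
  err <- cur0$s0$log_s0_molar - sim0$trueS0[cur0$s0$compound_id]
  expect_lt(max(abs(err)), 1e-9)
  # with noise, the derived values scatter around truth at about sigma
  cfg1 <- generatorConfig(nCompounds = 300, seed = 6, noiseSd = 0.3)
  sim1 <- simulateDataset(cfg1)
  cur1 <- curateS0(sim1$records, sim1$compounds)
  err1 <- cur1$s0$log_s0_molar - sim1$trueS0[cur1$s0$compound_id]
  expect_lt(sqrt(mean(err1^2)), 1.2 * 0.3)
})
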