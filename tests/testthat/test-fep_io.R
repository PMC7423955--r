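test_that("fepout dialect parses minimal fixtures and rejects malformed input", {
  f <- tempfile(fileext = ".fepout")
  writeLines(c("#NEW FEP WINDOW: LAMBDA SET TO 0.000000 LAMBDA2 0.025000",
               "FepEnergy: 1 0.123456 300.000000"), f)
  w <- parse_fepout(f)
  expect_length(w, 1)
  expect_equal(w[[1]]$lambda_from, 0)
  expect_equal(w[[1]]$lambda_to, 0.025)
  expect_equal(w[[1]]$dU, 0.123456)
  expect_equal(w[[1]]$temperature, 300)

  # stray commentary and blank lines are ignored
  f2 <- tempfile(fileext = ".fepout")
  writeLines(c("# some engine banner", "",
               "#NEW FEP WINDOW: LAMBDA SET TO 0.500000 LAMBDA2 0.750000",
               "ETITLE: irrelevant", "FepEnergy: 10 -1.250000 300.000000 ",
               ""), f2)
  w2 <- parse_fepout(f2)
  expect_equal(w2[[1]]$dU, -1.25)

  f3 <- tempfile()
  writeLines("FepEnergy: 1 0.5 300", f3)
  expect_error(parse_fepout(f3), ":1: data line before any window header")

  f4 <- tempfile()
  writeLines(c("#NEW FEP WINDOW: LAMBDA SET TO 0.000000 LAMBDA2 0.100000",
               "FepEnergy: 1 abc 300"), f4)
  expect_error(parse_fepout(f4), ":2: malformed numeric")

  f5 <- tempfile()
  writeLines(c("#NEW FEP WINDOW: LAMBDA SET TO 0.000000 LAMBDA2 0.100000",
               "FepEnergy: 5 0.1 300", "FepEnergy: 5 0.2 300"), f5)
  expect_error(parse_fepout(f5), "strictly increasing")

  f6 <- tempfile()
  writeLines(c("#NEW FEP WINDOW: LAMBDA SET TO 0.000000 LAMBDA2 0.100000",
               "#NEW FEP WINDOW: LAMBDA SET TO 0.100000 LAMBDA2 0.200000",
               "FepEnergy: 1 0.1 300"), f6)
  expect_warning(parse_fepout(f6), "empty window")
})

test_that("fepout and CSV writers round-trip at 6-decimal precision", {
  tw <- quick_transformation(seed = 101, n_windows = 3, n_steps = 1000)
  ff <- tempfile(fileext = ".fepout")
  fr <- tempfile(fileext = ".fepout")
  write_fepout(tw, ff, "forward")
  write_fepout(tw, fr, "reverse")
  paired <- pair_directions(parse_fepout(ff), parse_fepout(fr))
  expect_length(paired, 3)
  for (i in 1:3) {
    expect_equal(paired[[i]]$lambda_low, round(tw[[i]]$lambda_low, 6))
    expect_equal(paired[[i]]$forward_dU, round(tw[[i]]$forward_dU, 6))
    expect_equal(paired[[i]]$reverse_dU, round(tw[[i]]$reverse_dU, 6))
  }
  # writing the parsed windows again is byte-identical (normal form)
  ff2 <- tempfile()
  write_fepout(paired, ff2, "forward")
  expect_identical(readLines(ff), readLines(ff2))

  cf <- tempfile(fileext = ".csv")
  cr <- tempfile(fileext = ".csv")
  write_window_csv(tw, cf, "forward")
  write_window_csv(tw, cr, "reverse")
  paired_csv <- pair_directions(read_window_csv(cf), read_window_csv(cr))
  expect_equal(paired_csv[[2]]$forward_dU, paired[[2]]$forward_dU)

  # written-then-parsed data give identical estimates to the in-memory
  # pipeline at the serialization precision
  mem <- estimate_transformation(tw)$total
  disk <- estimate_transformation(paired)$total
  expect_equal(disk$value, mem$value, tolerance = 1e-4)
})

test_that("experiment table fixture reproduces the six reference rows", {
  tab <- read_experiment_table()
  expect_equal(nrow(tab), 6)
  expect_equal(tab$ddg_expt_kcal_mol[tab$mutation == "D112E"], 1.01)
  expect_equal(tab$err_expt_kcal_mol[tab$mutation == "D112E"], 0.05)
  expect_equal(tab$ddg_expt_kcal_mol[tab$mutation == "R208K"], -0.01)
  expect_equal(tab$ddg_expt_kcal_mol[tab$mutation == "R211S"], 0.11)
  expect_true(all(tab$direction == "forward"))

  dup <- tempfile(fileext = ".csv")
  writeLines(c("mutation,ddg_expt_kcal_mol,err_expt_kcal_mol,direction",
               "D112E,1.0,0.1,forward", "D112E,2.0,0.1,forward"), dup)
  expect_error(read_experiment_table(dup), "duplicate.*D112E")

  miss <- tempfile(fileext = ".csv")
  writeLines(c("mutation,ddg_expt_kcal_mol", "D112E,1.0"), miss)
  expect_error(read_experiment_table(miss), "missing column")
})

test_that("the manifest pipeline closes the null cycle and is reproducible", {
  # identical apo and holo toy specs: true ddG = 0 for both mutations
  expt <- tempfile(fileext = ".csv")
  writeLines(c("mutation,ddg_expt_kcal_mol,err_expt_kcal_mol,direction",
               "TOY1,0.0,0.01,forward", "TOY2,0.0,0.01,forward"), expt)
  leg <- list(type = "toy_harmonic", k_initial = 1, k_final = 2,
              n_windows = 3, n_steps = 3000)
  manifest <- list(
    temperature = 300, seed = 1234,
    estimator = list(method = "bar", decorrelate = TRUE),
    experiment_table = expt,
    mutations = list(
      list(name = "TOY1", direction = "forward", apo = leg, holo = leg),
      list(name = "TOY2", direction = "forward",
           apo = c(leg, k_final = NULL), holo = c(leg, k_final = NULL))))
  manifest$mutations[[2]]$apo$k_final <- 1.5
  manifest$mutations[[2]]$holo$k_final <- 1.5

  out1 <- tempfile()
  rep1 <- run_pipeline(manifest, out_dir = out1)
  expect_equal(rep1$settings$seed, 1234)
  expect_equal(rep1$settings$temperature, 300)
  # apo and holo legs are sampled independently, so ddG is only
  # statistically zero
  expect_lt(abs(rep1$cycle$ddg[1]), 4 * rep1$cycle$stderr[1])
  expect_lt(rep1$comparison$mae, 0.05)

  out2 <- tempfile()
  rep2 <- run_pipeline(manifest, out_dir = out2)
  expect_identical(readLines(file.path(out1, "cycle_report.csv")),
                   readLines(file.path(out2, "cycle_report.csv")))
  expect_identical(readLines(file.path(out1, "per_window.csv")),
                   readLines(file.path(out2, "per_window.csv")))

  # manifest validation
  broken <- manifest
  broken$temperature <- NULL
  expect_error(run_pipeline(broken), "temperature")
  broken2 <- manifest
  broken2$seed <- NULL
  expect_error(run_pipeline(broken2), "seed")
  broken3 <- manifest
  broken3$mutations[[1]]$apo <- list(type = "fepout",
                                     forward = "/nonexistent/f.fepout",
                                     reverse = "/nonexistent/r.fepout")
  expect_error(run_pipeline(broken3), "nonexistent")
})

test_that("a YAML manifest with fepout legs runs end to end", {
  tw <- quick_transformation(seed = 301, n_windows = 2, n_steps = 2000)
  dirs <- tempfile()
  dir.create(dirs)
  ff <- file.path(dirs, "fwd.fepout")
  fr <- file.path(dirs, "rev.fepout")
  write_fepout(tw, ff, "forward")
  write_fepout(tw, fr, "reverse")
  expt <- file.path(dirs, "expt.csv")
  writeLines(c("mutation,ddg_expt_kcal_mol,err_expt_kcal_mol,direction",
               "TOY,0.0,0.01,forward"), expt)
  mpath <- file.path(dirs, "manifest.yaml")
  yaml::write_yaml(list(
    temperature = 300, seed = 7,
    experiment_table = expt,
    mutations = list(list(
      name = "TOY", direction = "forward",
      apo = list(type = "fepout", forward = ff, reverse = fr),
      holo = list(type = "fepout", forward = ff, reverse = fr)))), mpath)
  rep <- run_pipeline(mpath)
  # same files for both legs: exact cycle closure
  expect_identical(rep$cycle$ddg, 0)
  expect_equal(rep$comparison$mae, 0)
})
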