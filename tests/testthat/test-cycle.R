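test_that("ddg assembles holo minus apo with RSS errors", {
  a <- leg_result("apo", "D112E", fe_estimate(1.0, 0.3, "bar"))
  h <- leg_result("holo", "D112E", fe_estimate(2.0, 0.4, "bar"))
  d <- ddg(a, h)
  expect_equal(d$value, 1.0)
  expect_equal(d$stderr, 0.5)

  same <- ddg(leg_result("apo", "m", fe_estimate(1.3, 0.2, "bar")),
              leg_result("holo", "m", fe_estimate(1.3, 0.2, "bar")))
  expect_equal(same$value, 0)
  expect_equal(same$stderr, sqrt(2) * 0.2)

  expect_error(ddg(a, leg_result("holo", "V178A",
                                 fe_estimate(1, 0.1, "bar"))),
               "mismatched")
  expect_error(ddg(h, a), "apo leg")
})

test_that("cycle closure is exact when both legs share the data", {
  tw <- quick_transformation(seed = 71, n_windows = 3, n_steps = 2000)
  est <- estimate_transformation(tw)$total
  d <- ddg(leg_result("apo", "toy", est), leg_result("holo", "toy", est))
  expect_identical(d$value, 0)
})

test_that("orient flips reversed-direction values and is an involution", {
  expect_equal(orient(1.3, "forward"), 1.3)
  expect_equal(orient(-1.3, "reversed"), 1.3)
  expect_equal(orient(orient(2.7, "reversed"), "reversed"), 2.7)

  d <- list(value = 5.9, stderr = 0.4)
  o <- orient(d, "reversed")
  expect_equal(o$value, -5.9)
  expect_equal(o$stderr, 0.4) # stderr unchanged

  # the packaged S211R reverse-direction values orient to the plotted
  # -1 x S211R convention
  s211r <- read.csv(system.file("extdata", "s211r_reverse_ddg.csv",
                                package = "fepcycle"))
  oriented <- orient(s211r$ddg_calc_kcal_mol[s211r$tautomer == "gbi1"],
                     "reversed")
  expect_equal(oriented, -5.9)
})

test_that("additive corrections shift legs and barely move the ddG", {
  corr <- read_corrections()
  expect_equal(unname(corr["apo"]), -3.1042)
  expect_equal(unname(ddg_correction_shift(corr["apo"], corr["gbi1"])),
               0.0012, tolerance = 1e-12)

  legs <- list(leg_result("apo", "R211S", fe_estimate(10, 0.5, "bar"),
                          system_label = "apo"),
               leg_result("holo", "R211S", fe_estimate(3, 0.5, "bar"),
                          system_label = "gbi1"))
  out <- apply_corrections(legs, corr)
  expect_equal(out$legs[[1]]$estimate$value, 10 - 3.1042)
  expect_equal(out$legs[[2]]$estimate$value, 3 - 3.1030)
  expect_equal(out$legs[[1]]$estimate$stderr, 0.5) # errors untouched
  d0 <- ddg(legs[[1]], legs[[2]])$value
  d1 <- ddg(out$legs[[1]], out$legs[[2]])$value
  expect_equal(d1 - d0, 0.0012, tolerance = 1e-12)

  # equal corrections cancel exactly in the ddG
  eq <- apply_corrections(legs, c(apo = -2, gbi1 = -2))
  expect_equal(ddg(eq$legs[[1]], eq$legs[[2]])$value, d0)

  # zero corrections are the identity
  zero <- apply_corrections(legs, c(apo = 0, gbi1 = 0))
  expect_equal(zero$legs[[1]]$estimate$value, 10)

  # missing label: correction 0 with a warning
  expect_warning(miss <- apply_corrections(legs, c(apo = -1)), "gbi2|gbi1")
  expect_equal(miss$legs[[2]]$estimate$value, 3)
  expect_error(apply_corrections(legs, c(apo = NaN, gbi1 = 0)),
               "non-finite")
})

test_that("uniform additive shifts leave every ddG unchanged", {
  set.seed(81)
  muts <- c("A1B", "C2D", "E3F")
  legs <- unlist(lapply(muts, function(m) {
    list(leg_result("apo", m, fe_estimate(rnorm(1), 0.1, "bar"),
                    system_label = "apo"),
         leg_result("holo", m, fe_estimate(rnorm(1), 0.1, "bar"),
                    system_label = "holo"))
  }), recursive = FALSE)
  shifted <- apply_corrections(legs, c(apo = 4.2, holo = 4.2))
  for (i in seq(1, length(legs), by = 2)) {
    expect_equal(ddg(shifted$legs[[i]], shifted$legs[[i + 1]])$value,
                 ddg(legs[[i]], legs[[i + 1]])$value, tolerance = 1e-12)
  }
})

test_that("fold-change band reproduces the 10-fold threshold", {
  expect_equal(fold_change_threshold(300, 10), 1.3727, tolerance = 1e-4)
  expect_equal(round(fold_change_threshold(300, 10), 1), 1.4)
  expect_equal(fold_change_threshold(300, 1), 0)
  expect_equal(fold_change_threshold(600, 10),
               2 * fold_change_threshold(300, 10))
  expect_error(fold_change_threshold(-300, 10), "temperature")
  expect_error(fold_change_threshold(300, 0), "fold")
})

test_that("comparison against the experimental table yields the MAE", {
  tab <- read_experiment_table()
  calc <- read.csv(system.file("extdata", "hv1_2gbi_computed_ddg.csv",
                               package = "fepcycle"))
  gbi2 <- calc[calc$tautomer == "gbi2", ]
  cmp <- compare_to_experiment(
    data.frame(mutation = gbi2$mutation, ddg = gbi2$ddg_calc_kcal_mol),
    tab)
  expect_equal(cmp$mae_rounded, 2.1)
  expect_equal(cmp$n_included, 6)

  cmp_excl <- compare_to_experiment(
    data.frame(mutation = gbi2$mutation, ddg = gbi2$ddg_calc_kcal_mol),
    tab, exclude = "R211S")
  expect_equal(cmp_excl$mae_rounded, 1.1)
  expect_equal(cmp_excl$n_included, 5)
  # excluding a mutation never increases the summed deviation
  expect_lte(cmp_excl$mae * 5, cmp$mae * 6)

  # perfect agreement: MAE 0, everything within the band
  perfect <- compare_to_experiment(
    data.frame(mutation = tab$mutation, ddg = tab$ddg_expt_kcal_mol), tab)
  expect_equal(perfect$mae, 0)
  expect_true(all(perfect$per_mutation$within_band))

  # permutation invariance
  shuffled <- gbi2[c(4, 1, 6, 3, 2, 5), ]
  cmp_shuf <- compare_to_experiment(
    data.frame(mutation = shuffled$mutation,
               ddg = shuffled$ddg_calc_kcal_mol), tab)
  expect_equal(cmp_shuf$mae, cmp$mae)

  expect_error(compare_to_experiment(
    data.frame(mutation = "Q999X", ddg = 0), tab), "absent")
})
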