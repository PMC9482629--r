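test_that("calibration replicates the benchmark and flags perturbations", {
  mod <- small_model()
  rc <- replication_check(mod)
  expect_lt(rc$max_residual, 1e-8)
  expect_true(rc$pass)
  ## negative control: a corrupted share coefficient breaks replication
  bad <- mod
  bad$theta_L[1, 1] <- bad$theta_L[1, 1] * 1.05
  expect_false(replication_check(bad)$pass)
  ## deterministic report
  expect_identical(replication_check(mod), replication_check(mod))
})

test_that("calibrated share coefficients equal benchmark value shares", {
  mod <- small_model()
  w <- small_world()
  fl <- extract_flows(w$sam, w$config)
  vva <- fl$V_lab + fl$V_cap
  for (j in mod$sn) for (r in mod$regions) {
    cid <- w$sam$cells$cell_id[w$sam$cells$region == r]
    vva[j, r] <- vva[j, r] + sum(fl$V_land[j, cid, ])
  }
  expect_equal(mod$theta_L, fl$V_lab / vva, tolerance = 1e-10)
  expect_equal(rowSums(cbind(as.numeric(mod$theta_L),
                             as.numeric(mod$theta_K),
                             as.numeric(mod$theta_T))),
               rep(1, length(mod$theta_L)), tolerance = 1e-10)
})

test_that("Cobb-Douglas value shares are invariant to prices", {
  ## closed-form property of the sigma = 1 limit used for non-land sectors
  shares <- c(L = 0.6, K = 0.4)
  for (p in list(c(1, 1), c(2, 0.5), c(1.3, 3))) {
    idx <- ces_price(p, shares, 1)
    dem <- shares / p * idx   # unit-cost-share demands
    expect_equal(p * dem / idx, shares, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("the two-region exchange toy matches its closed form", {
  toy <- toy_exchange()
  expect_lt(replication_check(toy$model)$max_residual, 1e-10)
  eq <- solve_equilibrium(toy$model,
                          list(endow_growth = rbind(LAB = c(A = 1.2, B = 1))))
  ## Cobb-Douglas exchange: fixed expenditure shares give
  ## 0.3 pA qA = 0.375 pB qB with qA = 1.2 qA0, qB = qB0, wage A = 1
  expect_equal(as.numeric(eq$phat), c(1, 1.2), tolerance = 1e-8)
  expect_equal(as.numeric(eq$qhat), c(1.2, 1), tolerance = 1e-8)
  expect_equal(as.numeric(eq$wL), c(1, 1.2), tolerance = 1e-8)
})

test_that("zero shocks return the benchmark and nominal rescaling is neutral", {
  mod <- small_model()
  eq0 <- solve_equilibrium(mod)
  expect_lt(max(abs(eq0$phat - 1)), 1e-8)
  expect_lt(max(abs(eq0$qhat - 1)), 1e-8)
  ## homogeneity: doubling the numeraire doubles prices, leaves quantities
  dr <- default_drivers(small_world()$config)
  eq1 <- solve_equilibrium(mod, dr)
  dr2 <- dr; dr2$numeraire <- 2
  eq2 <- solve_equilibrium(mod, dr2)
  expect_equal(eq2$phat, 2 * eq1$phat, tolerance = 1e-6)
  expect_equal(eq2$qhat, eq1$qhat, tolerance = 1e-6)
  expect_equal(eq2$land$area, eq1$land$area, tolerance = 1e-6)
})

test_that("solved equilibria satisfy Walras' law and land adding-up", {
  prep <- asm_prep()
  for (eq in list(prep$baseline, asm_run()$counterfactual)) {
    expect_lt(eq$walras, 1e-8)
    expect_lt(eq$residual_max, 1e-9)
    ## per cell: leaf areas sum to the fixed cell total
    tot <- tapply(eq$land$area, eq$land$cell_id, sum)
    tot0 <- tapply(eq$land$area_benchmark, eq$land$cell_id, sum)
    expect_lt(max(abs(tot - tot0) / tot0), 1e-6)
  }
})

test_that("the medium-run baseline clears forest in the policy country", {
  prep <- asm_prep()
  l <- prep$baseline$land
  bra_forest <- l$region == "BRA" & l$cover == "forest"
  expect_lt(sum(l$area[bra_forest] - l$area_benchmark[bra_forest]), 0)
  ## cropland expands under the oilseed-demand drivers
  bra_osd <- l$region == "BRA" & l$cover == "crop_osd"
  expect_gt(sum(l$area[bra_osd] - l$area_benchmark[bra_osd]), 0)
})

test_that("the conversion freeze binds exactly with nonnegative subsidies", {
  run <- asm_run()
  covered <- run$covered_cells
  expect_gt(length(covered), 0)
  cf <- run$counterfactual
  frozen <- cf$land[cf$land$cell_id %in% covered & cf$land$cover == "forest", ]
  expect_equal(frozen$area, frozen$area_benchmark, tolerance = 0)
  expect_true(all(cf$subsidy[covered] >= 0))
  ## constraint swap leaves uncovered cells priced by the market
  expect_true(all(is.na(cf$subsidy[setdiff(names(cf$subsidy), covered)])))
  ## definition B freezes grassland too, outside the Amazon
  w <- small_world()
  cfB <- run_counterfactual(run$model, default_drivers(w$config), covered,
                            "B")
  frozenB <- cfB$land[cfB$land$cell_id %in% covered &
                        cfB$land$cover %in% c("forest", "grass"), ]
  expect_equal(frozenB$area, frozenB$area_benchmark, tolerance = 0)
})

test_that("an empty footprint leaves the solution unchanged", {
  prep <- asm_prep()
  w <- small_world()
  cf <- run_counterfactual(prep$model, default_drivers(w$config),
                           character(0), "A")
  expect_equal(cf$phat, prep$baseline$phat, tolerance = 1e-9)
  expect_equal(cf$land$area, prep$baseline$land$area, tolerance = 1e-6)
  expect_error(apply_zdsp(prep$model, "no.such.cell"), "absent")
})

test_that("freezing conversion raises covered-cell agricultural rents", {
  run <- asm_run()
  covered <- run$covered_cells
  for (v in c("crop_osd", "pasture")) {
    expect_true(all(run$counterfactual$rho[covered, v] >=
                      run$baseline$rho[covered, v] - 1e-10))
  }
  ## and weakly raises the policy country's producer price of oilseeds
  expect_gte(run$counterfactual$phat["osd", "BRA"],
             run$baseline$phat["osd", "BRA"] - 1e-10)
})

test_that("land-change tables partition exactly and reject mismatches", {
  run <- asm_run()
  lct <- run$land_change
  s <- lct$summary
  expect_identical(s$delta_global, s$delta_zdsp + s$delta_no_zdsp)
  expect_identical(s$delta_no_zdsp,
                   s$delta_no_zdsp_domestic + s$delta_no_zdsp_foreign)
  ## identical equilibria give an all-zero table
  z <- diff_land(run$baseline, run$baseline, run$covered_cells, "BRA")
  expect_true(all(z$deltas$delta_ha == 0))
  expect_equal(z$summary$delta_global, 0)
  ## hand-built 2-cell partition
  mk_eq <- function(areas) {
    structure(list(land = data.frame(
      cell_id = c("BRA.X.ZDC", "BRA.Y.NoZDC"), region = "BRA",
      cover = "forest", area_benchmark = c(100, 100), area = areas,
      stringsAsFactors = FALSE)), class = "soy_equilibrium")
  }
  lct2 <- diff_land(mk_eq(c(100, 90)), mk_eq(c(100, 85)), "BRA.X.ZDC", "BRA")
  expect_equal(lct2$summary$delta_zdsp, 0)
  expect_equal(lct2$summary$delta_no_zdsp_domestic, -5)
  expect_equal(lct2$summary$delta_global, -5)
  bad <- mk_eq(c(1, 2)); bad$land <- bad$land[2:1, ]
  expect_error(diff_land(mk_eq(c(1, 2)), bad, "BRA.X.ZDC", "BRA"),
               "mismatched")
})

test_that("solver failures surface as errors with diagnostics", {
  mod <- small_model()
  expect_error(
    solve_equilibrium(mod, default_drivers(small_world()$config),
                      control = list(max_iter = 2)),
    "failed to converge")
})
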