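one_cell <- data.frame(cell_id = "X", biome = "Amazon",
                       stringsAsFactors = FALSE)

stocks <- function(forest = c(0, 0, 0), cropland = c(0, 0, 0),
                   other = c(0, 0, 0)) {
  cov <- ef_cover_classes
  out <- data.frame(cell_id = "X", cover = cov,
                    biomass_tC_ha = other[1], dom_tC_ha = other[2],
                    soil_tC_ha = other[3], stringsAsFactors = FALSE)
  out[out$cover == "forest", 3:5] <- as.list(forest)
  out[out$cover == "cropland", 3:5] <- as.list(cropland)
  out
}

bare <- function() {
  a <- default_ef_assumptions()
  a$wood_product_frac <- 0; a$nonco2_frac <- 0; a$foregone_seq_tco2_ha <- 0
  a$symmetric <- TRUE
  a
}

test_that("zero stocks give an all-zero factor matrix", {
  ef <- build_ef_matrix(stocks(), bare())
  expect_true(all(ef$total == 0))
})

test_that("stock differences convert stoichiometrically to CO2e", {
  ef <- build_ef_matrix(stocks(forest = c(100, 0, 0),
                               cropland = c(10, 0, 0)), bare())
  expect_equal(ef$total["X", "forest", "cropland"], (100 - 10) * 44 / 12)
  expect_equal(ef$total["X", "cropland", "forest"], -(100 - 10) * 44 / 12)
  expect_true(all(diag(ef$total["X", , ]) == 0))
  expect_error(build_ef_matrix(stocks(forest = c(-1, 0, 0))), "negative")
})

test_that("component factors sum to the total for arbitrary stocks", {
  cells <- small_world()$sam$cells
  st <- default_carbon_stocks(cells)
  ef <- build_ef_matrix(st)
  expect_equal(Reduce(`+`, ef$components), ef$total, tolerance = 1e-12)
  ## asymmetric default: regrowth credited at a discount
  expect_lt(abs(ef$total[1, "cropland", "forest"]),
            abs(ef$total[1, "forest", "cropland"]))
})

mk_lct <- function(delta_forest_ha, cell = "X", region = "BRA") {
  deltas <- data.frame(
    cell_id = cell, region = region,
    cover = c("forest", "cropland"),
    delta_ha = c(delta_forest_ha, -delta_forest_ha),
    stringsAsFactors = FALSE)
  structure(list(deltas = deltas,
                 forest = transform(deltas[1, ], category = "ZDSP"),
                 summary = list(delta_zdsp = delta_forest_ha,
                                delta_no_zdsp = 0,
                                delta_global = delta_forest_ha),
                 policy_region = region, footprint_cells = cell),
            class = "land_change_table")
}

test_that("emission deltas are factor times transition area", {
  ## 10 kha cleared at 300 t CO2e/ha -> 3,000 kt emitted
  ef <- build_ef_matrix(stocks(forest = c(300 / (44 / 12), 0, 0)), bare())
  em <- emissions_from_deltas(mk_lct(-10e3), ef)
  expect_equal(em$global_kt, 10e3 * 300 / 1e3, tolerance = 1e-9)
  ## avoided deforestation is a saving (negative delta)
  em2 <- emissions_from_deltas(mk_lct(+10e3), ef)
  expect_equal(em2$global_kt, -3000, tolerance = 1e-9)
  ## zero deltas -> zero report
  em0 <- emissions_from_deltas(mk_lct(0), ef)
  expect_equal(em0$global_kt, 0)
})

test_that("the report is linear in the deltas and additive over regions", {
  run <- asm_run()
  ef <- build_ef_matrix(default_carbon_stocks(asm_prep()$split$cells))
  em1 <- emissions_from_deltas(run$land_change, ef)
  expect_equal(em1$global_kt, sum(em1$by_region_kt), tolerance = 1e-10)
  expect_equal(sum(em1$components_kt), em1$global_kt, tolerance = 1e-8)
  lct2 <- run$land_change
  lct2$deltas$delta_ha <- 2 * lct2$deltas$delta_ha
  em2 <- emissions_from_deltas(lct2, ef)
  expect_equal(em2$global_kt, 2 * em1$global_kt, tolerance = 1e-9)
  ## net global avoided deforestation in the ASM run saves emissions
  expect_gt(run$leakage$net_global_kha, 0)
  expect_lt(em1$global_kt, 0)
})

test_that("unmapped covers and missing cells raise errors", {
  ef <- build_ef_matrix(stocks(), bare())
  bad <- mk_lct(-10)
  bad$deltas$cover[2] <- "wetland"
  expect_error(emissions_from_deltas(bad, ef), "unmapped cover")
  bad2 <- mk_lct(-10, cell = "Y")
  expect_error(emissions_from_deltas(bad2, ef), "does not cover")
})
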