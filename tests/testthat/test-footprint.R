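mk_exports <- function(volumes, companies = names(volumes)) {
  data.frame(muni_id = "M1", company_id = companies,
             destination = "China", volume_t = as.numeric(volumes),
             stringsAsFactors = FALSE)
}

test_that("committed market share is committed volume over total volume", {
  e <- mk_exports(c(A = 50, B = 30, C = 20))
  expect_equal(committed_share(e, c("A", "B")), 0.80)
  expect_equal(committed_share(e, character(0)), 0)
  expect_equal(committed_share(e, c("A", "B", "C")), 1)
  expect_true(is.na(committed_share(mk_exports(c(A = 0)), "A")))
})

test_that("threshold classification uses inclusive bounds except gt0", {
  expect_true(classify_municipality(0.80, "ge75"))
  expect_true(classify_municipality(0.50, "ge50"))  # boundary inclusive
  expect_true(classify_municipality(0.75, "ge75"))
  expect_false(classify_municipality(0.7499, "ge75"))
  expect_false(classify_municipality(0.0, "gt0"))
  expect_true(classify_municipality(1e-9, "gt0"))
  expect_false(classify_municipality(NA_real_, "gt0"))
})

test_that("destination rules commit a company's entire supply chain", {
  ex <- data.frame(
    muni_id = c("M1", "M1", "M2"),
    company_id = c("X", "X", "Y"),
    destination = c("EU", "China", "China"),
    volume_t = c(1, 999, 500), stringsAsFactors = FALSE)
  co <- data.frame(company_id = c("X", "Y"), asm_member = c(TRUE, FALSE),
                   global_zdc = c(FALSE, FALSE), stringsAsFactors = FALSE)
  ## one tonne to the EU is enough: the whole chain is covered
  expect_equal(resolve_scenario_companies(scenario_spec("EU"), ex, co), "X")
  expect_setequal(resolve_scenario_companies(scenario_spec("China"), ex, co),
                  c("X", "Y"))
  expect_setequal(
    resolve_scenario_companies(scenario_spec("EU_and_China"), ex, co),
    union(resolve_scenario_companies(scenario_spec("EU"), ex, co),
          resolve_scenario_companies(scenario_spec("China"), ex, co)))
  ## no exports to a destination -> empty committed set
  ex2 <- ex[ex$destination == "China", ]
  expect_length(resolve_scenario_companies(scenario_spec("EU"), ex2, co), 0)
})

test_that("cell assignment follows largest-AEZ and biome stringency rules", {
  got <- assign_cell(c(AEZ5 = 0.7, AEZ6 = 0.3), c(Amazon = 1))
  expect_equal(got$aez_id, "AEZ5")
  ## biome priority beats intersection area
  got <- assign_cell(c(AEZ5 = 1), c(Amazon = 0.2, Cerrado = 0.8))
  expect_equal(got$biome, "Amazon")
  got <- assign_cell(c(AEZ5 = 1), c(Cerrado = 0.3, Other = 0.7))
  expect_equal(got$biome, "Cerrado")
  got <- assign_cell(c(AEZ2 = 1), c(Other = 1))
  expect_equal(got$biome, "Other")
  expect_error(assign_cell(numeric(0), numeric(0)), "no candidate")
})

test_that("forest definitions restrict the intended covers", {
  m <- data.frame(biome = c("Amazon", "Cerrado", "Other"),
                  forest_A_ha = c(100, 50, 60),
                  forest_B_ha = c(100, 80, 90), stringsAsFactors = FALSE)
  expect_equal(apply_forest_definition(m, "A"), c(100, 50, 60))
  expect_equal(apply_forest_definition(m, "B"), c(100, 80, 90))
  expect_equal(apply_forest_definition(m[1, ], "B"), 100)  # Amazon: B == A
})

test_that("compliant sets nest across thresholds and scenarios", {
  w <- small_world()
  for (sc in c("ASM", "GlobalZDC", "EU", "China", "EU_and_China")) {
    flags <- lapply(c("gt0", "ge50", "ge75"), function(th) {
      cm <- build_compliance_map(w$municipalities, w$trader_exports,
                                 w$companies, scenario_spec(sc, th))
      cm$compliant
    })
    expect_true(all(!flags[[3]] | flags[[2]]))  # ge75 subset of ge50
    expect_true(all(!flags[[2]] | flags[[1]]))  # ge50 subset of gt0
  }
  ## ASM (Amazon-only) is contained in every wider scenario
  asm <- build_compliance_map(w$municipalities, w$trader_exports,
                              w$companies, scenario_spec("ASM", "ge50"))
  for (sc in c("GlobalZDC", "EU", "China", "EU_and_China")) {
    wide <- build_compliance_map(w$municipalities, w$trader_exports,
                                 w$companies, scenario_spec(sc, "ge50"))
    expect_true(all(!asm$compliant | wide$compliant))
  }
  ## ASM never flags municipalities outside the Amazon
  expect_true(all(w$municipalities$biome[asm$compliant] == "Amazon"))
})

test_that("account splitting conserves every national total", {
  w <- small_world()
  cm <- asm_prep()$compliance
  split <- asm_prep()$split
  unsplit <- w$sam
  for (col in grep("^area_", names(unsplit$cells), value = TRUE)) {
    for (r in w$config$regions) {
      expect_equal(sum(split$cells[split$cells$region == r, col]),
                   sum(unsplit$cells[unsplit$cells$region == r, col]),
                   tolerance = 1e-12)
    }
  }
  ## SAM national aggregates unchanged by the split
  f1 <- extract_flows(unsplit, w$config)
  f2 <- extract_flows(split, w$config)
  expect_equal(f2$V_out, f1$V_out, tolerance = 1e-9)
  expect_equal(f2$V_hh, f1$V_hh, tolerance = 1e-9)
  expect_equal(apply(f2$V_land, 1, sum), apply(f1$V_land, 1, sum),
               tolerance = 1e-9)
})

test_that("a hand-built world splits into the enumerated cells", {
  munis <- data.frame(
    muni_id = paste0("M", 1:5),
    biome = c("Amazon", "Amazon", "Cerrado", "Cerrado", "Other"),
    aez_id = c(1L, 1L, 1L, 2L, 1L),
    forest_A_ha = c(10, 20, 5, 8, 4) * 1000,
    forest_B_ha = c(10, 20, 8, 12, 6) * 1000,
    other_natural_ha = c(2, 3, 6, 8, 5) * 1000,
    grassland_ha = c(0, 0, 3, 4, 2) * 1000,
    cropland_ha = c(5, 6, 7, 8, 9) * 1000,
    pasture_ha = c(4, 5, 6, 7, 8) * 1000,
    soy_area_ha = c(2, 3, 4, 5, 6) * 1000,
    soy_production_t = c(6, 9, 12, 15, 18) * 1000,
    maize2_area_ha = c(1, 1, 2, 2, 3) * 1000,
    cattle_heads = c(4, 5, 6, 7, 8) * 1000,
    stringsAsFactors = FALSE)
  cfg <- small_config()
  flag <- c(M1 = TRUE, M2 = FALSE, M3 = TRUE, M4 = FALSE, M5 = FALSE)
  cl <- aggregate_cells(munis, cfg, compliance = flag)
  bra <- cl$cells[cl$cells$region == "BRA", ]
  ## hand enumeration: M1 -> Amazon.AEZ1.ZDC, M2 -> Amazon.AEZ1.NoZDC,
  ## M3 -> Cerrado.AEZ1.ZDC, M4 -> Cerrado.AEZ2.NoZDC, M5 -> Other.AEZ1.NoZDC
  expect_setequal(bra$cell_id, c(
    "BRA.Amazon.AEZ1.ZDC", "BRA.Amazon.AEZ1.NoZDC", "BRA.Cerrado.AEZ1.ZDC",
    "BRA.Cerrado.AEZ2.NoZDC", "BRA.Other.AEZ1.NoZDC"))
  expect_equal(bra["BRA.Amazon.AEZ1.ZDC", "area_forest"], 10000)
  expect_equal(bra["BRA.Amazon.AEZ1.NoZDC", "area_forest"], 20000)
  expect_equal(bra["BRA.Cerrado.AEZ1.ZDC", "area_grass"], 3000)
  expect_equal(bra["BRA.Cerrado.AEZ2.NoZDC", "area_pasture"], 7000)
  expect_equal(bra["BRA.Other.AEZ1.NoZDC", "area_crop_osd"], 6000)
  ## two municipalities in one cell are summed
  cl2 <- aggregate_cells(munis, cfg, compliance = c(M1 = TRUE, M2 = TRUE,
                                                    M3 = FALSE, M4 = FALSE,
                                                    M5 = FALSE))
  expect_equal(cl2$cells["BRA.Amazon.AEZ1.ZDC", "area_forest"], 30000)
})

test_that("coverage statistics match hand computation and the limit cases", {
  munis <- data.frame(
    muni_id = paste0("M", 1:4), biome = rep("Cerrado", 4), aez_id = 1L,
    forest_A_ha = c(10, 20, 30, 40), forest_B_ha = c(10, 20, 30, 40),
    other_natural_ha = 0, grassland_ha = 0,
    cropland_ha = c(100, 100, 200, 0), pasture_ha = c(50, 0, 50, 100),
    soy_area_ha = c(80, 20, 100, 0), soy_production_t = c(1, 1, 1, 0),
    maize2_area_ha = 0, cattle_heads = 1, stringsAsFactors = FALSE)
  cm <- data.frame(muni_id = munis$muni_id,
                   share = c(1, 0, 1, 0),
                   compliant = c(TRUE, FALSE, TRUE, FALSE))
  cov <- coverage_stats(munis, cm)
  expect_equal(unname(cov["soy_area"]), (80 + 100) / 200)
  expect_equal(unname(cov["cropland"]), (100 + 200) / 400)
  expect_equal(unname(cov["pasture"]), (50 + 50) / 200)
  expect_equal(unname(cov["forest"]), (10 + 30) / 100)
  cm$compliant <- TRUE
  expect_equal(unname(coverage_stats(munis, cm)), rep(1, 4))
  cm$compliant <- FALSE
  expect_equal(unname(coverage_stats(munis, cm)), rep(0, 4))
})

test_that("shipped company rosters load and nest correctly", {
  ro <- company_rosters()
  expect_gt(length(ro$asm), 20)
  expect_true(all(c("ADM", "Bunge", "Cargill", "Amaggi") %in% ro$asm))
  ## global pledgers are signatories, save for one newcomer
  expect_lte(length(setdiff(ro$global_zdc, ro$asm)), 1)
})

test_that("the scenario grid enumerates 30 distinct runs", {
  g <- scenario_grid()
  expect_equal(nrow(g), 30)
  expect_equal(nrow(unique(g)), 30)
  expect_setequal(unique(g$scenario),
                  c("ASM", "GlobalZDC", "EU", "China", "EU_and_China"))
})
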