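test_that("municipality tables satisfy their structural invariants", {
  m <- generate_municipalities(small_config())
  expect_equal(nrow(m), 30)
  expect_setequal(unique(m$biome), c("Amazon", "Cerrado", "Other"))
  areas <- m[, c("forest_A_ha", "forest_B_ha", "other_natural_ha",
                 "cropland_ha", "pasture_ha", "soy_area_ha",
                 "soy_production_t", "maize2_area_ha", "cattle_heads")]
  expect_true(all(areas >= 0))
  expect_true(all(m$soy_area_ha <= m$cropland_ha + 1e-9))
  expect_true(all(m$maize2_area_ha <= m$soy_area_ha + 1e-9))
  ## definition-B rule: no grassland increment inside the Amazon
  amz <- m$biome == "Amazon"
  expect_equal(m$forest_B_ha[amz], m$forest_A_ha[amz])
  expect_true(all(m$forest_B_ha[!amz] >= m$forest_A_ha[!amz]))
  expect_equal(m$forest_B_ha, m$forest_A_ha + m$grassland_ha)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 7L)
  expect_identical(generate_municipalities(cfg), generate_municipalities(cfg))
  expect_identical(generate_companies(cfg), generate_companies(cfg))
  m <- generate_municipalities(cfg)
  expect_identical(generate_trader_exports(m, cfg),
                   generate_trader_exports(m, cfg))
  s1 <- generate_sam(cfg, m); s2 <- generate_sam(cfg, m)
  expect_identical(s1$sam, s2$sam)
})

test_that("trader exports respect the per-municipality production cap", {
  w <- small_world()
  v <- tapply(w$trader_exports$volume_t, w$trader_exports$muni_id, sum)
  cap <- w$municipalities$soy_production_t[match(names(v),
                                                 w$municipalities$muni_id)]
  expect_true(all(v <= cap + 1e-6))
  expect_true(all(w$trader_exports$volume_t > 0))
  expect_error(generate_trader_exports(w$municipalities, w$config,
                                       w$companies[0, ]), "empty")
})

test_that("full segmentation sends each company to a single destination", {
  cfg <- small_config(seed = 3L, destination_segmentation = 1)
  co <- generate_companies(cfg)
  ndest <- rowSums(as.matrix(co[, c("w_EU", "w_China", "w_OtherDest")]) > 0)
  expect_true(all(ndest == 1))
  ex <- generate_trader_exports(generate_municipalities(cfg), cfg, co)
  per_co <- tapply(ex$destination, ex$company_id,
                   function(x) length(unique(x)))
  expect_true(all(per_co == 1))
})

test_that("segmented worlds concentrate soy trade on the main destinations", {
  cfg <- world_config(seed = 2L, destination_segmentation = 1)
  w <- generate_world(cfg)
  fl <- extract_flows(w$sam, cfg)
  bra <- fl$V_src["osd", "BRA", ]; bra["BRA"] <- 0
  bap <- fl$V_src["osd", "BAP", ]; bap["BAP"] <- 0
  expect_gt(bra["CHNROW"] / sum(bra), 0.9)
  expect_gt(bap["EU"] / sum(bap), 0.9)
})

test_that("the generated SAM balances and encodes a micro-consistent benchmark", {
  w <- small_world()
  expect_lt(sam_imbalance(w$sam), 1e-8)
  fl <- extract_flows(w$sam, w$config)
  ## zero profit: output value equals total cost, activity by activity
  landtot <- fl$V_out * 0
  for (j in rownames(fl$V_out)) for (r in colnames(fl$V_out)) {
    cid <- w$sam$cells$cell_id[w$sam$cells$region == r]
    landtot[j, r] <- sum(fl$V_land[j, cid, ])
  }
  cost <- apply(fl$V_int, c(2, 3), sum) + fl$V_lab + fl$V_cap + landtot
  expect_lt(max(abs(cost - fl$V_out) / fl$V_out), 1e-7)
  ## market clearing in benchmark values
  sales <- apply(fl$V_src, c(1, 2), sum)
  expect_lt(max(abs(sales - fl$V_out) / fl$V_out), 1e-10)
  ## all land rents nonnegative, and land payments by cell sum to the
  ## national land payment
  expect_true(all(fl$V_land >= 0))
  for (r in w$config$regions) {
    cid <- w$sam$cells$cell_id[w$sam$cells$region == r]
    expect_equal(sum(fl$V_land[, cid, ]), sum(landtot[, r]))
  }
})

test_that("scaling the economy scales the balanced SAM linearly", {
  cfg1 <- small_config(seed = 5L)
  cfg2 <- small_config(seed = 5L)
  cfg2$region_scale <- cfg1$region_scale * 2
  m <- generate_municipalities(cfg1)
  s1 <- generate_sam(cfg1, m)
  s2 <- generate_sam(cfg2, m)
  expect_equal(2 * s1$sam, s2$sam, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("worlds round-trip through the CSV/YAML directory format", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(all(file.exists(file.path(dir,
    c("municipalities.csv", "companies.csv", "trader_exports.csv",
      "land_cells.csv", "sam.csv", "config.yaml")))))
  w2 <- read_world(dir)
  expect_equal(w2$municipalities$forest_A_ha, w$municipalities$forest_A_ha)
  expect_equal(w2$sam$sam, w$sam$sam, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(w2$config$elasticities$sigma_nat,
               w$config$elasticities$sigma_nat)
  ## a re-read world calibrates to the same benchmark
  mod2 <- calibrate(w2$sam, w2$config)
  expect_lt(replication_check(mod2)$max_residual, 1e-7)
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(regions = "BRA"), class = "soyshift_config_error")
  expect_error(world_config(destination_segmentation = 1.2),
               class = "soyshift_config_error")
  expect_error(world_config(n_municipalities = 1),
               class = "soyshift_config_error")
  expect_error(generate_municipalities(list()),
               class = "soyshift_config_error")
})
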