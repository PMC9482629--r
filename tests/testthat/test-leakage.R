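test_that("leakage rates follow the displaced-over-avoided definition", {
  ## displaced 215 kha against 409 kha gross avoided
  expect_equal(leakage_rate(215, -409), 215 / 409 * 100)
  expect_equal(round(leakage_rate(215, -409)), 53)
  expect_equal(leakage_rate(0, -409), 0)
  ## 13 kha displaced abroad against 409 avoided: just above 3 percent
  r <- leakage_rate(2 + 11, -409)
  expect_gt(r, 3); expect_lt(r, 4)
  expect_warning(out <- leakage_rate(10, 0), "undefined")
  expect_true(is.na(out))
})

test_that("leakage rates are invariant to the area unit", {
  expect_equal(leakage_rate(215, -409), leakage_rate(215e3, -409e3))
})

test_that("reports decompose consistently on simulated runs", {
  run <- asm_run()
  lr <- run$leakage
  expect_equal(lr$net_country_kha,
               lr$gross_avoided_kha - lr$displaced_domestic_kha)
  expect_equal(lr$net_global_kha,
               lr$gross_avoided_kha - lr$displaced_domestic_kha -
                 lr$displaced_crossborder_kha)
  expect_equal(lr$displaced_crossborder_kha,
               lr$displaced_bap_kha + lr$displaced_row_kha)
  expect_equal(lr$domestic_leakage_rate_pct,
               lr$displaced_domestic_kha / abs(lr$gross_avoided_kha) * 100)
  ## all-zero table -> all-zero report
  z <- diff_land(run$baseline, run$baseline, run$covered_cells, "BRA")
  zr <- build_report(z, "BAP")
  expect_equal(zr$gross_avoided_kha, 0)
  expect_equal(zr$net_global_kha, 0)
  expect_true(is.na(zr$domestic_leakage_rate_pct))
})

test_that("the printed-values fixture loads with its expected schema", {
  fx <- published_values()
  expect_true(all(c("quantity", "scenario", "value", "unit", "flag") %in%
                    names(fx)))
  expect_false(any(duplicated(fx$quantity)))
  ## the internally inconsistent quantity is flagged and excluded
  expect_equal(fx$flag[fx$quantity == "amazon_cerrado_net_asm_kha"],
               "ambiguous")
  expect_equal(fx$flag[fx$quantity == "asm_bap_displaced_kha"],
               "upper_bound")
})

test_that("every recomputed headline quantity matches its printed value", {
  v <- verify_printed_arithmetic()
  expect_true(all(v$pass))
  expect_true(attr(v, "all_pass"))
  ## spot checks of the recomputation itself
  expect_equal(v$computed[v$check == "asm_annual_avoided"], 409 / 5)
  expect_equal(v$computed[v$check == "asm_domestic_leakage"],
               (409 - 194) / 409 * 100)
  expect_false("amazon_cerrado_net_asm" %in% v$check)
  ## schema violations are caught
  fx <- published_values()
  expect_error(verify_printed_arithmetic(fx[fx$scenario != "reference", ]),
               "fixture schema")
})
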