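test_that("a grid subset runs, summarises and reproduces exactly", {
  w <- small_world()
  g <- scenario_grid()
  sub <- g[g$scenario == "ASM" & g$forest_definition == "A", ]
  gr1 <- run_grid(w, grid = sub)
  expect_equal(nrow(gr1$summary), 3)
  expect_true(all(gr1$summary$converged))
  ## tabulated net equals gross minus displaced on every row
  s <- gr1$summary
  expect_equal(s$net_global_kha,
               s$gross_avoided_kha - s$displaced_domestic_kha -
                 s$displaced_crossborder_kha, tolerance = 1e-10)
  ## re-running from the same world and manifest seed is byte-identical
  gr2 <- run_grid(w, grid = sub)
  expect_equal(gr1$summary, gr2$summary, tolerance = 1e-12)
  expect_identical(gr1$manifest$config_hash, gr2$manifest$config_hash)
})

test_that("a single-draw sweep at unit multipliers equals the default run", {
  w <- small_world()
  sw <- sensitivity_sweep(
    w, sw = sweep_spec(n = 1, seed = 1,
                       ranges = list(sigma_nat = c(1, 1),
                                     sigma_agpast = c(1, 1),
                                     sigma_crop = c(1, 1),
                                     armington = c(1, 1))))
  run <- asm_run()
  expect_equal(sw$draws$gross_avoided_kha, run$leakage$gross_avoided_kha,
               tolerance = 1e-8)
  expect_equal(sw$draws$domestic_leakage_rate_pct,
               run$leakage$domestic_leakage_rate_pct, tolerance = 1e-6)
  ## fixed seed reproduces the whole distribution
  spec2 <- sweep_spec(n = 3, seed = 11)
  s1 <- sensitivity_sweep(w, sw = spec2)
  s2 <- sensitivity_sweep(w, sw = spec2)
  expect_equal(s1$draws, s2$draws, tolerance = 1e-12)
  expect_error(sweep_spec(n = 0), "count")
  expect_error(sweep_spec(ranges = list(sigma_nat = c(2, 1))), "range")
})

test_that("report writing emits tables, manifest and figure", {
  w <- small_world()
  g <- scenario_grid()
  gr <- run_grid(w, grid = g[g$scenario == "ASM" &
                               g$forest_definition == "A", ])
  dir <- withr::local_tempdir()
  report_runs(gr, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "summary_rounded.csv")))
  expect_true(file.exists(file.path(dir, "net_global_by_scenario.pdf")))
  rounded <- utils::read.csv(file.path(dir, "summary_rounded.csv"))
  expect_true(all(rounded$domestic_leakage_rate_pct ==
                    round(rounded$domestic_leakage_rate_pct)))
  expect_error(report_runs(structure(list(summary = NULL), class = "soy_grid"),
                           dir), "no completed runs")
})
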