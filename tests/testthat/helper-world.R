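## Shared fixtures, generated in code and memoized per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_config <- function(seed = 1L, ...) {
  world_config(n_municipalities = 30L, n_companies = 8L, seed = seed, ...)
}

small_world <- function() memo("small_world", generate_world(small_config()))

small_model <- function() memo("small_model", {
  w <- small_world()
  calibrate(w$sam, w$config)
})

## ASM scenario at the ge50 threshold on the small world, fully prepared
asm_prep <- function() memo("asm_prep", {
  w <- small_world()
  prepare_scenario(w, scenario_spec("ASM", "ge50", "A"))
})

asm_run <- function() memo("asm_run", {
  w <- small_world()
  run_scenario(w, scenario_spec("ASM", "ge50", "A"), prep = asm_prep())
})

## default-sized demo world used by the acceptance suite
demo_world <- function() memo("demo_world", generate_world(world_config()))

## hand-built two-region, one-good exchange economy with Cobb-Douglas
## preferences and labor-only production; its competitive equilibrium has a
## closed form
toy_exchange <- function() {
  config <- structure(list(
    regions = c("A", "B"),
    roles = list(policy = "A", frontier = character(0),
                 spare = character(0), eu = "B", china = "B"),
    sectors = data.frame(sector = "osd", land_cover = "crop",
                         stringsAsFactors = FALSE),
    elasticities = structure(list(
      sigma_nat = c(A = 0.1, B = 0.1), sigma_agpast = c(A = 0.5, B = 0.5),
      sigma_crop = c(A = 1, B = 1), sigma_va = c(osd = 0), sigma_cells = 5,
      armington1 = c(osd = 1), armington2 = c(osd = 2),
      income = c(osd = 1), frisch = -1), class = "soy_elasticities")
  ), class = "world_config")
  cells <- data.frame(cell_id = character(0), region = character(0),
                      biome = character(0), aez = character(0),
                      compliant = logical(0), area_forest = numeric(0),
                      area_grass = numeric(0), area_othernat = numeric(0),
                      area_pasture = numeric(0), area_crop_osd = numeric(0),
                      stringsAsFactors = FALSE)
  acc <- sam_account_table(config, cells)
  m <- matrix(0, nrow(acc), nrow(acc),
              dimnames = list(acc$account, acc$account))
  m["ACT.osd.A", "HH.A"] <- 70; m["ACT.osd.A", "HH.B"] <- 30
  m["ACT.osd.B", "HH.B"] <- 50; m["ACT.osd.B", "HH.A"] <- 30
  m["LAB.A", "ACT.osd.A"] <- 100; m["LAB.B", "ACT.osd.B"] <- 80
  m["HH.A", "LAB.A"] <- 100; m["HH.B", "LAB.B"] <- 80
  sam <- structure(list(sam = m, accounts = acc, cells = cells,
                        sector_weights = matrix(0, 0, 1,
                                                dimnames = list(NULL, "osd"))),
                   class = "soy_sam")
  list(config = config, sam = sam, model = calibrate(sam, config))
}
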