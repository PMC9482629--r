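## footprint module: from trader market shares to the spatial footprint of a
## zero-deforestation supply-chain policy (ZDSP) scenario, and from there to
## the biome-AEZ-compliance land cells the equilibrium model is calibrated on.

scenario_names <- c("ASM", "GlobalZDC", "EU", "China", "EU_and_China")
threshold_names <- c("gt0", "ge50", "ge75")

#' Specify a policy scenario
#'
#' A scenario is a committed-company rule (an explicit roster for the ASM and
#' the global voluntary commitments; a destination rule for the importer-led
#' scenarios), the biomes it applies in (ASM: Amazon only; all others: every
#' biome), a market-share threshold and a forest definition. The ASM is part
#' of every wider scenario: the importer-led and global-commitment footprints
#' are unions with the ASM footprint in the Amazon.
#'
#' @param name one of `"ASM"`, `"GlobalZDC"`, `"EU"`, `"China"`,
#'   `"EU_and_China"`.
#' @param threshold `"gt0"` (any committed company present), `"ge50"` or
#'   `"ge75"` (inclusive bounds).
#' @param forest_definition `"A"` (forest sensu stricto everywhere) or `"B"`
#'   (adds natural grassland outside the Amazon).
#' @param companies optional explicit committed-company roster (character);
#'   only allowed for ASM / GlobalZDC, where it overrides the roster flags.
#' @return object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, threshold = "ge75", forest_definition = "A",
                          companies = NULL) {
  name <- match.arg(name, scenario_names)
  threshold <- match.arg(threshold, threshold_names)
  forest_definition <- match.arg(forest_definition, c("A", "B"))
  dest_rule <- switch(name, EU = "EU", China = "China",
                      EU_and_China = c("EU", "China"))
  abort_if(!is.null(companies) && !is.null(dest_rule),
           "destination-rule scenarios take their roster from the export table")
  structure(list(name = name, threshold = threshold,
                 forest_definition = forest_definition,
                 companies = companies, destination_rule = dest_rule,
                 applies_in_biomes = if (name == "ASM") "Amazon"
                                     else c("Amazon", "Cerrado", "Other")),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, " | threshold ", x$threshold,
      " | forest definition ", x$forest_definition, "\n", sep = "")
  invisible(x)
}

#' Load the real-world committed-company rosters
#'
#' The soy-moratorium signatory list and the global voluntary
#' zero-deforestation pledgers, shipped as editable YAML configuration for
#' use against real trader tables (company names are configuration, not
#' code). Pledge-year staging is ignored: commitments are treated as in
#' force from the benchmark year.
#'
#' @return list with `asm` (exporting signatories), `asm_non_exporting` and
#'   `global_zdc` character vectors.
#' @export
company_rosters <- function() {
  p <- function(f) {
    path <- system.file("extdata", f, package = "soyshift")
    if (path == "") path <- file.path("inst", "extdata", f)
    yaml::read_yaml(path)
  }
  asm <- p("asm_companies.yaml")
  zdc <- p("global_zdc_companies.yaml")
  list(asm = unlist(asm$asm_soy_exporters),
       asm_non_exporting = unlist(asm$asm_members_not_exporting_from_amazon),
       global_zdc = vapply(zdc$global_zdc_companies, `[[`, "", "name"))
}

#' Committed-trader market share of a municipality
#'
#' Share of the municipality's exported soy volume bought by committed
#' companies. Municipalities with zero exported volume get `NA` (no buyer
#' leverage exists; treated as non-compliant downstream).
#'
#' @param exports_of_muni rows of the trader-export table for one
#'   municipality.
#' @param committed character vector of committed company ids.
#' @return fraction in \[0, 1\], or `NA_real_` for zero total volume.
#' @export
committed_share <- function(exports_of_muni, committed) {
  tot <- sum(exports_of_muni$volume_t)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(exports_of_muni$volume_t[exports_of_muni$company_id %in% committed]) / tot
}

#' Classify a municipality against a market-share threshold
#'
#' `gt0` requires a strictly positive committed share; `ge50` and `ge75` are
#' inclusive bounds. An undefined share (zero exports) is non-compliant.
#'
#' @param share committed market share in \[0, 1\] or `NA`.
#' @param threshold `"gt0"`, `"ge50"` or `"ge75"`.
#' @return logical flag.
#' @export
classify_municipality <- function(share, threshold) {
  threshold <- match.arg(threshold, threshold_names)
  out <- switch(threshold,
                gt0 = share > 0,
                ge50 = share >= 0.5,
                ge75 = share >= 0.75)
  out[is.na(out)] <- FALSE
  out
}

#' Resolve the committed-company set of a scenario
#'
#' Destination-rule scenarios include every company with any export to the
#' named destination(s): a company keeps a single supply chain, so selling
#' even one tonne to a regulated market commits its entire sourcing. ASM and
#' GlobalZDC return the explicit roster (the scenario's `companies` override or
#' the roster flags).
#'
#' @param spec a [scenario_spec()].
#' @param trader_exports trader export table.
#' @param companies company roster table (with `asm_member`, `global_zdc`).
#' @return character vector of committed company ids.
#' @export
resolve_scenario_companies <- function(spec, trader_exports, companies) {
  if (!is.null(spec$companies)) return(spec$companies)
  if (is.null(spec$destination_rule)) {
    return(switch(spec$name,
      ASM = companies$company_id[companies$asm_member],
      GlobalZDC = companies$company_id[companies$asm_member |
                                         companies$global_zdc]))
  }
  abort_if(!all(spec$destination_rule %in% trader_exports$destination) &&
             !all(spec$destination_rule %in% c("EU", "China", "OtherDest")),
           paste("unknown destination label:",
                 paste(spec$destination_rule, collapse = ", ")))
  sel <- trader_exports$destination %in% spec$destination_rule &
    trader_exports$volume_t > 0
  sort(unique(trader_exports$company_id[sel]))
}

#' Assign a split municipality to one AEZ and one biome
#'
#' AEZ by largest map intersection; biome by policy-stringency priority
#' (Amazon first, then Cerrado, then Other), regardless of intersection area.
#'
#' @param aez_fractions named numeric vector of intersection fractions per
#'   candidate AEZ.
#' @param biome_fractions named numeric vector per candidate biome.
#' @return list with `aez_id` and `biome`.
#' @export
assign_cell <- function(aez_fractions, biome_fractions) {
  abort_if(length(aez_fractions) == 0 || length(biome_fractions) == 0,
           "no candidate AEZ/biome intersections given")
  biomes <- names(biome_fractions)[biome_fractions > 0]
  abort_if(length(biomes) == 0, "no candidate AEZ/biome intersections given")
  biome <- if ("Amazon" %in% biomes) "Amazon"
           else if ("Cerrado" %in% biomes) "Cerrado" else biomes[1]
  list(aez_id = names(aez_fractions)[which.max(aez_fractions)], biome = biome)
}

#' Restricted-cover area of a municipality under a forest definition
#'
#' Definition A restricts forest sensu stricto everywhere; definition B adds
#' natural grassland outside the Amazon (inside the Amazon both definitions
#' coincide with the mapped forest).
#'
#' @param muni one-row municipality record (or the full table, vectorised).
#' @param definition `"A"` or `"B"`.
#' @return restricted-cover area in ha.
#' @export
apply_forest_definition <- function(muni, definition) {
  definition <- match.arg(definition, c("A", "B"))
  if (definition == "A") return(muni$forest_A_ha)
  ifelse(muni$biome == "Amazon", muni$forest_A_ha, muni$forest_B_ha)
}

#' Build the compliance map of a scenario
#'
#' Computes each municipality's committed market share and compliance flag.
#' The ASM rule (ASM roster, Amazon biome) is OR-ed into every wider
#' scenario, matching the construction of the scenario footprints.
#'
#' @param munis municipality table.
#' @param trader_exports trader export table.
#' @param companies company roster.
#' @param spec a [scenario_spec()].
#' @return data.frame(muni_id, share, compliant) with attribute
#'   `n_zero_export` (count of municipalities without exports, logged as
#'   non-compliant).
#' @export
build_compliance_map <- function(munis, trader_exports, companies, spec) {
  by_muni <- split(trader_exports, trader_exports$muni_id)
  share_of <- function(roster) {
    vapply(munis$muni_id, function(id) {
      e <- by_muni[[id]]
      if (is.null(e)) NA_real_ else committed_share(e, roster)
    }, numeric(1))
  }
  asm_roster <- resolve_scenario_companies(scenario_spec("ASM"),
                                           trader_exports, companies)
  asm_share <- share_of(asm_roster)
  asm_flag <- classify_municipality(asm_share, spec$threshold) &
    munis$biome == "Amazon"

  if (spec$name == "ASM") {
    share <- asm_share
    flag <- asm_flag
  } else {
    roster <- resolve_scenario_companies(spec, trader_exports, companies)
    if (spec$name == "GlobalZDC")
      roster <- companies$company_id[companies$global_zdc]
    wide_share <- share_of(roster)
    wide_flag <- classify_municipality(wide_share, spec$threshold)
    share <- pmax(wide_share, ifelse(munis$biome == "Amazon", asm_share, 0),
                  na.rm = TRUE)
    share[is.na(wide_share) & is.na(asm_share)] <- NA_real_
    flag <- wide_flag | asm_flag
  }
  out <- data.frame(muni_id = munis$muni_id, share = share,
                    compliant = flag, stringsAsFactors = FALSE)
  attr(out, "n_zero_export") <- sum(is.na(share))
  out
}

#' Split the world's accounts by scenario compliance
#'
#' Applies the biome-AEZ-compliance split: every biome-AEZ cell of the policy
#' country becomes a compliant (".ZDC") and a non-compliant (".NoZDC") cell,
#' with areas summed over member municipalities and land-rent/output weights
#' split accordingly; the SAM is rebuilt on the finer account set (national
#' totals are conserved). Crops beyond the first two are shared out in
#' proportion to cell cropland via the municipality crop-area split.
#'
#' @param world a `"soy_world"`.
#' @param compliance_map output of [build_compliance_map()].
#' @return a `"soy_sam"` on the split cells.
#' @export
split_accounts <- function(world, compliance_map) {
  flag <- stats::setNames(compliance_map$compliant, compliance_map$muni_id)
  cl <- aggregate_cells(world$municipalities, world$config, compliance = flag)
  build_sam_for_cells(world$config, cl$cells, cl$sector_weights)
}

#' Coverage of a compliance map over national soy and land covers
#'
#' Shares of the policy country's soy area, cropland, pasture and forest that
#' lie inside compliant municipalities.
#'
#' @param munis municipality table.
#' @param compliance_map output of [build_compliance_map()].
#' @param forest_definition `"A"` or `"B"` for the forest cover measure.
#' @return named numeric vector of shares in \[0, 1\].
#' @export
coverage_stats <- function(munis, compliance_map, forest_definition = "A") {
  flag <- compliance_map$compliant[match(munis$muni_id,
                                         compliance_map$muni_id)]
  fa <- apply_forest_definition(munis, forest_definition)
  sh <- function(x) if (sum(x) <= 0) 0 else sum(x[flag]) / sum(x)
  c(soy_area = sh(munis$soy_area_ha),
    cropland = sh(munis$cropland_ha),
    pasture = sh(munis$pasture_ha),
    forest = sh(fa))
}

#' Enumerate the full scenario grid
#'
#' All scenario x threshold x forest-definition combinations (5 x 3 x 2 = 30),
#' without duplication.
#'
#' @return data.frame with columns `scenario`, `threshold`,
#'   `forest_definition`.
#' @export
scenario_grid <- function() {
  g <- expand.grid(scenario = scenario_names, threshold = threshold_names,
                   forest_definition = c("A", "B"),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$scenario, g$threshold, g$forest_definition), , drop = FALSE]
}
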