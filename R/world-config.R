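#' Sector table for the default 6-sector aggregation
#'
#' Each sector is tagged with the land cover it occupies: `crop` sectors
#' compete for cropland inside the crop nest, `pasture` is used by grazing
#' livestock, `forest` by forestry, and `none` marks sectors with no land
#' input (processed food, manufactures & services).
#'
#' @return data.frame with columns `sector` and `land_cover`.
#' @export
default_sectors <- function() {
  data.frame(
    sector = c("osd", "gro", "lvs", "frs", "pfd", "mfs"),
    land_cover = c("crop", "crop", "pasture", "forest", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Paper-style 18-sector aggregation preset
#' @return data.frame with columns `sector` and `land_cover`.
#' @export
sectors_preset_18 <- function() {
  data.frame(
    sector = c("pdr", "wht", "gro", "osd", "sgr", "lvs", "olv", "frs",
               "ext", "plv", "vol", "prr", "psg", "ofd", "chm", "mnf",
               "svc", "trn"),
    land_cover = c("crop", "crop", "crop", "crop", "crop", "pasture", "none",
                   "forest", "none", "none", "none", "none", "none", "none",
                   "none", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Paper-style 11-region aggregation preset
#'
#' Brazil, Bolivia, Argentina, Paraguay, rest of Latin America, US-Canada,
#' the EU, China, Malaysia-Indonesia, sub-Saharan Africa and the rest of the
#' world, with the region roles the scenario machinery needs.
#' @return list with `regions` and `roles` suitable for [world_config()].
#' @export
regions_preset_11 <- function() {
  list(
    regions = c("BRA", "BOL", "ARG", "PRY", "RLA", "USCAN", "EU", "CHN",
                "MYIDN", "SSA", "ROW"),
    roles = list(policy = "BRA", frontier = c("BOL", "ARG", "PRY"),
                 spare = "USCAN", eu = "EU", china = "CHN")
  )
}

#' Default behavioural elasticities
#'
#' Transformation elasticities govern the land-supply nests: `sigma_nat`
#' (natural cover vs agricultural land; the deforestation margin, set low for
#' regions with little active forest-conversion frontier), `sigma_agpast`
#' (pasture vs cropland) and `sigma_crop` (between crops). `sigma_va` is the
#' substitution between land and non-land inputs (the intensification /
#' yield-price response channel), `sigma_cells` the substitutability of land
#' of the same cover across cells of a region, and `armington1`/`armington2`
#' the trade substitution between domestic and imported varieties and across
#' import origins. `income` holds income elasticities of final demand and
#' `frisch` the Frisch parameter of the linear expenditure system.
#'
#' @param regions character vector of region names.
#' @param sectors sector table (see [default_sectors()]).
#' @param roles region-role list (`policy`, `frontier`, `spare`, ...).
#' @return list of named numeric vectors, class `"soy_elasticities"`.
#' @export
default_elasticities <- function(regions, sectors = default_sectors(),
                                 roles = NULL) {
  sn <- sectors$sector
  sigma_nat <- stats::setNames(rep(0.08, length(regions)), regions)
  if (!is.null(roles)) {
    sigma_nat[intersect(roles$policy, regions)] <- 0.25
    sigma_nat[intersect(roles$frontier, regions)] <- 0.30
    sigma_nat[intersect(roles$spare, regions)] <- 0.02
    sigma_nat[intersect(roles$eu, regions)] <- 0.02
    ## the China-dominated aggregate is not an active conversion frontier
    sigma_nat[intersect(roles$china, regions)] <- 0.03
  }
  arm1 <- stats::setNames(ifelse(sectors$land_cover == "crop", 4,
                          ifelse(sectors$land_cover == "pasture", 1.5,
                          ifelse(sn == "mfs", 2, 3))), sn)
  inc <- stats::setNames(rep(0.8, length(sn)), sn)
  inc[sectors$land_cover == "crop"] <- 0.4
  inc[sectors$land_cover == "pasture"] <- 0.7
  ## timber demand is income-inelastic over a 5-year horizon
  inc[sectors$land_cover == "forest"] <- 0.1
  inc[sn %in% c("mfs", "svc", "mnf", "trn", "chm")] <- 1.15
  sva <- stats::setNames(ifelse(sectors$land_cover == "none", 1.0,
                         ifelse(sectors$land_cover == "forest", 1.0, 0.35)),
                         sn)
  structure(list(
    sigma_nat = sigma_nat,
    sigma_agpast = stats::setNames(rep(0.6, length(regions)), regions),
    sigma_crop = stats::setNames(rep(1.0, length(regions)), regions),
    sigma_va = sva,
    sigma_cells = 5,
    armington1 = arm1,
    armington2 = 2 * arm1,
    income = inc,
    frisch = -2
  ), class = "soy_elasticities")
}

#' Configuration of the synthetic mini-world
#'
#' Bundles everything the generators need: the regional and sectoral
#' aggregation, the size of the municipality and trader layers, behavioural
#' elasticities, and the structural-realism knobs. `destination_segmentation`
#' in \[0, 1\] controls how strongly exports concentrate on each exporter's
#' main destination (at 1, the policy country ships soy only to China and the
#' neighbouring frontier only to the EU). `domestic_use_frac` is the share of
#' soy production consumed domestically and therefore outside the export
#' market-share denominator.
#'
#' @param regions character vector of region names (>= 2). The default is the
#'   reduced 5-region aggregation; use [regions_preset_11()] for the full
#'   11-region preset.
#' @param roles list naming the policy country, neighbouring frontier,
#'   spare-land competitor and destination-market regions.
#' @param sectors sector table; see [default_sectors()] / [sectors_preset_18()].
#' @param n_municipalities,n_companies,n_aez layer sizes (all >= 2).
#' @param seed integer seed; all generators are deterministic given it.
#' @param destination_segmentation fraction in \[0, 1\].
#' @param domestic_use_frac fraction in \[0, 1).
#' @param elasticities optional [default_elasticities()] override.
#' @param region_scale named relative economic sizes (policy country = 1).
#' @return object of class `"world_config"`.
#' @export
world_config <- function(regions = c("BRA", "BAP", "USCAN", "EU", "CHNROW"),
                         roles = list(policy = "BRA", frontier = "BAP",
                                      spare = "USCAN", eu = "EU",
                                      china = "CHNROW"),
                         sectors = default_sectors(),
                         n_municipalities = 60L,
                         n_companies = 12L,
                         n_aez = 2L,
                         seed = 42L,
                         destination_segmentation = 0.85,
                         domestic_use_frac = 0.35,
                         elasticities = NULL,
                         region_scale = NULL) {
  abort_if(length(regions) < 2 || anyDuplicated(regions) > 0,
           "need >= 2 distinct regions", "soyshift_config_error")
  abort_if(!is.data.frame(sectors) ||
             !all(c("sector", "land_cover") %in% names(sectors)) ||
             nrow(sectors) < 2,
           "sectors must be a data.frame(sector, land_cover) with >= 2 rows",
           "soyshift_config_error")
  abort_if(!all(sectors$land_cover %in% c("crop", "pasture", "forest", "none")),
           "unknown land_cover tag in sector table", "soyshift_config_error")
  abort_if(sum(sectors$land_cover == "crop") < 1,
           "need at least one crop sector", "soyshift_config_error")
  for (nm in c("n_municipalities", "n_companies", "n_aez"))
    abort_if(!is_count(get(nm), 2L), paste(nm, "must be a count >= 2"),
             "soyshift_config_error")
  abort_if(!is.numeric(destination_segmentation) ||
             destination_segmentation < 0 || destination_segmentation > 1,
           "destination_segmentation must lie in [0, 1]",
           "soyshift_config_error")
  abort_if(!is.numeric(domestic_use_frac) ||
             domestic_use_frac < 0 || domestic_use_frac >= 1,
           "domestic_use_frac must lie in [0, 1)", "soyshift_config_error")
  abort_if(!all(unlist(roles) %in% regions),
           "all role regions must appear in `regions`",
           "soyshift_config_error")
  if (is.null(region_scale)) {
    region_scale <- stats::setNames(rep(1.5, length(regions)), regions)
    region_scale[roles$policy] <- 1.0
    region_scale[roles$frontier] <- 0.35
    region_scale[roles$spare] <- 2.2
    region_scale[roles$eu] <- 2.5
    region_scale[roles$china] <- 4.0
  }
  if (is.null(elasticities))
    elasticities <- default_elasticities(regions, sectors, roles)
  structure(list(
    regions = regions, roles = roles, sectors = sectors,
    n_municipalities = as.integer(n_municipalities),
    n_companies = as.integer(n_companies),
    n_aez = as.integer(n_aez),
    seed = as.integer(seed),
    destination_segmentation = destination_segmentation,
    domestic_use_frac = domestic_use_frac,
    elasticities = elasticities,
    region_scale = region_scale
  ), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", length(x$regions), " regions x ",
      nrow(x$sectors), " sectors; ", x$n_municipalities,
      " municipalities, ", x$n_companies, " companies, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
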