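## synthetic_world module: municipality layer, trader exports, balanced SAM.
## All generators take explicit seeds through the config; no global RNG state
## leaks (see with_seed()).

rdirich <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

## Concentrate a weight vector on its dominant entries as `seg` -> 1.
## At seg = 1 the result is one-hot at the argmax; at seg = 0 it is w itself.
sharpen_weights <- function(w, seg, drop_below = 0) {
  stopifnot(all(w >= 0), sum(w) > 0)
  if (seg >= 1) {
    out <- numeric(length(w)); out[which.max(w)] <- 1
    names(out) <- names(w)
    return(out)
  }
  p <- (w / sum(w))^(1 / (1 - seg))
  p <- p / sum(p)
  if (drop_below > 0) {
    p[p < drop_below] <- 0
    p <- p / sum(p)
  }
  p
}

#' Generate the synthetic municipality layer
#'
#' Draws a municipality table for the policy country with the structure the
#' footprint stage consumes: biome (Amazon / Cerrado / Other), AEZ, land
#' covers, soy area and production, second-harvest maize (always on soy area)
#' and cattle herd. Two forest measures are carried: `forest_A_ha` (forest
#' sensu stricto) and `forest_B_ha`, which adds natural grassland outside the
#' Amazon and equals `forest_A_ha` inside it.
#'
#' A small fraction of municipalities produce no soy, so the zero-export
#' classification path is always exercised downstream.
#'
#' @param config a [world_config()].
#' @return data.frame, one row per municipality.
#' @export
generate_municipalities <- function(config) {
  abort_if(!inherits(config, "world_config"), "config must be a world_config",
           "soyshift_config_error")
  n <- config$n_municipalities
  with_seed(config$seed, {
    biome <- sample(c("Amazon", "Cerrado", "Other"), n, replace = TRUE,
                    prob = c(0.30, 0.40, 0.30))
    ## guarantee every biome is represented
    biome[seq_len(3)] <- c("Amazon", "Cerrado", "Other")
    aez <- sample.int(config$n_aez, n, replace = TRUE)
    total_ha <- exp(stats::runif(n, log(5e4), log(8e5)))

    base_shares <- rbind(
      Amazon  = c(forest = 0.55, othernat = 0.10, pasture = 0.20, crop = 0.15),
      Cerrado = c(forest = 0.25, othernat = 0.25, pasture = 0.30, crop = 0.20),
      Other   = c(forest = 0.30, othernat = 0.15, pasture = 0.35, crop = 0.20))
    grass_frac <- c(Amazon = 0, Cerrado = 0.6, Other = 0.5)

    shares <- matrix(0, n, 4)
    for (i in seq_len(n))
      shares[i, ] <- rdirich(1, 25 * base_shares[biome[i], ])
    forest <- shares[, 1] * total_ha
    othernat <- shares[, 2] * total_ha
    pasture <- shares[, 3] * total_ha
    cropland <- shares[, 4] * total_ha
    grass <- grass_frac[biome] * othernat

    soy_frac <- stats::runif(n, 0.2, 0.7)
    soy_frac[biome == "Cerrado"] <- stats::runif(sum(biome == "Cerrado"),
                                                 0.35, 0.75)
    no_soy <- stats::runif(n) < 0.10
    soy_frac[no_soy] <- 0
    soy_area <- soy_frac * cropland
    yield <- stats::runif(n, 2.5, 3.5)
    data.frame(
      muni_id = sprintf("M%04d", seq_len(n)),
      biome = biome,
      aez_id = aez,
      forest_A_ha = forest,
      forest_B_ha = forest + grass,
      other_natural_ha = othernat,
      grassland_ha = grass,
      cropland_ha = cropland,
      pasture_ha = pasture,
      soy_area_ha = soy_area,
      soy_production_t = soy_area * yield,
      maize2_area_ha = soy_area * stats::runif(n, 0.2, 0.8),
      cattle_heads = pasture * stats::runif(n, 0.5, 1.5),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate the synthetic company roster
#'
#' Companies carry commitment metadata (ASM signatory; global voluntary
#' zero-deforestation pledge, always a subset of ASM signatories) and
#' destination propensities over EU / China / other destinations. The
#' `destination_segmentation` knob concentrates each company on its dominant
#' destination; at 1 every company ships to exactly one destination and the
#' aggregate pattern mimics the policy country's soy exports concentrating on
#' China while the neighbouring frontier serves the EU.
#'
#' @param config a [world_config()].
#' @return data.frame with one row per company and columns `w_EU`, `w_China`,
#'   `w_OtherDest` (destination volume shares).
#' @export
generate_companies <- function(config) {
  abort_if(!inherits(config, "world_config"), "config must be a world_config",
           "soyshift_config_error")
  n <- config$n_companies
  with_seed(config$seed + 1L, {
    size <- exp(stats::rnorm(n, 0, 1))
    asm <- stats::runif(n) < 0.6
    asm[which.max(size)] <- TRUE      # the largest trader signed the ASM
    zdc <- asm & (stats::runif(n) < 0.5)
    zdc[which.max(size)] <- TRUE
    base <- c(EU = 0.22, China = 0.68, OtherDest = 0.10)
    w <- matrix(0, n, 3, dimnames = list(NULL, names(base)))
    for (k in seq_len(n)) {
      noisy <- base * exp(stats::rnorm(3, 0, 0.55))
      w[k, ] <- sharpen_weights(noisy, config$destination_segmentation,
                                drop_below = 0.02)
    }
    ## keep the EU scenario non-degenerate: at least one EU-leaning trader
    if (all(w[, "EU"] == 0)) {
      k <- which.min(size)
      w[k, ] <- c(1, 0, 0)
    }
    data.frame(
      company_id = sprintf("C%02d", seq_len(n)),
      size_weight = size,
      asm_member = asm,
      global_zdc = zdc,
      w_EU = w[, "EU"], w_China = w[, "China"], w_OtherDest = w[, "OtherDest"],
      stringsAsFactors = FALSE
    )
  })
}

#' Generate the trader export table
#'
#' Emulates a municipality x exporter x destination export-volume table: each
#' soy-producing municipality sells its exportable surplus (production net of
#' the domestic-use fraction) through a small set of companies, each of which
#' splits volumes over destinations according to its propensities. Volumes per
#' municipality never exceed its soy production.
#'
#' @param munis municipality table from [generate_municipalities()].
#' @param config a [world_config()].
#' @param companies optional roster from [generate_companies()]; generated
#'   from the config when omitted.
#' @return data.frame(muni_id, company_id, destination, volume_t).
#' @export
generate_trader_exports <- function(munis, config, companies = NULL) {
  abort_if(!inherits(config, "world_config"), "config must be a world_config",
           "soyshift_config_error")
  if (is.null(companies)) companies <- generate_companies(config)
  abort_if(nrow(companies) == 0, "empty company roster")
  dest <- c("EU", "China", "OtherDest")
  wmat <- as.matrix(companies[, c("w_EU", "w_China", "w_OtherDest")])
  with_seed(config$seed + 2L, {
    rows <- vector("list", nrow(munis))
    for (i in seq_len(nrow(munis))) {
      prod_t <- munis$soy_production_t[i]
      if (prod_t <= 0) next
      exported <- prod_t * (1 - config$domestic_use_frac) *
        stats::runif(1, 0.85, 1)
      k <- sample(2:min(4, nrow(companies)), 1)
      ids <- sample.int(nrow(companies), k, prob = companies$size_weight)
      sh <- as.numeric(rdirich(1, rep(1.5, k)))
      sub <- list()
      for (a in seq_len(k)) {
        v <- exported * sh[a] * wmat[ids[a], ]
        keep <- v > 0
        if (!any(keep)) next
        sub[[a]] <- data.frame(
          muni_id = munis$muni_id[i],
          company_id = companies$company_id[ids[a]],
          destination = dest[keep],
          volume_t = unname(v[keep]),
          stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, sub)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## ---------------------------------------------------------------------------
## Cell aggregation: municipalities -> biome-AEZ(-compliance) land cells, plus
## one land cell per foreign region. Returns the cell table and the per-cell
## per-sector output weights used to impute land rents and split output.

biome_productivity <- c(Amazon = 1.15, Cerrado = 0.85, Other = 1.0,
                        Foreign = 1.0)

## per-municipality weight of each land-using sector (used for rent imputation
## and for splitting national output values across cells)
muni_sector_weights <- function(munis, sectors) {
  crop_sectors <- sectors$sector[sectors$land_cover == "crop"]
  w <- matrix(0, nrow(munis), nrow(sectors),
              dimnames = list(munis$muni_id, sectors$sector))
  prodf <- biome_productivity[munis$biome]
  for (j in seq_len(nrow(sectors))) {
    s <- sectors$sector[j]
    w[, j] <- switch(sectors$land_cover[j],
      crop = if (s == crop_sectors[1]) {
        ## first crop sector is the oilseed/soy aggregate
        munis$soy_production_t + 1e-3 * munis$cropland_ha
      } else if (length(crop_sectors) > 1 && s == crop_sectors[2]) {
        munis$maize2_area_ha + 0.4 * pmax(munis$cropland_ha -
                                            munis$soy_area_ha, 0) +
          1e-3 * munis$cropland_ha
      } else {
        ## remaining crops shared out in proportion to cropland
        munis$cropland_ha
      },
      pasture = munis$cattle_heads + 1e-3 * munis$pasture_ha,
      forest = munis$forest_A_ha,
      none = rep(0, nrow(munis)))
    w[, j] <- w[, j] * prodf
  }
  w
}

## per-municipality physical crop areas (first crop = soy; remainder split
## evenly over the other crop sectors, floored away from zero)
muni_crop_areas <- function(munis, sectors) {
  crop_sectors <- sectors$sector[sectors$land_cover == "crop"]
  nc <- length(crop_sectors)
  a <- matrix(0, nrow(munis), nc,
              dimnames = list(munis$muni_id, crop_sectors))
  soy <- pmax(munis$soy_area_ha, 0.005 * munis$cropland_ha)
  soy <- pmin(soy, munis$cropland_ha * (1 - 0.005 * (nc - 1)))
  a[, 1] <- soy
  if (nc > 1) {
    rest <- (munis$cropland_ha - soy) / (nc - 1)
    for (k in 2:nc) a[, k] <- rest
  }
  a
}

## Foreign land endowments, stated relative to the generated policy-country
## totals so hectare deltas stay commensurate across regions: a cover profile
## (shares of the region's land) and a size multiple of the policy country.
foreign_cell_base <- function(region, roles, policy_total_ha) {
  if (region %in% roles$frontier) {
    prof <- c(forest = 0.40, grass = 0.10, othernat = 0.10, pasture = 0.27,
              cropland = 0.13)
    mult <- 0.8
  } else if (region %in% roles$spare) {
    ## large existing farmland, little active forest-conversion frontier
    prof <- c(forest = 0.25, grass = 0.04, othernat = 0.08, pasture = 0.18,
              cropland = 0.45)
    mult <- 1.6
  } else if (region %in% roles$eu) {
    prof <- c(forest = 0.35, grass = 0.02, othernat = 0.05, pasture = 0.25,
              cropland = 0.33)
    mult <- 1.1
  } else {
    prof <- c(forest = 0.35, grass = 0.06, othernat = 0.25, pasture = 0.20,
              cropland = 0.14)
    mult <- 6.0
  }
  prof * mult * policy_total_ha
}

#' Aggregate municipalities into model land cells
#'
#' Builds the biome-AEZ (optionally x compliance) land cells for the policy
#' country by summing member-municipality areas, and one aggregate land cell
#' per foreign region. Cell areas are exactly additive in their member
#' municipalities, so national totals are conserved.
#'
#' @param munis municipality table.
#' @param config a [world_config()].
#' @param compliance optional logical vector named by `muni_id` (a compliance
#'   map); when given, cells are split into compliant (".ZDC") and
#'   non-compliant (".NoZDC") parts.
#' @return list with `cells` (data.frame) and `sector_weights` (cell x sector
#'   matrix of output/rent weights).
#' @export
aggregate_cells <- function(munis, config, compliance = NULL) {
  sectors <- config$sectors
  crop_sectors <- sectors$sector[sectors$land_cover == "crop"]
  pol <- config$roles$policy

  key <- paste(pol, munis$biome, paste0("AEZ", munis$aez_id), sep = ".")
  if (!is.null(compliance)) {
    flag <- compliance[munis$muni_id]
    flag[is.na(flag)] <- FALSE
    key <- paste(key, ifelse(flag, "ZDC", "NoZDC"), sep = ".")
  }
  wmat <- muni_sector_weights(munis, sectors)
  amat <- muni_crop_areas(munis, sectors)

  agg <- function(x) tapply(x, key, sum)
  ids <- sort(unique(key))
  cells <- data.frame(
    cell_id = ids,
    region = pol,
    biome = vapply(strsplit(ids, ".", fixed = TRUE), `[[`, "", 2),
    aez = vapply(strsplit(ids, ".", fixed = TRUE), `[[`, "", 3),
    compliant = if (is.null(compliance)) NA else
      vapply(strsplit(ids, ".", fixed = TRUE), `[[`, "", 4) == "ZDC",
    area_forest = as.numeric(agg(munis$forest_A_ha)[ids]),
    area_grass = as.numeric(agg(munis$grassland_ha)[ids]),
    area_othernat = as.numeric(agg(munis$other_natural_ha)[ids]),
    area_pasture = as.numeric(agg(munis$pasture_ha)[ids]),
    stringsAsFactors = FALSE
  )
  for (cs in crop_sectors)
    cells[[paste0("area_crop_", cs)]] <- as.numeric(tapply(amat[, cs],
                                                           key, sum)[ids])
  sw <- matrix(0, length(ids), nrow(sectors),
               dimnames = list(ids, sectors$sector))
  for (j in seq_len(nrow(sectors)))
    sw[, j] <- as.numeric(tapply(wmat[, j], key, sum)[ids])

  ## foreign regions: one land cell each, deterministic areas scaled to the
  ## generated policy-country total
  pol_total <- sum(munis$forest_A_ha + munis$other_natural_ha +
                     munis$pasture_ha + munis$cropland_ha)
  other <- setdiff(config$regions, pol)
  frows <- lapply(other, function(r) {
    b <- foreign_cell_base(r, config$roles, pol_total)
    row <- data.frame(cell_id = paste0(r, ".cell"), region = r,
                      biome = "Foreign", aez = "AEZ0", compliant = NA,
                      area_forest = unname(b["forest"]),
                      area_grass = unname(b["grass"]),
                      area_othernat = unname(b["othernat"]),
                      area_pasture = unname(b["pasture"]),
                      stringsAsFactors = FALSE)
    nc <- length(crop_sectors)
    osd_share <- if (r %in% config$roles$spare) 0.45 else 0.25
    for (k in seq_along(crop_sectors)) {
      sh <- if (k == 1) osd_share else (1 - osd_share) / max(nc - 1, 1)
      row[[paste0("area_crop_", crop_sectors[k])]] <- unname(b["cropland"]) * sh
    }
    row
  })
  fcells <- do.call(rbind, frows)
  fw <- matrix(0, nrow(fcells), nrow(sectors),
               dimnames = list(fcells$cell_id, sectors$sector))
  for (j in seq_len(nrow(sectors)))
    if (sectors$land_cover[j] != "none") fw[, j] <- 1  # sole cell gets all

  cells <- rbind(cells, fcells)
  rownames(cells) <- cells$cell_id
  list(cells = cells, sector_weights = rbind(sw, fw))
}

## covers with a market (a sector paying rent); othernat is the reservation
## cover and never appears in the SAM
marketed_covers <- function(sectors) {
  crop_sectors <- sectors$sector[sectors$land_cover == "crop"]
  c("forest", "pasture", paste0("crop_", crop_sectors))
}

cover_of_sector <- function(sectors) {
  lc <- sectors$land_cover
  out <- ifelse(lc == "crop", paste0("crop_", sectors$sector),
         ifelse(lc == "pasture", "pasture",
         ifelse(lc == "forest", "forest", NA)))
  stats::setNames(out, sectors$sector)
}
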