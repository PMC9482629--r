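## emissions module: land-cover transition deltas -> CO2-equivalent deltas
## through a per-cell emission-factor matrix over a 30-year horizon.

ef_cover_classes <- c("forest", "grass", "onat", "pasture", "cropland")

#' Default synthetic carbon stocks per cell and cover class
#'
#' Biome-typical carbon stocks (t C/ha) split into the components the
#' emission-factor model tracks: above+below-ground biomass, dead organic
#' matter and soil carbon. These are configurable inputs, not constants of
#' the method; replace them with your own table at will.
#'
#' @param cells a cell table (needs `cell_id` and `biome`).
#' @return data.frame(cell_id, cover, biomass_tC_ha, dom_tC_ha, soil_tC_ha).
#' @export
default_carbon_stocks <- function(cells) {
  base <- list(
    Amazon  = rbind(forest = c(150, 20, 90), grass = c(8, 2, 60),
                    onat = c(30, 5, 70), pasture = c(5, 1, 55),
                    cropland = c(4, 1, 50)),
    Cerrado = rbind(forest = c(60, 10, 70), grass = c(8, 2, 55),
                    onat = c(25, 4, 60), pasture = c(5, 1, 50),
                    cropland = c(4, 1, 45)),
    Other   = rbind(forest = c(80, 12, 75), grass = c(8, 2, 55),
                    onat = c(25, 4, 60), pasture = c(5, 1, 50),
                    cropland = c(4, 1, 45)),
    Foreign = rbind(forest = c(100, 15, 80), grass = c(8, 2, 55),
                    onat = c(25, 4, 60), pasture = c(5, 1, 50),
                    cropland = c(4, 1, 45)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    b <- base[[cells$biome[i]]] %||% base$Other
    data.frame(cell_id = cells$cell_id[i], cover = rownames(b),
               biomass_tC_ha = b[, 1], dom_tC_ha = b[, 2], soil_tC_ha = b[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default emission-factor assumptions
#'
#' `wood_product_frac`: fraction of cleared forest biomass carbon that stays
#' sequestered in wood products over the 30-year horizon (credited).
#' `nonco2_frac`: non-CO2 emissions (fire clearing) as a fraction of the
#' biomass CO2 term. `foregone_seq_tco2_ha`: foregone forest sequestration
#' over the horizon, per cleared hectare. `regrowth_discount`: fraction of
#' the forward factor credited to reverse (regrowing) transitions; set
#' `symmetric = TRUE` to make reverse factors the exact negatives.
#'
#' @return named list.
#' @export
default_ef_assumptions <- function() {
  list(wood_product_frac = 0.1, nonco2_frac = 0.05,
       foregone_seq_tco2_ha = 40, regrowth_discount = 0.5,
       symmetric = FALSE, horizon_years = 30)
}

#' Build the per-cell emission-factor matrix
#'
#' Converts per-cover carbon stocks into t CO2e/ha factors for every cover
#' transition, decomposed into biomass, dead organic matter, soil, foregone
#' sequestration, wood-product credit and a non-CO2 term. The diagonal is
#' zero; reverse transitions are discounted regrowth by default.
#'
#' @param carbon_stock_table see [default_carbon_stocks()].
#' @param assumptions see [default_ef_assumptions()].
#' @return object of class `"ef_matrix"`: list with `total` (cell x from x to
#'   array) and `components` (named list of like-shaped arrays).
#' @export
build_ef_matrix <- function(carbon_stock_table,
                            assumptions = default_ef_assumptions()) {
  st <- carbon_stock_table
  abort_if(any(st$biomass_tC_ha < 0 | st$dom_tC_ha < 0 | st$soil_tC_ha < 0),
           "negative carbon stock")
  cells <- unique(st$cell_id)
  cc <- ef_cover_classes
  dims <- list(cells, cc, cc)
  comp_names <- c("biomass", "dom", "soil", "foregone_seq", "wood_credit",
                  "nonco2")
  comps <- lapply(comp_names, function(x) array(0, dim = lengths(dims),
                                                dimnames = dims))
  names(comps) <- comp_names
  c44 <- 44 / 12
  for (cl in cells) {
    s <- st[st$cell_id == cl, ]
    rownames(s) <- s$cover
    for (from in cc) for (to in cc) {
      if (from == to) next
      bio <- (s[from, "biomass_tC_ha"] - s[to, "biomass_tC_ha"]) * c44
      dom <- (s[from, "dom_tC_ha"] - s[to, "dom_tC_ha"]) * c44
      soil <- (s[from, "soil_tC_ha"] - s[to, "soil_tC_ha"]) * c44
      fseq <- if (from == "forest") assumptions$foregone_seq_tco2_ha else 0
      wood <- if (from == "forest" && bio > 0)
        -assumptions$wood_product_frac * bio else 0
      nco2 <- if (bio > 0) assumptions$nonco2_frac * bio else 0
      comps$biomass[cl, from, to] <- bio
      comps$dom[cl, from, to] <- dom
      comps$soil[cl, from, to] <- soil
      comps$foregone_seq[cl, from, to] <- fseq
      comps$wood_credit[cl, from, to] <- wood
      comps$nonco2[cl, from, to] <- nco2
    }
  }
  total <- Reduce(`+`, comps)
  if (!isTRUE(assumptions$symmetric)) {
    ## regrowth (carbon-gaining transitions) credited at a discount
    disc <- assumptions$regrowth_discount
    for (k in seq_along(comps)) comps[[k]][total < 0] <-
        comps[[k]][total < 0] * disc
    total[total < 0] <- total[total < 0] * disc
  }
  structure(list(total = total, components = comps,
                 assumptions = assumptions), class = "ef_matrix")
}

## Net cover deltas -> gross transition flows along the nest structure:
## within each cell, losing covers are sources and gaining covers sinks,
## matched proportionally (a comparative-static model yields net areas, not
## gross flows).
transition_flows <- function(deltas_cell) {
  d <- deltas_cell
  loss <- pmax(-d, 0); gain <- pmax(d, 0)
  fl <- matrix(0, length(d), length(d), dimnames = list(names(d), names(d)))
  tg <- sum(gain)
  if (tg <= 0 || sum(loss) <= 0) return(fl)
  for (from in names(d)) if (loss[from] > 0)
    fl[from, ] <- loss[from] * gain / tg
  fl
}

#' Convert land-change deltas into a GHG emissions report
#'
#' Maps each cell's net cover deltas to gross transitions and applies the
#' emission-factor matrix. Sign convention: avoided deforestation yields a
#' negative emissions delta (a saving).
#'
#' @param land_change_table a [diff_land()] result.
#' @param ef an `"ef_matrix"` built on the same cells.
#' @return object of class `"emissions_report"`: `by_region` (kt CO2e),
#'   `global_kt`, `components_kt`.
#' @export
emissions_from_deltas <- function(land_change_table, ef) {
  d <- land_change_table$deltas
  d$class <- ifelse(startsWith(d$cover, "crop_"), "cropland", d$cover)
  abort_if(!all(d$class %in% ef_cover_classes),
           paste("unmapped cover:",
                 paste(setdiff(d$class, ef_cover_classes), collapse = ", ")))
  cells <- unique(d$cell_id)
  abort_if(!all(cells %in% dimnames(ef$total)[[1]]),
           "emission-factor matrix does not cover all cells")
  comp_names <- names(ef$components)
  by_region <- list()
  comp_tot <- stats::setNames(numeric(length(comp_names)), comp_names)
  for (cl in cells) {
    sub <- d[d$cell_id == cl, ]
    dl <- tapply(sub$delta_ha, sub$class, sum)
    dl <- stats::setNames(as.numeric(dl[ef_cover_classes]), ef_cover_classes)
    dl[is.na(dl)] <- 0
    fl <- transition_flows(dl)
    e_kt <- sum(fl * ef$total[cl, , ]) / 1e3
    r <- sub$region[1]
    by_region[[r]] <- (by_region[[r]] %||% 0) + e_kt
    for (cn in comp_names)
      comp_tot[cn] <- comp_tot[cn] + sum(fl * ef$components[[cn]][cl, , ]) / 1e3
  }
  by_region <- unlist(by_region)
  structure(list(by_region_kt = by_region, global_kt = sum(by_region),
                 components_kt = comp_tot),
            class = "emissions_report")
}

#' @export
print.emissions_report <- function(x, ...) {
  cat("<emissions_report> global ", format(x$global_kt, digits = 4),
      " kt CO2e (negative = savings)\n", sep = "")
  invisible(x)
}
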