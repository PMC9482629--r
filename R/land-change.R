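## Land-change accounting between paired equilibria.

#' Difference land allocations between a counterfactual and its baseline
#'
#' Computes per-cell per-cover area deltas (counterfactual minus baseline) and
#' classifies forest deltas into the policy partition: ZDSP (cells under the
#' conversion freeze), domestic No-ZDSP (uncovered cells of the policy
#' country) and foreign No-ZDSP. Positive forest deltas are gross avoided
#' deforestation, negative deltas gross displaced deforestation, and global,
#' ZDSP and No-ZDSP deltas add up exactly by construction.
#'
#' @param eq_baseline,eq_counterfactual equilibria from the same calibrated
#'   model and drivers.
#' @param footprint_cells character vector of covered cell ids.
#' @param policy_region region name of the policy country.
#' @return object of class `"land_change_table"`.
#' @export
diff_land <- function(eq_baseline, eq_counterfactual, footprint_cells,
                      policy_region) {
  lb <- eq_baseline$land
  lc <- eq_counterfactual$land
  abort_if(nrow(lb) != nrow(lc) ||
             !all(lb$cell_id == lc$cell_id & lb$cover == lc$cover),
           "mismatched model dimensions between the two equilibria")
  deltas <- data.frame(cell_id = lb$cell_id, region = lb$region,
                       cover = lb$cover, delta_ha = lc$area - lb$area,
                       stringsAsFactors = FALSE)
  f <- deltas[deltas$cover == "forest", , drop = FALSE]
  f$category <- ifelse(f$cell_id %in% footprint_cells, "ZDSP",
                ifelse(f$region == policy_region, "NoZDSP_domestic",
                       "NoZDSP_foreign"))
  sm <- list(
    delta_zdsp = sum(f$delta_ha[f$category == "ZDSP"]),
    delta_no_zdsp_domestic = sum(f$delta_ha[f$category == "NoZDSP_domestic"]),
    delta_no_zdsp_foreign = sum(f$delta_ha[f$category == "NoZDSP_foreign"]))
  sm$delta_no_zdsp <- sm$delta_no_zdsp_domestic + sm$delta_no_zdsp_foreign
  sm$delta_global <- sm$delta_zdsp + sm$delta_no_zdsp
  structure(list(deltas = deltas, forest = f, summary = sm,
                 policy_region = policy_region,
                 footprint_cells = footprint_cells),
            class = "land_change_table")
}

#' @export
print.land_change_table <- function(x, ...) {
  s <- x$summary
  cat("<land_change_table> forest deltas (ha, + = avoided deforestation)\n",
      "  ZDSP ", format(s$delta_zdsp, digits = 4),
      " | NoZDSP domestic ", format(s$delta_no_zdsp_domestic, digits = 4),
      " | NoZDSP foreign ", format(s$delta_no_zdsp_foreign, digits = 4),
      " | global ", format(s$delta_global, digits = 4), "\n", sep = "")
  invisible(x)
}
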