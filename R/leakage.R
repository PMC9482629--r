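## leakage_metrics module: leakage rates, the domestic / cross-border
## decomposition, and recomputation of the published headline arithmetic from
## the bundled printed-values fixture.

#' Deforestation leakage rate
#'
#' The increase in deforestation in regions without restrictions as a
#' percentage of the absolute deforestation change in restricted regions:
#' `delta_no_zdsp / |delta_zdsp| * 100`. Arguments are in deforestation
#' terms, so a positive `delta_no_zdsp` means displaced clearing.
#'
#' @param delta_no_zdsp deforestation increase outside restricted regions.
#' @param delta_zdsp deforestation change inside restricted regions
#'   (non-zero).
#' @return leakage rate in percent; `NA` with a warning for a zero
#'   denominator.
#' @examples
#' leakage_rate(215, -409)  # 52.6
#' @export
leakage_rate <- function(delta_no_zdsp, delta_zdsp) {
  if (abs(delta_zdsp) < .Machine$double.eps) {
    warning("leakage rate undefined: zero deforestation change in ",
            "restricted regions")
    return(NA_real_)
  }
  delta_no_zdsp / abs(delta_zdsp) * 100
}

#' Build a leakage report from a land-change table
#'
#' Decomposes forest-area deltas into gross avoided deforestation inside the
#' footprint, displaced deforestation at home and abroad (the cross-border
#' part split into the neighbouring-frontier analogue and the rest of the
#' world), nets, and the two leakage rates. Raw floats are retained; rounding
#' belongs to the presentation layer.
#'
#' @param land_change_table a [diff_land()] result.
#' @param frontier_regions region names of the neighbouring-frontier group
#'   (the Bolivia-Argentina-Paraguay analogue).
#' @return object of class `"leakage_report"` (a list of numerics, kha).
#' @export
build_report <- function(land_change_table, frontier_regions = character(0)) {
  abort_if(!inherits(land_change_table, "land_change_table"),
           "need a land_change_table")
  f <- land_change_table$forest
  s <- land_change_table$summary
  gross <- s$delta_zdsp / 1000
  disp_dom <- -s$delta_no_zdsp_domestic / 1000
  fr <- f$category == "NoZDSP_foreign"
  disp_bap <- -sum(f$delta_ha[fr & f$region %in% frontier_regions]) / 1000
  disp_row <- -sum(f$delta_ha[fr & !(f$region %in% frontier_regions)]) / 1000
  disp_cross <- disp_bap + disp_row
  out <- list(
    gross_avoided_kha = gross,
    displaced_domestic_kha = disp_dom,
    displaced_crossborder_kha = disp_cross,
    displaced_bap_kha = disp_bap,
    displaced_row_kha = disp_row,
    net_country_kha = gross - disp_dom,
    net_global_kha = gross - disp_dom - disp_cross,
    domestic_leakage_rate_pct =
      if (gross == 0) NA_real_ else leakage_rate(disp_dom * 1000,
                                                 s$delta_zdsp),
    crossborder_leakage_rate_pct =
      if (gross == 0) NA_real_ else leakage_rate(disp_cross * 1000,
                                                 s$delta_zdsp))
  structure(out, class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat("<leakage_report> (kha)\n",
      sprintf("  gross avoided %.1f | displaced: domestic %.1f, cross-border %.1f (frontier %.2f, RoW %.2f)\n",
              x$gross_avoided_kha, x$displaced_domestic_kha,
              x$displaced_crossborder_kha, x$displaced_bap_kha,
              x$displaced_row_kha),
      sprintf("  net country %.1f | net global %.1f | leakage rates: domestic %.0f%%, cross-border %.1f%%\n",
              x$net_country_kha, x$net_global_kha,
              x$domestic_leakage_rate_pct, x$crossborder_leakage_rate_pct),
      sep = "")
  invisible(x)
}

#' Load the bundled printed-results fixture
#'
#' One row per headline number of the source study's results (scenario-level
#' forest-area changes, GHG deltas, reference totals), with a `flag` column
#' marking upper bounds and one internally inconsistent quantity (excluded
#' from arithmetic verification).
#'
#' @return data.frame.
#' @export
published_values <- function() {
  path <- system.file("extdata", "published_headline_values.csv",
                      package = "soyshift")
  if (path == "") path <- file.path("inst", "extdata",
                                    "published_headline_values.csv")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("quantity", "scenario", "value", "unit", "flag") %in%
                  names(out)), "fixture schema mismatch")
  out
}

pv <- function(fx, q) {
  v <- fx$value[fx$quantity == q]
  abort_if(length(v) != 1, paste("fixture schema mismatch: missing", q))
  v
}

#' Recompute the published headline arithmetic from the fixture
#'
#' Every derived headline quantity (annualized avoided deforestation, leakage
#' rates, cross-scenario ratios, emission shares) is recomputed from the raw
#' printed inputs with the package's own leakage operations, and compared to
#' the printed value under its stated rounding rule (`nearest` at the printed
#' precision; `within_1` percentage point for ratios the source rounds
#' loosely; `above` for "just above" statements).
#'
#' @param fixture optionally a pre-loaded fixture table.
#' @return data.frame(check, computed, printed, rule, pass) with attribute
#'   `all_pass`.
#' @export
verify_printed_arithmetic <- function(fixture = published_values()) {
  fx <- fixture
  g_asm <- pv(fx, "asm_gross_avoided_kha")
  nb_asm <- pv(fx, "asm_net_brazil_kha")
  bap_asm <- pv(fx, "asm_bap_displaced_kha")
  row_asm <- pv(fx, "asm_row_displaced_kha")
  yrs <- pv(fx, "period_years")
  g_gz <- g_asm + pv(fx, "gzdc_gross_added_kha")
  nb_gz <- pv(fx, "gzdc_net_brazil_kha")

  checks <- list(
    list("asm_annual_avoided", g_asm / yrs, pv(fx, "asm_annual_printed_kha"),
         "nearest", 1),
    list("asm_domestic_leakage",
         leakage_rate(g_asm - nb_asm, -g_asm),
         pv(fx, "asm_domestic_leakage_printed_pct"), "nearest", 1),
    list("asm_crossborder_leakage",
         leakage_rate(bap_asm + row_asm, -g_asm),
         pv(fx, "asm_crossborder_leakage_printed_pct"), "above", 1),
    list("gzdc_domestic_leakage",
         leakage_rate(g_gz - nb_gz, -g_gz),
         pv(fx, "gzdc_domestic_leakage_printed_pct"), "nearest", 1),
    list("gzdc_crossborder_leakage",
         leakage_rate(pv(fx, "gzdc_bap_displaced_kha") +
                        pv(fx, "gzdc_row_displaced_kha"), -g_gz),
         pv(fx, "gzdc_crossborder_leakage_printed_pct"), "nearest", 1),
    list("gzdc_gross_increase_over_asm",
         pv(fx, "gzdc_gross_added_kha") / g_asm * 100,
         pv(fx, "gzdc_gross_increase_printed_pct"), "within_1", 1),
    list("gzdc_net_brazil_soy_share",
         nb_gz / pv(fx, "soy_deforestation_2011_2016_kha") * 100,
         pv(fx, "gzdc_soy_share_printed_pct"), "nearest", 1),
    list("eu_amazon_cerrado_soy_share",
         pv(fx, "eu_amazon_cerrado_net_kha") /
           pv(fx, "soy_deforestation_2011_2016_kha") * 100,
         pv(fx, "eu_soy_biome_share_printed_pct"), "nearest", 1),
    list("eu_vs_gzdc_ghg_reduction",
         (pv(fx, "eu_ghg_saved_kt") - pv(fx, "gzdc_ghg_saved_kt")) /
           pv(fx, "gzdc_ghg_saved_kt") * 100,
         pv(fx, "eu_vs_gzdc_ghg_reduction_printed_pct"), "nearest", 1),
    list("eu_vs_gzdc_net_brazil_increase",
         (pv(fx, "eu_net_brazil_kha") - nb_gz) / nb_gz * 100,
         pv(fx, "eu_vs_gzdc_netbr_increase_printed_pct"), "nearest", 1),
    list("eu_vs_gzdc_net_global_increase",
         (pv(fx, "eu_net_global_kha") - pv(fx, "gzdc_net_global_kha")) /
           pv(fx, "gzdc_net_global_kha") * 100,
         pv(fx, "eu_vs_gzdc_netglobal_increase_printed_pct"), "nearest", 1),
    list("eu_annual_avoided", pv(fx, "eu_net_global_kha") / yrs,
         pv(fx, "eu_annual_printed_kha"), "nearest", 1),
    list("asm_ghg_global_share",
         pv(fx, "asm_ghg_saved_kt") * 1e3 /
           (pv(fx, "global_lucf_mt") * 1e6) * 100,
         pv(fx, "asm_ghg_global_share_printed_pct"), "nearest", 0.001),
    list("asm_ghg_brazil_share",
         pv(fx, "asm_ghg_saved_kt") * 1e3 /
           (pv(fx, "brazil_lucf_mt") * 1e6) * 100,
         pv(fx, "asm_ghg_brazil_share_printed_pct"), "nearest", 0.01)
  )
  out <- do.call(rbind, lapply(checks, function(ck) {
    comp <- ck[[2]]; printed <- ck[[3]]; rule <- ck[[4]]; prec <- ck[[5]]
    pass <- switch(rule,
      nearest = round(comp / prec) * prec == printed,
      within_1 = abs(comp - printed) <= 1,
      above = comp > printed & comp < printed + 1)
    data.frame(check = ck[[1]], computed = comp, printed = printed,
               rule = rule, pass = pass, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "all_pass") <- all(out$pass)
  out
}
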