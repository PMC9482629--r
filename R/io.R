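## World serialization: a directory of plain CSV tables plus a YAML config.
## Column schemas are documented in inst/extdata/world_schema.yaml.

#' Write a world to a directory of CSV tables
#'
#' Writes `municipalities.csv`, `companies.csv`, `trader_exports.csv`,
#' `land_cells.csv`, `sam.csv` (with account ids in the first column) and
#' `config.yaml`.
#'
#' @param world a `"soy_world"`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$municipalities,
                   file.path(dir, "municipalities.csv"), row.names = FALSE)
  utils::write.csv(world$companies, file.path(dir, "companies.csv"),
                   row.names = FALSE)
  utils::write.csv(world$trader_exports,
                   file.path(dir, "trader_exports.csv"), row.names = FALSE)
  utils::write.csv(world$sam$cells, file.path(dir, "land_cells.csv"),
                   row.names = FALSE)
  sam_df <- data.frame(account = rownames(world$sam$sam), world$sam$sam,
                       check.names = FALSE)
  utils::write.csv(sam_df, file.path(dir, "sam.csv"), row.names = FALSE)
  utils::write.csv(world$sam$sector_weights,
                   file.path(dir, "sector_weights.csv"), row.names = TRUE)
  cfg <- world$config
  yaml::write_yaml(list(
    regions = cfg$regions, roles = cfg$roles,
    sectors = as.list(cfg$sectors),
    n_municipalities = cfg$n_municipalities,
    n_companies = cfg$n_companies, n_aez = cfg$n_aez, seed = cfg$seed,
    destination_segmentation = cfg$destination_segmentation,
    domestic_use_frac = cfg$domestic_use_frac,
    region_scale = as.list(cfg$region_scale),
    elasticities = lapply(unclass(cfg$elasticities), function(x)
      if (is.null(names(x))) x else as.list(x))
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a world back from a directory
#'
#' @param dir a directory written by [write_world()].
#' @return a `"soy_world"`.
#' @export
read_world <- function(dir) {
  abort_if(!file.exists(file.path(dir, "config.yaml")),
           paste("no world found in", dir))
  y <- yaml::read_yaml(file.path(dir, "config.yaml"))
  el <- y$elasticities
  el <- lapply(el, function(x) if (is.list(x)) unlist(x) else x)
  config <- world_config(
    regions = unlist(y$regions), roles = y$roles,
    sectors = as.data.frame(y$sectors, stringsAsFactors = FALSE),
    n_municipalities = y$n_municipalities, n_companies = y$n_companies,
    n_aez = y$n_aez, seed = y$seed,
    destination_segmentation = y$destination_segmentation,
    domestic_use_frac = y$domestic_use_frac,
    elasticities = structure(el, class = "soy_elasticities"),
    region_scale = unlist(y$region_scale))
  munis <- utils::read.csv(file.path(dir, "municipalities.csv"),
                           stringsAsFactors = FALSE)
  companies <- utils::read.csv(file.path(dir, "companies.csv"),
                               stringsAsFactors = FALSE)
  exports <- utils::read.csv(file.path(dir, "trader_exports.csv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "land_cells.csv"),
                           stringsAsFactors = FALSE)
  rownames(cells) <- cells$cell_id
  sam_df <- utils::read.csv(file.path(dir, "sam.csv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(sam_df[, -1])
  rownames(m) <- sam_df$account
  sw <- as.matrix(utils::read.csv(file.path(dir, "sector_weights.csv"),
                                  row.names = 1, check.names = FALSE))
  sam <- structure(list(sam = m, accounts = sam_account_table(config, cells),
                        cells = cells, sector_weights = sw),
                   class = "soy_sam")
  structure(list(config = config, municipalities = munis,
                 companies = companies, trader_exports = exports, sam = sam),
            class = "soy_world")
}
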