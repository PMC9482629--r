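# Column schemas of the world directory written by write_world().
municipalities.csv:
  muni_id: municipality identifier (M0001, ...)
  biome: Amazon | Cerrado | Other
  aez_id: agro-ecological zone index (1..n_aez)
  forest_A_ha: forest sensu stricto (definition A), hectares
  forest_B_ha: forest plus natural grassland outside the Amazon (definition B)
  other_natural_ha: non-forest natural cover (includes grassland), ha
  grassland_ha: natural grassland component of other_natural_ha, ha
  cropland_ha: total cropland, ha
  pasture_ha: planted and natural pasture in use, ha
  soy_area_ha: soybean harvested area (<= cropland_ha), ha
  soy_production_t: soybean production, tonnes
  maize2_area_ha: second-harvest maize area (<= soy_area_ha), ha
  cattle_heads: cattle herd size
companies.csv:
  company_id: trader identifier (C01, ...)
  size_weight: relative size used to draw municipality portfolios
  asm_member: soy-moratorium signatory flag
  global_zdc: global voluntary zero-deforestation pledge flag (subset of ASM)
  w_EU / w_China / w_OtherDest: destination volume shares (sum to 1)
trader_exports.csv:
  muni_id: source municipality
  company_id: exporting company
  destination: EU | China | OtherDest
  volume_t: exported volume, tonnes (sums per municipality never exceed
    soy_production_t)
land_cells.csv:
  cell_id: REGION.biome.AEZk[.ZDC|.NoZDC] or REGION.cell for foreign regions
  region, biome, aez, compliant: cell coordinates and compliance flag
  area_forest / area_grass / area_othernat / area_pasture: cover areas, ha
  area_crop_<sector>: cropland by crop sector, ha
sam.csv:
  account: ACT.<sector>.<region> | LAB.<region> | CAP.<region> |
    LND.<cell>.<cover> | HH.<region>; remaining columns form the square
    balanced value matrix (row = receipts, column = outlays)
sector_weights.csv:
  row names: cell_id; columns: sectors; output/rent split weights
config.yaml:
  the world_config() fields, including elasticities
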