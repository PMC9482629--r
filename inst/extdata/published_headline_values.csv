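quantity,scenario,value,unit,flag,note
asm_gross_avoided_kha,ASM,409,kha,,gross avoided deforestation in the Amazon 2011-2016
asm_net_brazil_kha,ASM,194,kha,,net avoided deforestation within the policy country
asm_bap_displaced_kha,ASM,2,kha,upper_bound,spillover to the neighbouring frontier stated as below 2 kha
asm_row_displaced_kha,ASM,11,kha,,deforestation increase in the rest of the world
asm_net_global_kha,ASM,180,kha,,global net avoided deforestation
asm_ghg_saved_kt,ASM,153,ktCO2e,,avoided land-use-change GHG emissions
asm_domestic_leakage_printed_pct,ASM,53,pct,,within-country leakage rate as printed
asm_crossborder_leakage_printed_pct,ASM,3,pct,,cross-border leakage rate stated as just above 3
asm_annual_printed_kha,ASM,82,kha_per_yr,,annualized gross avoided deforestation
amazon_cerrado_net_asm_kha,ASM,238,kha,ambiguous,stated as about 23 percent of 847 kha but 238/847 is 28 percent; excluded from checks
gzdc_gross_added_kha,GlobalZDC,167,kha,,gross avoided deforestation added by global commitments
gzdc_net_brazil_kha,GlobalZDC,306,kha,,net avoided deforestation within the policy country
gzdc_cerrado_net_kha,GlobalZDC,39,kha,,net avoided deforestation in the Cerrado
gzdc_bap_displaced_kha,GlobalZDC,3,kha,,spillover to the neighbouring frontier
gzdc_row_displaced_kha,GlobalZDC,14,kha,,deforestation increase in the rest of the world
gzdc_net_global_kha,GlobalZDC,288,kha,,global net avoided deforestation
gzdc_ghg_saved_kt,GlobalZDC,220,ktCO2e,,avoided land-use-change GHG emissions
gzdc_domestic_leakage_printed_pct,GlobalZDC,47,pct,,within-country leakage rate as printed
gzdc_crossborder_leakage_printed_pct,GlobalZDC,3,pct,,combined cross-border leakage rate as printed
gzdc_gross_increase_printed_pct,GlobalZDC,40,pct,,gross forest savings relative to ASM-only as printed
gzdc_soy_share_printed_pct,GlobalZDC,36,pct,,net avoided share of observed soy-driven deforestation
eu_net_brazil_kha,EU,419,kha,,net avoided deforestation within the policy country
eu_net_global_kha,EU,398,kha,,worldwide net forest savings
eu_ghg_saved_kt,EU,297,ktCO2e,,avoided land-use-change GHG emissions
eu_domestic_leakage_printed_pct,EU,43,pct,,within-country leakage rate as printed
eu_amazon_cerrado_net_kha,EU,340,kha,,net forest savings in Amazon plus Cerrado
eu_soy_biome_share_printed_pct,EU,40,pct,,share of observed soy-driven deforestation in those biomes
eu_vs_gzdc_ghg_reduction_printed_pct,EU,35,pct,,extra GHG savings relative to global commitments
eu_vs_gzdc_netbr_increase_printed_pct,EU,37,pct,,increase in country forest savings relative to global commitments
eu_vs_gzdc_netglobal_increase_printed_pct,EU,38,pct,,increase in global net avoided deforestation
eu_annual_printed_kha,EU,80,kha_per_yr,,annualized global net forest savings
china_net_brazil_kha,China,429,kha,,net avoided deforestation within the policy country
china_net_global_kha,China,408,kha,,global net forest savings
china_ghg_saved_kt,China,300,ktCO2e,,avoided land-use-change GHG emissions
soy_deforestation_2011_2016_kha,reference,847,kha,,observed deforestation for soy in Amazon plus Cerrado 2011-2016
global_lucf_mt,reference,4018,MtCO2e,,global land-use-change and forestry emissions 2011-2016
brazil_lucf_mt,reference,1730,MtCO2e,,policy-country land-use-change and forestry emissions 2011-2016
period_years,reference,5,years,,length of the simulation horizon
asm_ghg_global_share_printed_pct,ASM,0.004,pct,,avoided emissions as share of global LUCF emissions
asm_ghg_brazil_share_printed_pct,ASM,0.01,pct,,avoided emissions as share of country LUCF emissions
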