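# Soy-moratorium signatory roster (editable configuration, not code).
# Pledge-year staging is ignored: all commitments are applied as if in force
# from the benchmark year onward.
asm_soy_exporters:
  - Abc Industria
  - ADM
  - Amaggi
  - Bunge
  - Cargill
  - Louis Dreyfus
  - Seara
  - Fiagril
  - Nidera
  - Noble
  - Cofco
  - Baldo
  - Imcopa
  - Agrex
  - CHS
  - Coamo
  - Engelhart CTP
  - Gavilon
  - Glencore
  - Invivo
  - Marubeni
  - Multigrain
  - Nova Agri
  - Olam
  - Perdue
  - Sodrugestvo
  - Timbro
  - Selecta
asm_members_not_exporting_from_amazon:
  - Binatural
  - JBS
  - Oleos menu
  - Agribrasil
  - Culturale
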