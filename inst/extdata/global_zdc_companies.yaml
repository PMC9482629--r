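# Global voluntary zero-deforestation pledgers (a subset of the moratorium
# signatories, plus one non-signatory), with pledge years for reference.
# Pledge-year staging is ignored in the scenarios.
global_zdc_companies:
  - {name: ADM, pledge_year: 2015}
  - {name: Amaggi, pledge_year: 2017}
  - {name: Bunge, pledge_year: 2015}
  - {name: Cargill, pledge_year: 2014}
  - {name: Louis Dreyfus, pledge_year: 2018}
  - {name: Cofco, pledge_year: 2019}
  - {name: Glencore, pledge_year: 2019}
  - {name: Denofa do Brazil, pledge_year: 2014}
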