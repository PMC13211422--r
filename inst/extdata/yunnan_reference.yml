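# Reference values for the eight-metal panel, agricultural soils, Yunnan Province.
# background: Yunnan Province soil background values (mg/kg)
# toxicity:   Hakanson toxicity response coefficients (unitless)
# screening:  agricultural-land screening values (mg/kg)
# control:    agricultural-land risk control values (mg/kg); absent where no
#             national threshold is specified (Cu, Ni, Zn)
# mdl:        method detection limits (mg/kg); representative values for the
#             standard regional-geochemistry analytical methods -- replace
#             with your laboratory's limits when known
# ref_element: conservative reference element for enrichment factors; the
#             background value is a regional constant the user should confirm
metals: [Hg, Cd, Pb, As, Cr, Cu, Ni, Zn]
background:
  Hg: 0.06
  Cd: 0.22
  Pb: 40.60
  As: 18.40
  Cr: 65.20
  Cu: 46.30
  Ni: 42.50
  Zn: 89.70
toxicity:
  Hg: 40
  Cd: 30
  Pb: 5
  As: 10
  Cr: 2
  Cu: 5
  Ni: 5
  Zn: 1
screening:
  Hg: 0.50
  Cd: 0.40
  Pb: 100.00
  As: 30.00
  Cr: 250.00
  Cu: 150.00
  Ni: 70.00
  Zn: 200.00
control:
  Hg: 2.50
  Cd: 2.00
  Pb: 500.00
  As: 150.00
  Cr: 850.00
mdl:
  Hg: 0.002
  Cd: 0.01
  Pb: 2.0
  As: 0.2
  Cr: 5.0
  Cu: 1.0
  Ni: 2.0
  Zn: 4.0
ref_element:
  name: Ti
  column: Ti
  background: 5400
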