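gene	panel
GAPDH	housekeeping
PGK1	housekeeping
ACT1	housekeeping
HSP60	housekeeping
CYTC	housekeeping
TPI1	housekeeping
CDC42	housekeeping
RPL5	housekeeping
DGA1	lipid
DGK1	lipid
LRO1	lipid
TGL3	lipid
FAA1	lipid
LCB1	lipid
ERG4	lipid
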