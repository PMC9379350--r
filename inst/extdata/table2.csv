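species,area_current_km2,area_future_km2,change_km2
Aconitum ferox,4664,3359,-1305
Aconitum spicatum,4010,3817,-193
Allium wallichii,5846,8147,2301
Astilbe rivularis,1706,1443,-263
Bergenia ciliata,7992,7647,-345
Bergenia purpurascens,1297,2247,950
Cinnamomum tamala,3982,5872,1890
Corydalis govaniana,6762,7346,584
Dactylorhiza hatagirea,1607,5169,3562
Daphne bholua,2972,2847,-125
Delphinium himalayae,2648,970,-1678
Dioscorea deltoidea,3544,5938,2394
Ephedra gerardiana,6943,6915,-28
Fritillaria cirrhosa,8754,1416,-7338
Hedychium spicatum,1572,3744,2172
Heracleum candicans,6603,3216,-3387
Nardostachys jatamansi,8684,8581,-103
Neopicrorhiza scrophulariiflora,4652,3899,-753
Paris polyphylla,6660,12047,5387
Podophyllum hexandrum,3178,827,-2351
Potentilla lineata,1967,2097,130
Rheum acuminatum,1040,1624,584
Rheum australe,6650,5030,-1620
Rhododendron anthopogon,11336,6891,-4445
Rubia manjith,1378,1111,-267
Swertia chirayita,522,319,-203
Swertia ciliata,5639,4058,-1581
Valeriana hardwickei,22683,13206,-9477
Zanthoxylum armatum,23515,21455,-2060
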