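species,family,life_form,elev_min_m,elev_max_m,n_occurrences
Aconitum ferox,Ranunculaceae,PH,2100,3800,25
Aconitum spicatum,Ranunculaceae,PH,1800,4200,22
Allium wallichii,Amaryllidaceae,PH,2400,4650,21
Astilbe rivularis,Saxifragaceae,PH,2000,3600,23
Bergenia ciliata,Saxifragaceae,PH,1000,3200,28
Bergenia purpurascens,Saxifragaceae,PH,3800,4700,28
Cinnamomum tamala,Lauraceae,T,450,2000,23
Corydalis govaniana,Papaveraceae,PH,3000,4800,31
Dactylorhiza hatagirea,Orchidaceae,PH,2800,3960,23
Daphne bholua,Thymelaeaceae,S,1800,3000,34
Delphinium himalayae,Ranunculaceae,PH,3000,4500,26
Dioscorea deltoidea,Dioscoreaceae,C,450,3100,25
Ephedra gerardiana,Ephedraceae,S,2400,4500,33
Fritillaria cirrhosa,Liliaceae,PH,3000,4600,31
Hedychium spicatum,Zingiberaceae,PH,1500,2100,26
Heracleum candicans,Apiaceae,PH,2200,3800,26
Nardostachys jatamansi,Caprifoliaceae,PH,3200,5000,56
Neopicrorhiza scrophulariiflora,Plantaginaceae,PH,3500,4800,103
Paris polyphylla,Melanthiaceae,PH,2000,3000,42
Podophyllum hexandrum,Berberidaceae,PH,3000,4500,22
Potentilla lineata,Rosaceae,PH,1600,4800,27
Rheum acuminatum,Polygonaceae,PH,3300,4200,26
Rheum australe,Polygonaceae,PH,3200,4200,23
Rhododendron anthopogon,Ericaceae,S,3000,4800,40
Rubia manjith,Rubiaceae,C,1200,2100,25
Swertia chirayita,Gentianaceae,AH,1500,2500,23
Swertia ciliata,Gentianaceae,AH,2800,4000,28
Valeriana hardwickei,Caprifoliaceae,PH,1200,4000,35
Zanthoxylum armatum,Rutaceae,S,1100,2500,79
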