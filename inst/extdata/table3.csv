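zone_id,area_current_km2,area_future_km2,change_km2
Annapurna Conservation Area,2813,1179,-1634
Api Nampa Conservation Area,207,110,-97
Dhorpatan Hunting Reserve,205,5,-200
Gaurishankar Conservation Area,1360,1458,98
Kangchenjunga Conservation Area,740,589,-151
Khaptad National Park,2,0,-2
Langtang National Park,1008,1024,16
Makalu Barun National Park,863,735,-128
Manaslu Conservation Area,627,444,-183
Rara National Park,1,4,3
Sagarmatha National Park,389,301,-88
Shey-Phoksundo National Park,462,177,-285
Shivapuri National Park,71,64,-7
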