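zone_id,area_current_km2,area_future_km2,change_km2
Eastern Himalayan alpine shrub and meadows,4720,3634,-1086
Eastern Himalayan broadleaf forests,2450,1824,-626
Eastern Himalayan subalpine conifer forests,3535,2569,-966
Himalayan subtropical broadleaf forests,7,12,5
Himalayan subtropical pine forests,617,783,166
Rock and Ice,903,742,-161
Western Himalayan alpine shrub and meadows,3335,374,-2961
Western Himalayan broadleaf forests,612,179,-433
Western Himalayan subalpine conifer forests,681,49,-632
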