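name,E_ads_calculated,E_ads_predicted_published,who_tef
"2,3,7,8-tetrachlorodibenzo-p-dioxin",0.958,0.733,1
"1,2,3,7,8-pentachlorodibenzo-p-dioxin",NA,0.599,1
"1,2,3,4,7,8-hexachlorodibenzo-p-dioxin",NA,-0.738,0.1
"1,2,3,6,7,8-hexachlorodibenzo-p-dioxin",NA,-0.749,0.1
"1,2,3,7,8,9-hexachlorodibenzo-p-dioxin",NA,0.095,0.1
"1,2,3,4,6,7,8-heptachlorodibenzo-p-dioxin",NA,-2.132,0.01
"1,2,3,4,6,7,8,9-octachlorodibenzo-p-dioxin",NA,-2.315,0.0003
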