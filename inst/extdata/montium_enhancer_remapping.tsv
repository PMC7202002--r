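Species	Attempted Remappings	Successful Remappings	% Successful Remappings	Reciprocal Best Hits (RBH)	% Successful Remappings that are RBH
D. asahinai	3,457	3,450	99.8	3,361	97.4
D. auraria	3,457	3,448	99.7	3,347	97.1
D. cf. bakoue	3,457	3,451	99.8	3,275	94.9
D. birchii	3,457	3,449	99.8	3,385	98.1
D. bocki	3,457	3,449	99.8	3,377	97.9
D. bunnanda	3,457	3,447	99.7	3,359	97.4
D. burlai	3,457	3,450	99.8	3,272	94.8
D. jambulina	3,457	3,450	99.8	3,327	96.4
D. kanapiae	3,457	3,449	99.8	3,406	98.8
D. kikkawai	3,457	3,449	99.8	3,377	97.9
D. lacteicornis	3,457	3,451	99.8	3,375	97.8
D. leontia	3,457	3,444	99.6	3,247	94.3
D. mayri	3,457	3,449	99.8	3,384	98.1
D. nikananu	3,457	3,451	99.8	3,221	93.3
D. pectinifera	3,457	3,449	99.8	3,383	98.1
D. punjabiensis	3,457	3,449	99.8	3,266	94.7
D. rufa	3,457	3,452	99.9	3,368	97.6
D. seguyi	3,457	3,444	99.6	3,334	96.8
D. serrata	3,457	3,447	99.7	3,350	97.2
D. tani	3,457	3,451	99.8	3,301	95.7
D. triauraria	3,457	3,448	99.7	3,258	94.5
D. truncata	3,457	3,449	99.8	3,366	97.6
D. vulcana	3,457	3,448	99.7	3,358	97.4
D. watanabei	3,457	3,449	99.8	3,147	91.2
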