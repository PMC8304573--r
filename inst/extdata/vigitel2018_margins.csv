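variable,level,inactive,active
total,all,31917,19098
gender,male,10243,8257
gender,female,21674,10841
age_group,20-29,2989,3010
age_group,30-39,3773,2937
age_group,40-49,4680,3087
age_group,50-59,6140,3834
age_group,60-69,6853,3736
age_group,70+,7807,3529
unit,Acre,1006,725
unit,Alagoas,1294,702
unit,Amapa,771,569
unit,Amazonas,1009,568
unit,Bahia,1347,622
unit,Ceara,1253,696
unit,Distrito Federal,900,957
unit,Espirito Santo,1218,780
unit,Goias,1264,717
unit,Maranhao,1190,760
unit,Mato Grosso,1210,761
unit,Mato Grosso do Sul,1297,688
unit,Minas Gerais,1209,725
unit,Paraiba,1284,698
unit,Parana,1286,736
unit,Para,1334,733
unit,Pernambuco,1334,649
unit,Piaui,1199,736
unit,Rio Grande do Norte,1219,738
unit,Rio Grande do Sul,1370,655
unit,Rio de Janeiro,1363,618
unit,Rondonia,1008,744
unit,Roraima,922,635
unit,Santa Catarina,1200,718
unit,Sergipe,1167,778
unit,Sao Paulo,1190,534
unit,Tocantins,1401,856
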