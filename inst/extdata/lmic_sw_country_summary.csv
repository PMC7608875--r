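region,country,year,n,prev_all,poor_pct,prev_poor,prev_nonpoor
Eastern Africa,Burundi,2016,6052,0.9,42.5,1.4,0.5
Eastern Africa,Comoro,2012,2387,3.9,47.1,4.6,3.2
Eastern Africa,Ethiopia,2016,8919,3.0,46.8,3.5,2.6
Eastern Africa,Kenya,2014,18656,1.0,45.2,1.3,0.7
Eastern Africa,Malawi,2016,5178,0.6,47.5,0.5,0.7
Eastern Africa,Mozambique,2011,9313,2.1,45.6,2.9,1.4
Eastern Africa,Rwanda,2015,3538,0.6,46.8,0.7,0.6
Eastern Africa,Tanzania,2016,8962,1.3,46.4,1.5,1.0
Eastern Africa,Uganda,2016,4413,1.4,43.2,1.9,1.0
Middle Africa,Angola,2016,6407,1.0,45.4,1.5,0.7
Middle Africa,Cameroon,2010,5033,1.9,44.3,3.1,0.8
Middle Africa,Chad,2015,9826,4.3,42.5,3.8,4.6
Middle Africa,Congo,2012,4475,1.6,47.8,2.1,1.1
Middle Africa,DRC,2014,8059,2.7,45.1,3.1,2.3
Middle Africa,Gabon,2012,3336,1.2,43.1,0.9,1.3
Northern Africa,Egypt,2014,13682,3.8,37.5,3.4,4.0
Southern Africa,Lesotho,2016,1312,0.7,42.3,1.4,0.2
Southern Africa,Namibia,2013,1558,2.2,47.3,3.1,1.3
Southern Africa,South Africa,2016,1082,0.5,47.5,0.6,0.4
Southern Africa,Zambia,2014,11407,2.1,47.7,2.3,1.9
Southern Africa,Zimbabwe,2015,4914,1.1,44.4,1.5,0.8
Western Africa,Benin,2018,12033,1.1,41.6,1.1,1.0
Western Africa,Burkina Faso,2010,6532,5.8,42.0,6.4,5.5
Western Africa,Cote d'Ivoire,2012,3200,1.8,49.4,1.9,1.8
Western Africa,Gambia,2013,3098,4.7,46.0,4.2,5.1
Western Africa,Ghana,2014,2720,0.7,43.2,1.1,0.4
Western Africa,Guinea,2012,3085,3.7,46.1,4.1,3.4
Western Africa,Liberia,2013,3171,2.2,47.8,2.5,1.9
Western Africa,Mali,2013,4306,5.1,42.5,6.2,4.2
Western Africa,Niger,2012,4771,6.2,39.5,6.7,5.8
Western Africa,Nigeria,2013,24505,8.8,43.9,10.6,7.5
Western Africa,Senegal,2017,10787,1.5,46.8,2.1,1.0
Western Africa,Sierra Leone,2013,4069,3.8,47.1,3.9,3.7
Western Africa,Togo,2014,3185,1.6,43.1,1.7,1.5
Central Asia,Kyrgyz,2012,4016,1.1,39.2,1.2,1.0
Central Asia,Tajikistan,2017,5867,1.8,39.4,1.4,2.1
South-Eastern Asia,Myanmar,2016,4197,1.4,52.1,1.4,1.4
South-Eastern Asia,Timor-Leste,2016,5718,9.9,39.9,12.3,8.4
Southern Asia,Bangladesh,2014,6965,3.1,41.5,3.6,2.7
Southern Asia,India,2016,225002,7.4,47.2,8.2,6.8
Southern Asia,Maldives,2016,2362,2.0,44.7,2.0,1.9
Southern Asia,Nepal,2016,2369,1.9,42.2,2.1,1.7
Southern Asia,Pakistan,2018,4151,2.3,42.0,3.3,1.6
Southern Asia,Cambodia,2014,4324,2.4,44.4,2.6,2.3
Western Asia,Armenia,2016,1561,1.5,40.4,1.9,1.2
Central America,Guatemala,2012,11744,0.1,48.8,0.1,0.1
Central America,Honduras,2016,9973,0.3,45.9,0.3,0.2
South America,Peru,2012,9213,0.1,47.5,0.1,0.1
Southern Europe,Albania,2018,2462,0.5,44.5,0.7,0.3
Caribbean,Dominica,2013,3187,0.6,45.6,0.4,0.6
Caribbean,Haiti,2016,5598,0.9,46.6,1.2,0.6
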