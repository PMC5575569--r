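location,route_type,route_id,event_label,dogs_per_km,pct_lactating,pct_bcs1,pct_bcs1or2,pct_skin
Bosnia,hotspot,Kljuc,16 June,9.07,0,0,0,4.2
Bosnia,hotspot,Mrkonjic Grad,16 June,0.78,0,0,0,
Bosnia,hotspot,Trebinje,16 September,1.49,11.1,0,17.9,10.7
Bogatic municipality Serbia,representative,Badovinci,16 May,0.855,50,0,4.2,0
Bogatic municipality Serbia,representative,Bogatic,16 May,0.6,33.3,0,11.1,0
Bogatic municipality Serbia,representative,Crna Bara,16 May,0.52,0,0,0,0
Bogatic municipality Serbia,representative,Dublje,16 May,0.145,0,0,5.6,0
Bogatic municipality Serbia,representative,Klenje,16 May,0.72,0,0,18.8,0
Constanta county Romania,hotspot,Cernavoda,16 July,4.79,6.8,0,8.3,1.4
Constanta county Romania,representative,Agigea,16 September,6.52,25.9,0,44.4,18.5
Panama City Panama,representative,San Miguelito,November-December 2013,5.62,11.1,4,38.7,28.2
Panama City Panama,representative,Casco Viejo,November-December 2013,1.07,8,2.3,15.9,11.8
Panama City Panama,representative,Juan Diaz,November-December 2013,1.87,0,5.1,22,22.8
Panama City Panama,representative,Kuna Nega,November-December 2013,5.83,4.6,2.5,18.6,14.5
Puerto Rico,representative,Aguadilla,14 March,1.13,0,0,2.6,9.4
Puerto Rico,representative,Fajardo/Ceiba,14 March,1.73,4.3,0,11.3,22.7
Puerto Rico,representative,Toa Alta,14 March,1.73,0,0,2,9.5
San Jose Costa Rica,representative,San Jose,14 June,2.59,8.8,0,5.6,6.2
San Jose Costa Rica,representative,Heredia Y Belen,14 June,1.5,0,0,2,6.3
San Jose Costa Rica,representative,Cartago,14 June,3.09,11.1,1,9,5.1
San Jose Costa Rica,representative,Alajuela,14 June,2.28,20,1.1,9.6,6.2
San Jose Costa Rica,representative,Rancho Redondo,14 June,4.09,6.5,1.3,6.4,2
Kathmandu Nepal,representative,Zone 1,16 March,12.3,12.3,0,,0.9
Kathmandu Nepal,representative,Zone 2,16 March,27.14,6.2,0.1,,3.3
Kathmandu Nepal,representative,Zone 3,16 March,12.28,6,0,,2.7
Kathmandu Nepal,representative,Zone 4,16 March,14.41,6.6,0.1,,2.6
Kathmandu Nepal,representative,Zone 5,16 March,15.66,4.1,0.1,,3
Kathmandu Nepal,representative,Zone 6,16 March,8.4,8.3,0,,6.5
Kathmandu Nepal,representative,Zone 7,16 March,11.37,20.3,0,,1.8
Kathmandu Nepal,representative,Zone 8,16 March,11.76,10.3,0,,0.9
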