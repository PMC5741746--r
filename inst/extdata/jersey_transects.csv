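site,year,habitat,area_ha,n_visits,acos,transect_km,detected
A,2015,scrub,8.10,3,39,2.91,0
B,2014,scrub,75.91,8,90,6.07,0
C,2014,dune grassland,36.99,8,117,6.40,1
C,2015,dune grassland,36.50,6,238,10.53,1
D,2014,scrub,23.19,8,72,3.41,0
E,2014,amenity grassland,29.63,8,34,1.12,0
F,2014,dune grassland,65.72,8,195,8.77,1
F,2015,dune grassland,65.64,6,436,19.10,1
G,2014,scrub,38.81,8,81,4.19,1
H,2014,rough grassland,29.53,8,45,4.51,0
I,2015,amenity grassland,3.89,4,51,1.76,0
J,2014,scrub,10.48,8,60,2.20,1
J,2015,scrub,10.48,6,110,4.86,1
K,2014,scrub,15.77,8,42,2.80,0
L,2014,scrub,37.54,8,90,6.07,1
L,2015,scrub,3.61,6,46,1.46,1
M,2014,rough grassland,1.01,8,6,0.28,1
M,2015,rough grassland,1.01,5,18,0.44,1
N,2014,amenity grassland,36.06,8,36,1.62,0
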