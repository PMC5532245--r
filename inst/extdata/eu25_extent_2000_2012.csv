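# EU-25 land-cover extent account inputs, 2000-2012 accounting period:
# published opening areas, net area flows and closing areas (km2) per SEEA class.
# Empty cells mark classes reported as absent (mangrove; permanent snow and
# glaciers carries no published value). A few printed closings differ by 1 km2
# from opening + net (source-table rounding); printed values are kept verbatim.
seea_code,opening_km2,net_km2,closing_km2
1,99128,8354,107482
2,941477,-8676,932801
3,88041,1596,89636
4,410037,-2921,407116
5,383142,-1228,381913
6,1270472,4049,1274521
7,,,
8,143195,-1186,142009
9,76508,-565,75942
10,17298,-74,17225
11,5054,-182,4872
12,,,
13,155996,815,156811
14,2106,19,2125
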