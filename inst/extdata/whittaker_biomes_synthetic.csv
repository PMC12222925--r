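biome_id,biome_name,vertex,temp_c,precip_mm
1,Tundra,1,-15,0
1,Tundra,2,-5,0
1,Tundra,3,-5,1000
2,Boreal forest,1,-5,250
2,Boreal forest,2,3,250
2,Boreal forest,3,3,1800
2,Boreal forest,4,-5,1000
3,Temperate seasonal forest,1,3,600
3,Temperate seasonal forest,2,20,600
3,Temperate seasonal forest,3,20,1500
3,Temperate seasonal forest,4,3,1500
4,Temperate rain forest,1,3,1500
4,Temperate rain forest,2,20,1500
4,Temperate rain forest,3,20,3500
4,Temperate rain forest,4,3,1800
5,Tropical rain forest,1,20,2300
5,Tropical rain forest,2,30,2300
5,Tropical rain forest,3,30,4500
5,Tropical rain forest,4,20,3500
6,Tropical seasonal forest/savanna,1,20,500
6,Tropical seasonal forest/savanna,2,30,500
6,Tropical seasonal forest/savanna,3,30,2300
6,Tropical seasonal forest/savanna,4,20,2300
7,Subtropical desert,1,20,0
7,Subtropical desert,2,30,0
7,Subtropical desert,3,30,500
7,Subtropical desert,4,20,500
8,Temperate grassland/desert,1,-5,0
8,Temperate grassland/desert,2,20,0
8,Temperate grassland/desert,3,20,250
8,Temperate grassland/desert,4,-5,250
9,Woodland/shrubland,1,3,250
9,Woodland/shrubland,2,20,250
9,Woodland/shrubland,3,20,600
9,Woodland/shrubland,4,3,600
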