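species,family,n_individuals,body_mass_g,skull_mass_g,skull_length_mm,jaw_muscle_mass_g,bite_force_N,bf_bm_ratio_printed
Cacatua_alba,Cacatuidae,3,570.0,12.6,78.0,4.8,180.4,0.316
Cacatua_galerita,Cacatuidae,3,720.4,12.0,76.9,6.8,167.3,0.232
Cacatua_moluccensis,Cacatuidae,1,835.0,18.7,91.3,6.6,264.7,0.317
Melopsittacus_undulatus,Psittaculidae,1,29.0,0.4,27.3,0.1,12.4,0.428
Psittacula_eupatria,Psittaculidae,1,214.0,5.0,59.0,2.7,105.7,0.480
Psittacula_krameri,Psittaculidae,4,116.1,2.0,45.8,0.7,34.6,0.298
Ara_ararauna,Psittacidae,3,1125.0,20.4,106.4,7.1,201.1,0.179
Ara_chloropterus,Psittacidae,3,1214.0,35.6,117.8,11.8,374.9,0.309
Ara_macao,Psittacidae,1,1015.0,31.5,103.9,6.5,443.8,0.437
Amazona_aestiva,Psittacidae,2,451.0,6.4,65.6,1.8,117.7,0.261
Amazona_amazonica,Psittacidae,3,370.0,6.6,67.6,1.8,83.1,0.225
Amazona_auropalliata,Psittacidae,1,476.9,6.5,65.6,2.4,93.6,0.196
Amazona_autumnalis,Psittacidae,2,416.0,5.7,72.2,2.0,84.9,0.204
Amazona_farinosa,Psittacidae,1,626.0,9.7,79.8,3.3,136.1,0.217
Amazona_oratrix,Psittacidae,1,517.0,9.6,72.4,1.5,123.0,0.238
Amazona_ochrocephala,Psittacidae,3,476.9,5.5,65.3,2.1,77.3,0.162
Myiopsitta_monachus,Psittacidae,3,120.0,1.3,41.8,0.5,21.3,0.178
Poicephalus_senegalus,Psittacidae,2,147.0,2.7,49.6,1.0,34.8,0.237
Psittacus_erithacus,Psittacidae,5,333.0,6.8,71.5,2.7,84.1,0.252
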