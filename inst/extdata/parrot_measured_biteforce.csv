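species,n_individuals,body_mass_g,measured_bite_force_N,measured_ratio_printed,predicted_bite_force_N,predicted_ratio_printed
Anodorhynchus_hyacinthinus,7,1253.7,538.86,0.4298,466.81,0.3723
Ara_ararauna,13,1040.2,259.77,0.2497,209.78,0.2017
Ara_chloropterus,9,1140.8,350.22,0.307,393.44,0.3449
Ara_glaucogularis,1,866,290,0.3349,NA,NA
Ara_macao,5,1000.6,224.8,0.2247,286.74,0.2866
Ara_militaris,5,809.8,237.7,0.2935,222.77,0.2751
Ara_severus,1,400,59,0.1475,NA,NA
Aratinga_canicularis,1,85,53.6,0.6306,38.78,0.4562
Trichoglossus_haematodus,6,120,52.45,0.4371,23.97,0.1998
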