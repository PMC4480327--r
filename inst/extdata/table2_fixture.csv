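species,field_code,value_min,value_max,n_entries,units
Abutilon theophrasti,COMPHEIGHT,97,300,10,cm
Abutilon theophrasti,COMPHYP_1,0.9,60.3,23,% loss per plant m-2
Abutilon theophrasti,FECUNDITY_2,2.48,3.31,2,Ln seeds per g
Abutilon theophrasti,GERMBASE,6.2,6.5,2,degC
Abutilon theophrasti,EMDEPTH_2,12,,1,cm
Abutilon theophrasti,EMTOT_1,1.5,1.9,3,%
Abutilon theophrasti,SEEDPER_2,0.79,,1,years
Abutilon theophrasti,SEEDWEIGHT,9.0,10.6,4,mg
Alopecurus myosuroides,COMPHEIGHT,115,,1,cm
Alopecurus myosuroides,COMPHYP_1,0.02,1.43,17,% loss per plant m-2
Alopecurus myosuroides,FECUNDITY_2,4.93,,1,Ln seeds per g
Alopecurus myosuroides,GERMBASE,0.0,,1,degC
Alopecurus myosuroides,EMDEPTH_2,8,12,2,cm
Alopecurus myosuroides,EMTOT_1,40.4,,1,%
Alopecurus myosuroides,SEEDPER_2,0.34,1.85,6,years
Alopecurus myosuroides,SEEDWEIGHT,1.55,2.19,6,mg
Ambrosia artemisiifolia,COMPHEIGHT,120,180,3,cm
Ambrosia artemisiifolia,COMPHYP_1,7.07,25.9,7,% loss per plant m-2
Ambrosia artemisiifolia,GERMBASE,5.0,6.0,2,degC
Ambrosia artemisiifolia,EMDEPTH_2,4,6.5,3,cm
Ambrosia artemisiifolia,SEEDWEIGHT,1.72,3.99,10,mg
Apera spica-venti,COMPHEIGHT,100,,1,cm
Apera spica-venti,COMPHYP_1,0.08,3.4,7,% loss per plant m-2
Apera spica-venti,FECUNDITY_2,6.55,,1,Ln seeds per g
Apera spica-venti,EMDEPTH_2,1,3.5,2,cm
Apera spica-venti,EMTOT_1,30,,1,%
Apera spica-venti,SEEDPER_2,0.43,,1,years
Apera spica-venti,SEEDWEIGHT,0.1,0.1,2,mg
Anisantha sterilis,COMPHEIGHT,70,100,5,cm
Anisantha sterilis,FECUNDITY_2,4.51,,1,Ln seeds per g
Anisantha sterilis,GERMBASE,3.0,,1,degC
Anisantha sterilis,EMDEPTH_2,4.5,13,4,cm
Anisantha sterilis,EMTOT_1,65,,1,%
Anisantha sterilis,SEEDPER_2,1.0,,1,years
Anisantha sterilis,SEEDWEIGHT,5.26,8.37,7,mg
Centaurea cyanus,COMPHEIGHT,60,80,7,cm
Centaurea cyanus,COMPHYP_1,0.11,0.25,3,% loss per plant m-2
Centaurea cyanus,GERMBASE,1.7,5.0,4,degC
Centaurea cyanus,EMDEPTH_2,3,10,7,cm
Centaurea cyanus,EMTOT_1,11,20,3,%
Centaurea cyanus,SEEDPER_2,5.0,,1,years
Centaurea cyanus,SEEDWEIGHT,3.28,4.80,7,mg
Chenopodium album,COMPHEIGHT,60,,1,cm
Chenopodium album,FECUNDITY_2,6.04,7.36,4,Ln seeds per g
Chenopodium album,GERMBASE,5.8,,1,degC
Chenopodium album,EMDEPTH_2,6,,1,cm
Chenopodium album,EMTOT_1,7.8,15.8,2,%
Chenopodium album,SEEDWEIGHT,0.49,0.79,6,mg
Echinochloa crus-galli,COMPHEIGHT,75,110,2,cm
Echinochloa crus-galli,FECUNDITY_2,6.15,,1,Ln seeds per g
Echinochloa crus-galli,GERMBASE,6.2,13,5,degC
Echinochloa crus-galli,EMDEPTH_2,7.5,,1,cm
Echinochloa crus-galli,EMTOT_1,0,100,4,%
Echinochloa crus-galli,SEEDPER_2,0.69,,1,years
Echinochloa crus-galli,SEEDWEIGHT,0.89,2.35,6,mg
Fallopia convolvulus,COMPHEIGHT,64,,1,cm
Fallopia convolvulus,FECUNDITY_2,4.55,,1,Ln seeds per g
Fallopia convolvulus,EMDEPTH_2,9.5,19,2,cm
Fallopia convolvulus,SEEDWEIGHT,5.06,7.0,4,mg
Galium aparine,COMPHEIGHT,67,180,3,cm
Galium aparine,COMPHYP_1,0.09,23,44,% loss per plant m-2
Galium aparine,FECUNDITY_2,3.12,5.09,3,Ln seeds per g
Galium aparine,GERMBASE,0.0,,1,degC
Galium aparine,EMDEPTH_2,10,,1,cm
Galium aparine,EMTOT_1,58,,1,%
Galium aparine,SEEDPER_2,0.76,1.90,3,years
Galium aparine,SEEDWEIGHT,6.64,13.06,5,mg
Papaver rhoeas,COMPHEIGHT,88,,1,cm
Papaver rhoeas,COMPHYP_1,0.1,,1,% loss per plant m-2
Papaver rhoeas,FECUNDITY_2,6.38,7.03,2,Ln seeds per g
Papaver rhoeas,GERMBASE,1.0,,1,degC
Papaver rhoeas,EMTOT_1,3,70,2,%
Papaver rhoeas,SEEDPER_2,5,44,2,years
Papaver rhoeas,SEEDWEIGHT,0.07,0.20,4,mg
Poa annua,COMPHEIGHT,38,,1,cm
Poa annua,EMTOT_1,35,,1,%
Poa annua,SEEDWEIGHT,0.19,0.48,11,mg
Polygonum aviculare,COMPHEIGHT,58,,1,cm
Polygonum aviculare,FECUNDITY_2,4.66,,1,Ln seeds per g
Polygonum aviculare,GERMBASE,0.0,8.0,2,degC
Polygonum aviculare,EMDEPTH_2,3,16,2,cm
Polygonum aviculare,EMTOT_1,32,,1,%
Polygonum aviculare,SEEDWEIGHT,0.68,3.0,7,mg
Persicaria lapathifolia,GERMBASE,1.7,,1,degC
Persicaria lapathifolia,EMDEPTH_2,6.5,,1,cm
Persicaria lapathifolia,EMTOT_1,50.1,,1,%
Persicaria lapathifolia,SEEDWEIGHT,1.50,2.91,6,mg
Raphanus raphanistrum,COMPHEIGHT,200,,1,cm
Raphanus raphanistrum,COMPHYP_1,0.51,1.71,6,% loss per plant m-2
Raphanus raphanistrum,GERMBASE,5,,1,degC
Raphanus raphanistrum,EMTOT_1,1.4,10.4,4,%
Raphanus raphanistrum,SEEDPER_2,1.0,1.0,2,years
Raphanus raphanistrum,SEEDWEIGHT,2.10,4.76,3,mg
Sinapis arvensis,COMPHEIGHT,93,99.5,3,cm
Sinapis arvensis,COMPHYP_1,0.3,7.0,4,% loss per plant m-2
Sinapis arvensis,FECUNDITY_2,3.6,4.93,3,Ln seeds per g
Sinapis arvensis,GERMBASE,10,,1,degC
Sinapis arvensis,EMTOT_1,20,80,4,%
Sinapis arvensis,SEEDPER_2,2.3,,1,years
Sinapis arvensis,SEEDWEIGHT,0.92,2.33,7,mg
Solanum nigrum,COMPHEIGHT,24.9,78.1,4,cm
Solanum nigrum,FECUNDITY_2,7.34,,1,Ln seeds per g
Solanum nigrum,GERMBASE,7.5,11.5,4,degC
Solanum nigrum,EMDEPTH_2,6,15,2,cm
Solanum nigrum,SEEDPER_2,0.86,,1,years
Solanum nigrum,SEEDWEIGHT,0.70,1.02,8,mg
Stellaria media,COMPHEIGHT,61.5,,1,cm
Stellaria media,COMPHYP_1,0.016,4.2,32,% loss per plant m-2
Stellaria media,FECUNDITY_2,5.2,6.46,4,Ln seeds per g
Stellaria media,GERMBASE,1.4,4.7,2,degC
Stellaria media,EMDEPTH_2,5,10.5,4,cm
Stellaria media,EMTOT_1,1.7,30,3,%
Stellaria media,SEEDPER_2,1.46,1.7,2,years
Stellaria media,SEEDWEIGHT,0.33,0.67,9,mg
Tripleurospermum inodorum,COMPHEIGHT,100,109,2,cm
Tripleurospermum inodorum,COMPHYP_1,1.31,,1,% loss per plant m-2
Tripleurospermum inodorum,FECUNDITY_2,6.31,6.67,3,Ln seeds per g
Tripleurospermum inodorum,GERMBASE,1.9,,1,degC
Tripleurospermum inodorum,EMDEPTH_2,8,,1,cm
Tripleurospermum inodorum,SEEDPER_2,1.6,,1,years
Tripleurospermum inodorum,SEEDWEIGHT,0.27,0.74,15,mg
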