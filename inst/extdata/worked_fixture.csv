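"patient_id","age","sex","ais_head_neck","ais_face","ais_chest","ais_abdomen","ais_extremities","ais_external","gcs","asa","sbp","prbc_pre_icu","icu_admitted","mechanism","transfer_status","region_of_hospital","died_in_hospital","los"
"W01_all_criteria",85,"male",5,0,4,3,0,0,3,4,120,TRUE,TRUE,"low_fall","primary","europe",TRUE,
"W02_no_criteria",70,"male",0,0,3,0,0,0,15,2,120,FALSE,TRUE,"low_fall","primary","europe",FALSE,
"W03_only_age",82,"male",0,0,3,0,0,0,15,2,120,FALSE,TRUE,"low_fall","primary","europe",FALSE,
"W04_only_ais",70,"male",4,0,0,0,0,0,15,2,120,FALSE,TRUE,"low_fall","primary","europe",FALSE,
"W05_only_transfusion",70,"male",0,0,3,0,0,0,15,2,120,TRUE,TRUE,"low_fall","primary","europe",FALSE,
"W06_only_asa",70,"male",0,0,3,0,0,0,15,3,120,FALSE,TRUE,"low_fall","primary","europe",FALSE,
"W07_only_gcs",70,"male",0,0,3,0,0,0,13,2,120,FALSE,TRUE,"low_fall","primary","europe",FALSE,
"W08_under_65",64,"male",5,0,0,0,0,0,15,2,120,FALSE,TRUE,"low_fall","primary","europe",TRUE,
"W09_missing_transfusion",75,"male",0,0,4,0,0,0,15,2,120,,TRUE,"low_fall","primary","europe",FALSE,
"W10_minor_no_icu",70,"male",0,0,0,0,2,0,15,2,120,FALSE,FALSE,"low_fall","primary","europe",FALSE,
"W11_transfer_in",75,"male",0,0,3,0,0,0,15,2,120,FALSE,TRUE,"low_fall","transfer_in","europe",FALSE,
"W12_gtos_showcase",80,"male",5,0,4,3,0,0,14,2,120,TRUE,TRUE,"low_fall","primary","europe",TRUE,
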