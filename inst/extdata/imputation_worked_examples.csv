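person_id,age,sex,pregnant,menopausal,iron_mg_day,red_meat_g_day,red_meat_iron_mg_day,expected_pregnant,expected_menopausal,expected_excluded
w01,52,female,no,unknown,10,20,0.4,no,yes,FALSE
w02,30,female,unknown,no,11,15,0.3,yes,no,TRUE
w03,16,female,unknown,no,9,10,0.2,no,no,FALSE
w04,45,female,no,unknown,12,25,0.5,no,no,FALSE
w05,60,female,unknown,yes,10,30,0.6,no,yes,FALSE
w06,33,female,yes,no,13,20,0.4,yes,no,TRUE
w07,40,female,unknown,unknown,10,10,0.2,yes,no,TRUE
w08,55,female,unknown,unknown,11,20,0.4,no,yes,FALSE
w09,40,male,no,not_applicable,14,40,0.8,no,not_applicable,FALSE
w10,35,female,yes,yes,12,15,0.3,yes,yes,TRUE
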