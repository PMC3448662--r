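patient_id,indication,annual_dose_mg
P001,chronic_liver_disease,5200
P002,chronic_liver_disease,1000
P003,chronic_liver_disease,600
P004,chronic_liver_disease,2000
P005,chronic_liver_disease,1000
P006,chronic_liver_disease,1000
P007,chronic_liver_disease,2000
P008,chronic_liver_disease,600
P009,chronic_liver_disease,2600
P010,chronic_liver_disease,800
P011,chronic_liver_disease,2000
P012,chronic_liver_disease,3000
P013,chronic_liver_disease,1000
P014,chronic_liver_disease,600
P015,chronic_liver_disease,1000
P016,chronic_liver_disease,400
P017,chronic_liver_disease,600
P018,chronic_liver_disease,1000
P019,chronic_liver_disease,1000
P020,chronic_liver_disease,2000
P021,chronic_liver_disease,1000
P022,chronic_liver_disease,200
P023,chronic_liver_disease,800
P024,chronic_liver_disease,1800
P025,chronic_liver_disease,3000
P026,chronic_liver_disease,1000
P027,chronic_liver_disease,600
P028,chronic_liver_disease,400
P029,chronic_liver_disease,1000
P030,chronic_liver_disease,800
P031,chronic_liver_disease,1000
P032,chronic_liver_disease,1000
P033,chronic_liver_disease,2000
P034,chronic_liver_disease,800
P035,chronic_liver_disease,2000
P036,chronic_liver_disease,800
P037,chronic_liver_disease,1000
P038,chronic_liver_disease,200
P039,chronic_liver_disease,400
P040,chronic_liver_disease,800
P041,chronic_liver_disease,600
P042,chronic_liver_disease,1000
P043,chronic_liver_disease,200
P044,chronic_liver_disease,1000
P045,chronic_liver_disease,200
P046,chronic_liver_disease,1000
P047,chronic_liver_disease,1000
P048,chronic_liver_disease,1800
P049,chronic_liver_disease,1000
P050,chronic_liver_disease,1000
P051,chronic_liver_disease,1000
P052,chronic_liver_disease,800
P053,chronic_liver_disease,2600
P054,chronic_liver_disease,800
P055,chronic_liver_disease,800
P056,inflammatory_bowel_disease,200
P057,inflammatory_bowel_disease,600
P058,inflammatory_bowel_disease,1000
P059,inflammatory_bowel_disease,1000
P060,inflammatory_bowel_disease,400
P061,inflammatory_bowel_disease,1000
P062,inflammatory_bowel_disease,1000
P063,inflammatory_bowel_disease,1000
P064,inflammatory_bowel_disease,800
P065,inflammatory_bowel_disease,400
P066,inflammatory_bowel_disease,1000
P067,inflammatory_bowel_disease,600
P068,inflammatory_bowel_disease,800
P069,inflammatory_bowel_disease,1000
P070,inflammatory_bowel_disease,800
P071,inflammatory_bowel_disease,1000
P072,inflammatory_bowel_disease,1000
P073,inflammatory_bowel_disease,800
P074,inflammatory_bowel_disease,1000
P075,inflammatory_bowel_disease,1000
P076,inflammatory_bowel_disease,1000
P077,inflammatory_bowel_disease,200
P078,angiodysplasia,800
P079,angiodysplasia,1000
P080,angiodysplasia,1000
P081,angiodysplasia,1000
P082,angiodysplasia,1000
P083,angiodysplasia,800
P084,angiodysplasia,400
P085,angiodysplasia,800
P086,angiodysplasia,1000
P087,angiodysplasia,600
P088,angiodysplasia,1000
P089,angiodysplasia,600
P090,other,800
P091,other,800
P092,other,400
P093,other,800
P094,other,200
P095,other,800
P096,other,400
P097,other,600
P098,other,600
P099,other,1000
P100,other,600
P101,other,2000
P102,other,2000
P103,other,600
P104,other,1800
P105,other,800
P106,other,800
P107,other,1000
P108,other,400
P109,other,1000
P110,other,600
P111,other,1000
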