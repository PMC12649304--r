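"drug_id","dose_ug","ee_dose_ug","bmi_group","inducer","n_virtual","seed","is_reference"
"DRSP",3000,20,"25to30","CBZ400",100,19,FALSE
"DRSP",3000,20,"25to30","none",100,7,TRUE
"DRSP",3000,20,"25to30","RIF600",100,31,FALSE
"DRSP",3000,20,"ge30","CBZ400",100,23,FALSE
"DRSP",3000,20,"ge30","none",100,11,TRUE
"DRSP",3000,20,"ge30","RIF600",100,35,FALSE
"DRSP",3000,20,"lt25","CBZ400",100,15,FALSE
"DRSP",3000,20,"lt25","none",100,3,TRUE
"DRSP",3000,20,"lt25","RIF600",100,27,FALSE
"DRSP",3000,30,"25to30","CBZ400",100,20,FALSE
"DRSP",3000,30,"25to30","none",100,8,TRUE
"DRSP",3000,30,"25to30","RIF600",100,32,FALSE
"DRSP",3000,30,"ge30","CBZ400",100,24,FALSE
"DRSP",3000,30,"ge30","none",100,12,TRUE
"DRSP",3000,30,"ge30","RIF600",100,36,FALSE
"DRSP",3000,30,"lt25","CBZ400",100,16,FALSE
"DRSP",3000,30,"lt25","none",100,4,TRUE
"DRSP",3000,30,"lt25","RIF600",100,28,FALSE
"LNG",100,20,"25to30","CBZ400",100,17,FALSE
"LNG",100,20,"25to30","none",100,5,TRUE
"LNG",100,20,"25to30","RIF600",100,29,FALSE
"LNG",100,20,"ge30","CBZ400",100,21,FALSE
"LNG",100,20,"ge30","none",100,9,TRUE
"LNG",100,20,"ge30","RIF600",100,33,FALSE
"LNG",100,20,"lt25","CBZ400",100,13,FALSE
"LNG",100,20,"lt25","none",100,1,TRUE
"LNG",100,20,"lt25","RIF600",100,25,FALSE
"LNG",150,30,"25to30","CBZ400",100,18,FALSE
"LNG",150,30,"25to30","none",100,6,TRUE
"LNG",150,30,"25to30","RIF600",100,30,FALSE
"LNG",150,30,"ge30","CBZ400",100,22,FALSE
"LNG",150,30,"ge30","none",100,10,TRUE
"LNG",150,30,"ge30","RIF600",100,34,FALSE
"LNG",150,30,"lt25","CBZ400",100,14,FALSE
"LNG",150,30,"lt25","none",100,2,TRUE
"LNG",150,30,"lt25","RIF600",100,26,FALSE
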