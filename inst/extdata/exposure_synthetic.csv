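"drug_id","dose_ug","ee_dose_ug","bmi_group","inducer","cavg_ng_ml","gcv_percent"
"LNG",30,0,"lt25","none",0.54,30
"LNG",90,30,"lt25","none",2.18,30
"LNG",100,20,"lt25","none",2.42,30
"LNG",150,30,"lt25","none",3.63,30
"DRSP",500,20,"lt25","none",5.465,30
"DRSP",500,30,"lt25","none",5.465,30
"DRSP",1000,20,"lt25","none",10.93,30
"DRSP",1000,30,"lt25","none",10.93,30
"DRSP",2000,20,"lt25","none",21.86,30
"DRSP",2000,30,"lt25","none",21.86,30
"DRSP",3000,20,"lt25","none",32.79,30
"DRSP",3000,30,"lt25","none",32.79,30
"DRSP",4000,20,"lt25","none",43.72,30
"DRSP",4000,30,"lt25","none",43.72,30
"LNG",30,0,"lt25","CBZ400",0.297,30
"LNG",90,30,"lt25","CBZ400",1.199,30
"LNG",100,20,"lt25","CBZ400",1.331,30
"LNG",150,30,"lt25","CBZ400",1.9965,30
"DRSP",500,20,"lt25","CBZ400",3.00575,30
"DRSP",500,30,"lt25","CBZ400",3.00575,30
"DRSP",1000,20,"lt25","CBZ400",6.0115,30
"DRSP",1000,30,"lt25","CBZ400",6.0115,30
"DRSP",2000,20,"lt25","CBZ400",12.023,30
"DRSP",2000,30,"lt25","CBZ400",12.023,30
"DRSP",3000,20,"lt25","CBZ400",18.0345,30
"DRSP",3000,30,"lt25","CBZ400",18.0345,30
"DRSP",4000,20,"lt25","CBZ400",24.046,30
"DRSP",4000,30,"lt25","CBZ400",24.046,30
"LNG",30,0,"lt25","RIF600",0.243,30
"LNG",90,30,"lt25","RIF600",0.981,30
"LNG",100,20,"lt25","RIF600",1.089,30
"LNG",150,30,"lt25","RIF600",1.6335,30
"DRSP",500,20,"lt25","RIF600",2.45925,30
"DRSP",500,30,"lt25","RIF600",2.45925,30
"DRSP",1000,20,"lt25","RIF600",4.9185,30
"DRSP",1000,30,"lt25","RIF600",4.9185,30
"DRSP",2000,20,"lt25","RIF600",9.837,30
"DRSP",2000,30,"lt25","RIF600",9.837,30
"DRSP",3000,20,"lt25","RIF600",14.7555,30
"DRSP",3000,30,"lt25","RIF600",14.7555,30
"DRSP",4000,20,"lt25","RIF600",19.674,30
"DRSP",4000,30,"lt25","RIF600",19.674,30
"LNG",30,0,"25to30","none",0.4428,30
"LNG",90,30,"25to30","none",1.7876,30
"LNG",100,20,"25to30","none",1.9844,30
"LNG",150,30,"25to30","none",2.9766,30
"DRSP",500,20,"25to30","none",4.4813,30
"DRSP",500,30,"25to30","none",4.4813,30
"DRSP",1000,20,"25to30","none",8.9626,30
"DRSP",1000,30,"25to30","none",8.9626,30
"DRSP",2000,20,"25to30","none",17.9252,30
"DRSP",2000,30,"25to30","none",17.9252,30
"DRSP",3000,20,"25to30","none",26.8878,30
"DRSP",3000,30,"25to30","none",26.8878,30
"DRSP",4000,20,"25to30","none",35.8504,30
"DRSP",4000,30,"25to30","none",35.8504,30
"LNG",30,0,"25to30","CBZ400",0.24354,30
"LNG",90,30,"25to30","CBZ400",0.98318,30
"LNG",100,20,"25to30","CBZ400",1.09142,30
"LNG",150,30,"25to30","CBZ400",1.63713,30
"DRSP",500,20,"25to30","CBZ400",2.464715,30
"DRSP",500,30,"25to30","CBZ400",2.464715,30
"DRSP",1000,20,"25to30","CBZ400",4.92943,30
"DRSP",1000,30,"25to30","CBZ400",4.92943,30
"DRSP",2000,20,"25to30","CBZ400",9.85886,30
"DRSP",2000,30,"25to30","CBZ400",9.85886,30
"DRSP",3000,20,"25to30","CBZ400",14.78829,30
"DRSP",3000,30,"25to30","CBZ400",14.78829,30
"DRSP",4000,20,"25to30","CBZ400",19.71772,30
"DRSP",4000,30,"25to30","CBZ400",19.71772,30
"LNG",30,0,"25to30","RIF600",0.19926,30
"LNG",90,30,"25to30","RIF600",0.80442,30
"LNG",100,20,"25to30","RIF600",0.89298,30
"LNG",150,30,"25to30","RIF600",1.33947,30
"DRSP",500,20,"25to30","RIF600",2.016585,30
"DRSP",500,30,"25to30","RIF600",2.016585,30
"DRSP",1000,20,"25to30","RIF600",4.03317,30
"DRSP",1000,30,"25to30","RIF600",4.03317,30
"DRSP",2000,20,"25to30","RIF600",8.06634,30
"DRSP",2000,30,"25to30","RIF600",8.06634,30
"DRSP",3000,20,"25to30","RIF600",12.09951,30
"DRSP",3000,30,"25to30","RIF600",12.09951,30
"DRSP",4000,20,"25to30","RIF600",16.13268,30
"DRSP",4000,30,"25to30","RIF600",16.13268,30
"LNG",30,0,"ge30","none",0.4212,30
"LNG",90,30,"ge30","none",1.7004,30
"LNG",100,20,"ge30","none",1.8876,30
"LNG",150,30,"ge30","none",2.8314,30
"DRSP",500,20,"ge30","none",4.2627,30
"DRSP",500,30,"ge30","none",4.2627,30
"DRSP",1000,20,"ge30","none",8.5254,30
"DRSP",1000,30,"ge30","none",8.5254,30
"DRSP",2000,20,"ge30","none",17.0508,30
"DRSP",2000,30,"ge30","none",17.0508,30
"DRSP",3000,20,"ge30","none",25.5762,30
"DRSP",3000,30,"ge30","none",25.5762,30
"DRSP",4000,20,"ge30","none",34.1016,30
"DRSP",4000,30,"ge30","none",34.1016,30
"LNG",30,0,"ge30","CBZ400",0.23166,30
"LNG",90,30,"ge30","CBZ400",0.93522,30
"LNG",100,20,"ge30","CBZ400",1.03818,30
"LNG",150,30,"ge30","CBZ400",1.55727,30
"DRSP",500,20,"ge30","CBZ400",2.344485,30
"DRSP",500,30,"ge30","CBZ400",2.344485,30
"DRSP",1000,20,"ge30","CBZ400",4.68897,30
"DRSP",1000,30,"ge30","CBZ400",4.68897,30
"DRSP",2000,20,"ge30","CBZ400",9.37794,30
"DRSP",2000,30,"ge30","CBZ400",9.37794,30
"DRSP",3000,20,"ge30","CBZ400",14.06691,30
"DRSP",3000,30,"ge30","CBZ400",14.06691,30
"DRSP",4000,20,"ge30","CBZ400",18.75588,30
"DRSP",4000,30,"ge30","CBZ400",18.75588,30
"LNG",30,0,"ge30","RIF600",0.18954,30
"LNG",90,30,"ge30","RIF600",0.76518,30
"LNG",100,20,"ge30","RIF600",0.84942,30
"LNG",150,30,"ge30","RIF600",1.27413,30
"DRSP",500,20,"ge30","RIF600",1.918215,30
"DRSP",500,30,"ge30","RIF600",1.918215,30
"DRSP",1000,20,"ge30","RIF600",3.83643,30
"DRSP",1000,30,"ge30","RIF600",3.83643,30
"DRSP",2000,20,"ge30","RIF600",7.67286,30
"DRSP",2000,30,"ge30","RIF600",7.67286,30
"DRSP",3000,20,"ge30","RIF600",11.50929,30
"DRSP",3000,30,"ge30","RIF600",11.50929,30
"DRSP",4000,20,"ge30","RIF600",15.34572,30
"DRSP",4000,30,"ge30","RIF600",15.34572,30
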