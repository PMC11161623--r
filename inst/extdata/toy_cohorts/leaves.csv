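# synthetic toy census: three hand-made cohorts for ingest-mode checks
"plant_id","leaf_id","cohort_date","tagged","true_regime","true_longevity_d","observed_longevity_d","end_date","event","treatment_arm"
1,"P001_20190101_L01","2019-01-01",TRUE,NA,NA,10,"2019-01-11",1,NA
1,"P001_20190101_L02","2019-01-01",TRUE,NA,NA,20,"2019-01-21",1,NA
2,"P002_20190101_L01","2019-01-01",TRUE,NA,NA,30,"2019-01-31",1,NA
2,"P002_20190101_L02","2019-01-01",TRUE,NA,NA,40,"2019-02-10",1,NA
1,"P001_20190115_L01","2019-01-15",TRUE,NA,NA,42,"2019-02-26",1,NA
2,"P002_20190115_L01","2019-01-15",TRUE,NA,NA,42,"2019-02-26",1,NA
3,"P003_20190115_L01","2019-01-15",TRUE,NA,NA,42,"2019-02-26",1,NA
1,"P001_20190129_L01","2019-01-29",TRUE,NA,NA,7,"2019-02-05",1,NA
2,"P002_20190129_L01","2019-01-29",TRUE,NA,NA,14,"2019-02-12",1,NA
3,"P003_20190129_L01","2019-01-29",TRUE,NA,NA,21,"2019-02-19",1,NA
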