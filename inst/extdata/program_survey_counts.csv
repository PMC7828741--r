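variable,category,city,n
sex,male,bogota,619
sex,female,bogota,382
sex,male,mexico_city,370
sex,female,mexico_city,351
sex,male,santiago_cali,583
sex,female,santiago_cali,572
sex,male,santiago_chile,142
sex,female,santiago_chile,259
age_group,18-29,bogota,367
age_group,30-49,bogota,451
age_group,ge50,bogota,181
age_group,18-29,mexico_city,255
age_group,30-49,mexico_city,334
age_group,ge50,mexico_city,127
age_group,18-29,santiago_cali,306
age_group,30-49,santiago_cali,522
age_group,ge50,santiago_cali,331
age_group,18-29,santiago_chile,115
age_group,30-49,santiago_chile,181
age_group,ge50,santiago_chile,82
marital,single,bogota,574
marital,partner,bogota,425
marital,single,mexico_city,458
marital,partner,mexico_city,262
marital,single,santiago_cali,563
marital,partner,santiago_cali,596
education,primary,bogota,44
education,secondary,bogota,287
education,college,bogota,535
education,masters_plus,bogota,130
education,primary,mexico_city,8
education,secondary,mexico_city,272
education,college,mexico_city,363
education,masters_plus,mexico_city,78
education,primary,santiago_cali,44
education,secondary,santiago_cali,419
education,college,santiago_cali,617
education,masters_plus,santiago_cali,68
education,primary,santiago_chile,1
education,secondary,santiago_chile,71
education,college,santiago_chile,267
education,masters_plus,santiago_chile,0
ses3,low,bogota,207
ses3,middle,bogota,655
ses3,high,bogota,139
ses3,low,mexico_city,4
ses3,middle,mexico_city,52
ses3,high,mexico_city,602
ses3,low,santiago_cali,335
ses3,middle,santiago_cali,751
ses3,high,santiago_cali,73
ses3,low,santiago_chile,32
ses3,middle,santiago_chile,264
ses3,high,santiago_chile,43
car,yes,bogota,458
car,no,bogota,543
car,yes,mexico_city,202
car,no,mexico_city,349
car,yes,santiago_cali,703
car,no,santiago_cali,453
health3,excellent,bogota,314
health3,good,bogota,588
health3,fair,bogota,99
health3,excellent,santiago_cali,230
health3,good,santiago_cali,760
health3,fair,santiago_cali,167
health3,excellent,santiago_chile,277
health3,good,santiago_chile,104
health3,fair,santiago_chile,20
bmi_cat,under,bogota,20
bmi_cat,normal,bogota,644
bmi_cat,over,bogota,297
bmi_cat,obese,bogota,40
bmi_cat,under,mexico_city,4
bmi_cat,normal,mexico_city,352
bmi_cat,over,mexico_city,270
bmi_cat,obese,mexico_city,95
bmi_cat,under,santiago_cali,11
bmi_cat,normal,santiago_cali,511
bmi_cat,over,santiago_cali,469
bmi_cat,obese,santiago_cali,168
meets_pa_program,yes,bogota,453
meets_pa_program,no,bogota,548
meets_pa_program,yes,mexico_city,629
meets_pa_program,no,mexico_city,92
meets_pa_program,yes,santiago_cali,487
meets_pa_program,no,santiago_cali,672
meets_pa_program,yes,santiago_chile,109
meets_pa_program,no,santiago_chile,292
meets_ltpa,yes,bogota,688
meets_ltpa,no,bogota,313
meets_ltpa,yes,mexico_city,434
meets_ltpa,no,mexico_city,287
meets_overall,yes,bogota,857
meets_overall,no,bogota,144
meets_overall,yes,mexico_city,601
meets_overall,no,mexico_city,120
meets_transport,yes,bogota,524
meets_transport,no,bogota,477
meets_transport,yes,mexico_city,353
meets_transport,no,mexico_city,368
activity,cycling,bogota,603
activity,rollerblading,bogota,52
activity,walking,bogota,222
activity,running,bogota,118
activity,other,bogota,4
activity,cycling,mexico_city,634
activity,rollerblading,mexico_city,25
activity,walking,mexico_city,23
activity,running,mexico_city,38
activity,other,mexico_city,1
activity,cycling,santiago_cali,205
activity,rollerblading,santiago_cali,21
activity,walking,santiago_cali,464
activity,running,santiago_cali,163
activity,other,santiago_cali,286
activity,cycling,santiago_chile,275
activity,rollerblading,santiago_chile,29
activity,walking,santiago_chile,16
activity,running,santiago_chile,73
activity,other,santiago_chile,8
time_cat,lt3h,bogota,586
time_cat,3-4h,bogota,210
time_cat,ge4h,bogota,205
time_cat,lt3h,mexico_city,92
time_cat,3-4h,mexico_city,279
time_cat,ge4h,mexico_city,350
time_cat,lt3h,santiago_cali,796
time_cat,3-4h,santiago_cali,231
time_cat,ge4h,santiago_cali,132
time_cat,lt3h,santiago_chile,312
time_cat,3-4h,santiago_chile,62
time_cat,ge4h,santiago_chile,27
freq_cat,ge1_per_year,bogota,68
freq_cat,one_per_month,bogota,120
freq_cat,two_three_per_month,bogota,258
freq_cat,ge4_per_month,bogota,553
freq_cat,ge1_per_year,mexico_city,127
freq_cat,one_per_month,mexico_city,95
freq_cat,two_three_per_month,mexico_city,282
freq_cat,ge4_per_month,mexico_city,217
freq_cat,ge1_per_year,santiago_cali,110
freq_cat,one_per_month,santiago_cali,105
freq_cat,two_three_per_month,santiago_cali,200
freq_cat,ge4_per_month,santiago_cali,740
freq_cat,ge1_per_year,santiago_chile,184
freq_cat,one_per_month,santiago_chile,59
freq_cat,two_three_per_month,santiago_chile,47
freq_cat,ge4_per_month,santiago_chile,111
companion,alone,bogota,567
companion,accompanied,bogota,434
companion,alone,mexico_city,473
companion,accompanied,mexico_city,247
companion,alone,santiago_cali,763
companion,accompanied,santiago_cali,396
safety3,unsafe,bogota,37
safety3,safe,bogota,915
safety3,neither,bogota,48
safety3,unsafe,santiago_cali,494
safety3,safe,santiago_cali,383
safety3,neither,santiago_cali,282
safety3,unsafe,santiago_chile,22
safety3,safe,santiago_chile,379
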