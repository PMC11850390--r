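strain,age_days,sex,n_unelevated,n_unilateral,n_elevated,n_total
C57BL/6J,14.0,all,37,0,1,38
C57BL/6J,14.125,all,79,6,29,114
C57BL/6J,14.25,all,6,7,51,64
C57BL/6J,14.125,male,34,NA,NA,56
C57BL/6J,14.125,female,45,NA,NA,58
C57BL/6J,14.25,male,0,0,30,30
C57BL/6J,14.25,female,6,7,21,34
FVB/NJ,13.875,all,37,0,0,37
FVB/NJ,14.0,all,61,15,16,92
FVB/NJ,14.25,all,NA,NA,74,99
FVB/NJ,14.0,male,24,NA,NA,48
FVB/NJ,14.0,female,33,NA,NA,38
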