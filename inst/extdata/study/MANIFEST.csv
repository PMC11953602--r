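file,md5
constants.csv,3ece275441518aba7a33191b69bd6e9c
table2_cohort.csv,9e948b1ceed2823a94f1d3ff677b480b
table3_suggestions.csv,3f6850dd2e9a44171df2fd40c2000bcf
table4_gender.csv,c54b4c313127d644e3104a842f042bcf
table5_alarms.csv,daf1cba2e2d91a27c9a71b8ac8c9a5e3
table6_control.csv,c333a84eceeff1557706e5b5ea613638
table7_acceptance.csv,f68f177edbc48e414b2999657793b67c
table8_declines.csv,c9f6d7e155f9deaf3f73bf43e0544437
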