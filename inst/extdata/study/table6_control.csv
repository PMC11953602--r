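gender,severity,measure,center,n
female,warning,birth_complications,nursery_school,3
female,none,birth_complications,nursery_school,1
female,warning,bilingual,nursery_school,3
female,none,bilingual,nursery_school,4
male,alarm,birth_complications,nursery_school,4
male,alarm,birth_complications,psychopedagogical_center,2
male,none,birth_complications,nursery_school,3
male,alarm,family_history,nursery_school,1
male,alarm,family_history,psychopedagogical_center,1
male,alarm,bilingual,nursery_school,1
male,none,bilingual,nursery_school,2
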