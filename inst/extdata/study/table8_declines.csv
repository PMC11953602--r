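suggestion,reason,gender,month
refer_early_intervention,"We will monitor the situation closely. If necessary, we will consult the Early Assessment Team for guidance.",male,26
refer_early_intervention,"There are alternative forms of communication besides verbal language, and he demonstrates proficiency in them. We will observe his development and see how it progresses.",male,18
refer_early_intervention,"The questions do not align with the child's developmental stage.",female,10
refer_early_intervention,"The questions do not align with the child's developmental stage.",male,10
refer_early_intervention,"The questions do not align with the child's developmental stage.",female,15
repeat_2mo,"The questions do not align with the child's developmental stage.",female,12
repeat_2mo,"We consider that it is not necessary at this stage.",male,18
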