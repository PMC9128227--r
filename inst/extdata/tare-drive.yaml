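# TARE drive parameters measured from the heterozygote crosses
c_germ_tare: 0.888
c_embryo_tare: 0.632
homing_locus_rule: none
fitness:
  f_hom: 0.867
  component: both_sexes
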