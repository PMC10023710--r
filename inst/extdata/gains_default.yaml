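abd_act_profile:
- 2.6
- 0.023
- 0.0
abd_act_constant:
- 1.4
- 0.006
- 0.001
fe_dist_profile:
- 0.03
- 0.05
- 0.0
fe_dist_constant:
- 0.05
- 0.07
- 0.0
fe_act:
- 0.03
- 0.05
- 0.0
ir_dist_profile:
- 0.03
- 0.06
- 0.0
ir_dist_constant:
- 0.05
- 0.05
- 0.0
ir_act:
- 0.02
- 0.05
- 0.0
act_scale_abd: 2.0
act_scale_couple: 350.0
dist_scale: 3.0
ssp_slaved: yes
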