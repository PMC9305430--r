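outcome,group,timepoint,median,iqr,n
steps,intervention,T0,4314.83,3620.33,41
steps,intervention,T1,4577.85,4620.26,35
steps,intervention,T2,6042.45,6242.31,18
steps,intervention,T3,4556.94,5226.94,12
steps,control,T0,5084.83,5220.33,51
steps,control,T1,5361.50,5960.88,43
steps,control,T2,4909.32,5128.09,24
steps,control,T3,4821.64,5228.79,18
solid_di,intervention,T0,6.73,5.03,27
solid_di,intervention,T1,6.79,3.67,20
solid_di,intervention,T2,6.14,2.63,14
solid_di,intervention,T3,5.45,3.19,13
solid_di,control,T0,5.83,4.11,40
solid_di,control,T1,5.79,5.41,34
solid_di,control,T2,4.42,5.42,19
solid_di,control,T3,4.86,3.75,14
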