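name,strandedness,length_nt,mass_kda,kuhn_length_nm
dN-5,single,5,2.057,NA
dN-5p,double,5,4.286,NA
dN-8,single,8,2.594,NA
dN-8p,double,8,6.139,NA
dN-11,single,11,3.926,NA
dN-11p,double,11,7.993,NA
dN-14,single,14,4.872,NA
dN-17,single,17,5.795,NA
dN-50,single,50,15.682,4.5177
dN-50p,double,50,31.157,14.674
dT-50,single,50,15.541,2.6702
dA-50,single,50,15.992,9.3488
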