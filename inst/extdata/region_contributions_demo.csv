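zone,cr_r,cr_tau,cr_s,delta
north_of_400mm,1.26e22,6.63e21,4.59e22,-8.16e20
between_400_800mm,-2.94e20,2.74e21,2.66e22,6.41e19
south_of_800mm,6.12e22,6.68e21,3.65e22,1.93e21
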