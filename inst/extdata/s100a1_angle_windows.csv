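system,subunit,window_end_ns,mean_deg,sd_deg
apo,A,10,64.34,5.82
apo,A,40,68.71,5.18
apo,A,80,69.82,4.72
apo,B,10,46.42,6.86
apo,B,40,54.89,13.34
apo,B,80,66.94,17.02
holo,A,10,65.65,5.12
holo,A,40,72.19,7.59
holo,A,100,79.94,9.97
holo,B,10,66.40,1.64
holo,B,40,79.66,6.58
holo,B,100,106.13,11.99
ca_entry,A,10,66.75,8.23
ca_entry,A,40,77.50,5.97
ca_entry,A,80,80.31,5.84
ca_entry,B,10,47.34,5.96
ca_entry,B,40,42.30,5.93
ca_entry,B,80,62.01,8.76
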