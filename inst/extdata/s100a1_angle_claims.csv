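system,subunit,quantity,reported_deg
apo,A,window_mean,67.22
holo,A,window_mean,72.59
holo,B,window_mean,84.35
holo,A,first_last_diff,14.29
holo,B,first_last_diff,42.73
ca_entry,A,first_last_diff,45.46
ca_entry,B,first_last_diff,14.67
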