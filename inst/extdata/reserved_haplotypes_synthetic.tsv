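name	rs_sim01	rs_sim02	rs_sim03	rs_sim04	rs_sim05	rs_sim06	rs_sim07	rs_sim08	rs_sim09	rs_sim10	rs_sim11	rs_sim12	rs_sim13	rs_sim14	rs_sim15	rs_sim16	rs_sim17	rs_sim18	rs_sim19	rs_sim20	rs149109767
hap.1	1	1	0	1	1	0	0	1	0	1	1	1	0	0	0	0	0	0	0	1	0
hap.2	1	0	0	0	0	0	0	0	1	1	0	0	0	0	1	0	0	0	0	1	0
hap.3	0	0	0	0	0	0	1	0	1	0	0	1	0	0	0	0	0	1	1	0	0
hap.4	1	0	1	0	1	0	0	0	0	1	0	1	0	0	0	0	0	0	1	0	0
hap.5	0	1	0	0	0	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0
hap.6	0	0	0	1	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	1
hap.7	1	1	1	0	0	0	0	0	1	1	0	0	1	0	0	0	0	0	0	0	0
hap.8	0	1	0	1	0	0	0	1	0	0	0	0	1	1	0	0	1	0	0	1	1
hap.9	0	0	0	0	0	0	1	0	1	1	0	1	1	0	0	0	0	0	1	0	1
hap.10	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0	1	0	0	0	0	1
hap.11	0	0	0	0	0	0	1	0	1	0	1	1	1	0	1	0	1	0	0	0	1
hap.12	1	1	1	0	1	0	1	0	0	1	0	1	0	1	1	0	0	1	0	1	0
hap.13	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	0	0	0
hap.14	0	1	1	1	0	1	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0
hap.15	0	1	1	1	0	1	0	1	0	0	0	0	1	0	0	0	0	0	0	1	0
hap.16	1	1	0	0	0	1	1	1	1	0	0	1	0	1	0	1	1	0	0	1	0
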